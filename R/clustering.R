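# k-means partitioning of herbs in score space. Two solvers share one result
# type: a Lloyd iteration with k-means++ restarts, and a branch-and-bound
# exact enumeration over all set partitions, feasible for the small panels
# this package targets and used as the ground-truth oracle for Lloyd.

as_points_matrix <- function(points) {
  if (!is.data.frame(points) || !"herb_id" %in% names(points)) {
    abort("points must be a data frame with a 'herb_id' column")
  }
  num_cols <- names(points)[vapply(points, is.numeric, logical(1))]
  if (length(num_cols) == 0) abort("points must have numeric coordinate columns")
  points <- points[order(points$herb_id), , drop = FALSE]
  X <- as.matrix(points[, num_cols, drop = FALSE])
  if (any(!is.finite(X))) {
    abort("all coordinates must be finite; drop herbs with missing scores upstream")
  }
  rownames(X) <- points$herb_id
  X
}

scale_points <- function(X, scaling) {
  if (scaling == "zscore") {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    X <- X[, , drop = FALSE]
  }
  X
}

wss_of <- function(X, assignment) {
  sum(vapply(split(seq_len(nrow(X)), assignment), function(idx) {
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

centroids_of <- function(X, assignment) {
  labs <- sort(unique(assignment))
  cen <- t(vapply(labs, function(l) colMeans(X[assignment == l, , drop = FALSE]),
                  numeric(ncol(X))))
  tibble(cluster = labs) |>
    dplyr::bind_cols(as_tibble(cen, .name_repair = "minimal") |>
                       stats::setNames(colnames(X)))
}

new_herb_clusters <- function(X, assignment, wss, algorithm, k,
                              restarts = NA_integer_, seed = NA_integer_,
                              trace = NULL) {
  structure(
    list(
      assignments = tibble(herb_id = rownames(X)) |>
        dplyr::bind_cols(as_tibble(X, .name_repair = "minimal") |>
                           stats::setNames(colnames(X))) |>
        dplyr::mutate(cluster = as.integer(assignment)),
      centroids = centroids_of(X, assignment),
      wss = wss,
      k = k,
      algorithm = algorithm,
      restarts = restarts,
      seed = seed,
      space = colnames(X),
      trace = trace
    ),
    class = "herb_clusters"
  )
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (j in seq_len(k)[-1]) {
    idx[j] <- if (sum(d2) <= 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
  }
  X[idx, , drop = FALSE]
}

# squared distances, n x k
dist2_to_centroids <- function(X, centers) {
  outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) -
    2 * X %*% t(centers)
}

lloyd_once <- function(X, k, max_iter = 100L) {
  centers <- kmeanspp_init(X, k)
  assignment <- rep(0L, nrow(X))
  trace <- numeric()
  for (it in seq_len(max_iter)) {
    D <- dist2_to_centroids(X, centers)
    new_assign <- max.col(-D, ties.method = "first")  # nearest, lowest index on ties
    # empty-cluster repair: reseed at the point farthest from its own centroid
    for (c_empty in setdiff(seq_len(k), unique(new_assign))) {
      far <- which.max(D[cbind(seq_len(nrow(X)), new_assign)])
      new_assign[far] <- c_empty
      centers[c_empty, ] <- X[far, ]
      D <- dist2_to_centroids(X, centers)
    }
    for (c in unique(new_assign)) {
      centers[c, ] <- colMeans(X[new_assign == c, , drop = FALSE])
    }
    trace <- c(trace, wss_of(X, new_assign))
    if (identical(new_assign, assignment)) break
    assignment <- new_assign
  }
  list(assignment = assignment, wss = wss_of(X, assignment), trace = trace)
}

#' k-means by Lloyd iteration with k-means++ restarts
#'
#' Iterates nearest-centroid assignment (squared Euclidean; ties go to the
#' lowest-index centroid) and member-mean update to a fixed point, restarting
#' from independent k-means++ seedings and keeping the solution with minimal
#' within-cluster sum of squares (wss). Empty clusters arising during
#' iteration are repaired by reseeding the empty centroid at the point
#' farthest from its current centroid. Deterministic given `seed`; the input
#' row order is irrelevant because points are sorted by `herb_id` first.
#'
#' @param points Data frame with `herb_id` plus numeric coordinate columns;
#'   all coordinates must be finite (exclude herbs with missing scores
#'   upstream).
#' @param k Number of clusters (default 3).
#' @param restarts Number of k-means++ restarts (default 100).
#' @param seed Integer seed governing all restarts.
#' @param scaling `"none"` (default; score axes share the percent-of-control
#'   scale) or `"zscore"`.
#' @return A `herb_clusters` object: assignments, centroids, `wss`,
#'   bookkeeping fields, and (for `restarts = 1`) the per-iteration wss trace.
#' @seealso [kmeans_exact()], [canonical_labels()], [cluster_scores()]
#' @export
kmeans_lloyd <- function(points, k = 3, restarts = 100, seed = 1,
                         scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  X <- scale_points(as_points_matrix(points), scaling)
  if (k > nrow(X)) abort("k must not exceed the number of points")
  if (k < 1) abort("k must be positive")
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(X, k)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })
  new_herb_clusters(X, best$assignment, best$wss, "lloyd", k,
                    restarts = restarts, seed = seed,
                    trace = if (restarts == 1) best$trace else NULL)
}

#' Exact minimum-wss clustering by exhaustive enumeration
#'
#' Enumerates all set partitions of the points into at most `k` non-empty
#' clusters (restricted-growth strings with branch-and-bound pruning) and
#' returns the global wss minimum. For 15 points and k = 3 there are
#' 2,375,101 three-block partitions; the guard `exact_max_n` keeps the
#' enumeration feasible. Ties are broken by the lexicographically smallest
#' assignment vector over herbs sorted by `herb_id`.
#'
#' @inheritParams kmeans_lloyd
#' @param exact_max_n Enumeration guard; inputs with more points are refused
#'   with a pointer to [kmeans_lloyd()].
#' @return A `herb_clusters` object with `algorithm = "exact"`.
#' @export
kmeans_exact <- function(points, k = 3, exact_max_n = 18,
                         scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  X <- scale_points(as_points_matrix(points), scaling)
  if (nrow(X) > exact_max_n) {
    abort(paste0("exact enumeration limited to n <= ", exact_max_n,
                 " points; use kmeans_lloyd() for larger panels"))
  }
  if (k > nrow(X)) abort("k must not exceed the number of points")
  if (k < 1) abort("k must be positive")
  res <- exact_kmeans_cpp(unname(X), as.integer(k))
  new_herb_clusters(X, res$assignment, res$wss, "exact", k)
}

#' Relabel clusters canonically by activity
#'
#' Clusters are renumbered 1..k by ascending Euclidean norm of their
#' centroid. Because 0 = maximal inhibition on the percent-of-control scale,
#' cluster 1 is always the most active (strongest combined inhibition). Ties
#' between equal-norm centroids are broken by the smallest member `herb_id`.
#'
#' @param result A `herb_clusters` object.
#' @return The same object with relabelled assignments and centroids.
#' @export
canonical_labels <- function(result) {
  stopifnot(inherits(result, "herb_clusters"))
  cen <- result$centroids
  coord_cols <- setdiff(names(cen), "cluster")
  norms <- sqrt(rowSums(as.matrix(cen[, coord_cols, drop = FALSE])^2))
  first_member <- vapply(cen$cluster, function(l) {
    min(result$assignments$herb_id[result$assignments$cluster == l])
  }, character(1))
  ord <- order(norms, first_member)
  relabel <- stats::setNames(seq_along(ord), cen$cluster[ord])
  result$assignments$cluster <-
    as.integer(relabel[as.character(result$assignments$cluster)])
  cen$cluster <- as.integer(relabel[as.character(cen$cluster)])
  result$centroids <- dplyr::arrange(cen, .data$cluster)
  result
}

#' Cluster a score table in a two-score plane
#'
#' Convenience wrapper: selects the two score columns for the requested
#' plane, drops herbs with a missing coordinate (e.g. herbs without an L12
#' measurement have no `chi` score), runs the exact solver when the panel is
#' small enough (else Lloyd), and applies canonical activity-ordered labels.
#'
#' @param scores Score table from [score_panel()].
#' @param space `"alpha-beta"` or `"alpha-chi"` (any pair of score columns
#'   joined by `-` is accepted).
#' @param k Number of clusters.
#' @param algorithm `"auto"` (exact when n fits the guard), `"exact"` or
#'   `"lloyd"`.
#' @param restarts,seed Passed to [kmeans_lloyd()].
#' @param exact_max_n Enumeration guard for the exact solver.
#' @param scaling Coordinate scaling, see [kmeans_lloyd()].
#' @return A canonical-labelled `herb_clusters` object; dropped herbs are in
#'   attribute `dropped`.
#' @export
#' @examples
#' scores <- score_panel(read_activity_table(herbvec_example("activity")))
#' cl <- cluster_scores(scores, "alpha-beta", seed = 1)
#' tidy(cl)
cluster_scores <- function(scores, space = "alpha-beta", k = 3,
                           algorithm = c("auto", "exact", "lloyd"),
                           restarts = 100, seed = 1, exact_max_n = 18,
                           scaling = "none") {
  algorithm <- match.arg(algorithm)
  axes <- strsplit(space, "-", fixed = TRUE)[[1]]
  if (length(axes) != 2 || !all(axes %in% names(scores))) {
    abort(paste0("space '", space, "' does not name two score columns"))
  }
  pts <- scores[, c("herb_id", axes)]
  dropped <- pts$herb_id[!stats::complete.cases(pts)]
  pts <- pts[stats::complete.cases(pts), ]
  if (algorithm == "auto") {
    algorithm <- if (nrow(pts) <= exact_max_n) "exact" else "lloyd"
  }
  fit <- switch(algorithm,
    exact = kmeans_exact(pts, k = k, exact_max_n = exact_max_n,
                         scaling = scaling),
    lloyd = kmeans_lloyd(pts, k = k, restarts = restarts, seed = seed,
                         scaling = scaling))
  fit <- canonical_labels(fit)
  fit$space_name <- space
  attr(fit, "dropped") <- dropped
  fit
}

#' Best partition with one herb forced into its own cluster
#'
#' Exact minimum-wss partition subject to the constraint that `singleton_id`
#' forms a cluster by itself: the remaining points are partitioned exactly
#' into `k - 1` clusters. Useful for comparing a reported clustering that
#' isolates one herb against the unconstrained optimum.
#'
#' @inheritParams kmeans_exact
#' @param singleton_id The `herb_id` to isolate.
#' @return A canonical-labelled `herb_clusters` object.
#' @export
singleton_constrained_partition <- function(points, singleton_id, k = 3,
                                            exact_max_n = 18) {
  X <- as_points_matrix(points)
  if (!singleton_id %in% rownames(X)) abort("singleton_id not found in points")
  rest <- X[setdiff(rownames(X), singleton_id), , drop = FALSE]
  res <- exact_kmeans_cpp(unname(rest), as.integer(k - 1))
  assignment <- integer(nrow(X))
  names(assignment) <- rownames(X)
  assignment[rownames(rest)] <- res$assignment
  assignment[singleton_id] <- k
  fit <- new_herb_clusters(X, assignment[rownames(X)], wss_of(X, assignment),
                           "exact-constrained", k)
  canonical_labels(fit)
}

#' @export
print.herb_clusters <- function(x, ...) {
  cat("herb_clusters: k =", x$k, "| n =", nrow(x$assignments),
      "| algorithm =", x$algorithm, "| wss =", format(x$wss), "\n")
  cat("(scores are percent-of-control magnitudes; 0 = maximal inhibition,",
      "so cluster 1 is the most active)\n")
  sizes <- table(x$assignments$cluster)
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a clustering result
#'
#' @param x A `herb_clusters` object.
#' @param ... Unused.
#' @return A tibble with one row per clustered herb: `herb_id`, the
#'   coordinate columns, and `cluster`.
#' @export
tidy.herb_clusters <- function(x, ...) x$assignments

#' One-row summary of a clustering result
#'
#' @param x A `herb_clusters` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `wss`, `algorithm`.
#' @export
glance.herb_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), wss = x$wss,
         algorithm = x$algorithm)
}

#' Scatterplot of a clustering result
#'
#' @param object A `herb_clusters` object.
#' @param ... Unused.
#' @return A ggplot: herbs in score space, coloured by cluster, centroids
#'   marked with crosses.
#' @export
autoplot.herb_clusters <- function(object, ...) {
  axes <- object$space
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = object$centroids, shape = 4, size = 4,
                        stroke = 1.5) +
    ggplot2::labs(colour = "cluster",
                  caption = "0 = maximal inhibition; cluster 1 = most active") +
    ggplot2::theme_minimal()
}
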