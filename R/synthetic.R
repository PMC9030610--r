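# Synthetic panels with known cluster structure and cluster-coupled traits,
# for end-to-end testing and parameter-recovery experiments.

#' Cluster centroids resembling the example panel
#'
#' Three centroids in a two-endpoint activity space, placed at the
#' approximate cluster means of the packaged 15-herb panel: a compact
#' high-activity cluster near (40, 28), an eicosanoid-selective cluster near
#' (133, 31), and a diffuse low-activity cluster near (131, 105). Synthetic
#' panels built on these exercise the same geometry as the real data.
#'
#' @return A 3 x 2 matrix with endpoint column names `E1`, `E2`.
#' @export
paper_like_centroids <- function() {
  m <- rbind(c(40, 28), c(133, 31), c(131, 105))
  colnames(m) <- c("E1", "E2")
  m
}

#' Specify a synthetic herb panel
#'
#' @param n_herbs Number of herbs (>= `n_clusters`).
#' @param n_clusters Number of clusters.
#' @param centroids Matrix (`n_clusters` x endpoints) of cluster centroids on
#'   the percent-of-control scale, within \[0, 200\]; column names name the
#'   endpoints (default [paper_like_centroids()]).
#' @param spread Normal standard deviation per endpoint (percent), > 0.
#' @param trait_purity Probability that a herb carries its own cluster's
#'   signature trait rather than another cluster's, in \[0, 1\].
#' @param missing_rate Independent per-value missingness probability, in
#'   \[0, 1\].
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @return A `synthetic_panel_spec` object.
#' @export
synthetic_panel_spec <- function(n_herbs = 15, n_clusters = 3,
                                 centroids = paper_like_centroids(),
                                 spread = 10, trait_purity = 1,
                                 missing_rate = 0, seed = 1) {
  centroids <- as.matrix(centroids)
  if (is.null(colnames(centroids))) {
    colnames(centroids) <- paste0("E", seq_len(ncol(centroids)))
  }
  if (nrow(centroids) != n_clusters) {
    abort("centroids must have one row per cluster")
  }
  if (any(centroids < 0) || any(centroids > 200)) {
    abort("centroids must lie within [0, 200] percent of control")
  }
  if (length(spread) == 1) spread <- rep(spread, ncol(centroids))
  if (any(spread <= 0)) abort("spread must be > 0")
  if (n_herbs < n_clusters) abort("n_herbs must be >= n_clusters")
  if (trait_purity < 0 || trait_purity > 1) abort("trait_purity must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) abort("missing_rate must be in [0, 1]")
  structure(list(n_herbs = n_herbs, n_clusters = n_clusters,
                 centroids = centroids, spread = spread,
                 trait_purity = trait_purity, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

# signature traits cycled over the clusters
.signature_flavors <- c("bitter", "sweet", "pungent", "sour", "bland")
.signature_natures <- c("cold", "neutral", "warm")

#' Generate a synthetic herb panel
#'
#' Cluster memberships are assigned round-robin (balanced, so small panels
#' cannot lose a cluster by chance); endpoint values are drawn from
#' independent normals at the cluster centroid with the given spread and
#' clipped at 0 (values above 100 remain representable, mirroring
#' enhancement); each herb carries its cluster's signature flavor and nature
#' with probability `trait_purity`, otherwise those of another
#' uniformly-chosen cluster; each value is independently set missing with
#' probability `missing_rate`. Identical spec and seed give an identical
#' panel.
#'
#' @param spec A [synthetic_panel_spec()].
#' @return A list of class `synthetic_panel`: `profiles` (long activity
#'   tibble as from [read_activity_table()]), `traits` (trait tibble),
#'   `true_labels` (tibble `herb_id`, `cluster`), and `spec`.
#' @export
#' @examples
#' panel <- generate_panel(synthetic_panel_spec(n_herbs = 9, seed = 42))
#' panel$true_labels
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  k <- spec$n_clusters
  n <- spec$n_herbs
  d <- ncol(spec$centroids)
  endpoints <- colnames(spec$centroids)
  herb_ids <- sprintf("H%03d", seq_len(n))
  true <- rep_len(seq_len(k), n)

  withr::with_seed(spec$seed, {
    values <- matrix(NA_real_, n, d, dimnames = list(herb_ids, endpoints))
    for (i in seq_len(n)) {
      values[i, ] <- pmax(0, stats::rnorm(d, spec$centroids[true[i], ],
                                          spec$spread))
    }
    eff <- true
    impure <- stats::runif(n) >= spec$trait_purity
    if (k > 1 && any(impure)) {
      eff[impure] <- vapply(true[impure], function(cl) {
        sample(setdiff(seq_len(k), cl), 1)
      }, integer(1))
    }
    miss <- matrix(stats::runif(n * d) < spec$missing_rate, n, d)
  })
  values[miss] <- NA_real_

  profiles <- tidyr::expand_grid(herb_id = herb_ids, endpoint = endpoints) |>
    dplyr::mutate(
      display_name = .data$herb_id,
      value = values[cbind(.data$herb_id, .data$endpoint)],
      provenance = dplyr::if_else(is.na(.data$value), "missing", "measured"),
      citation = NA_character_
    ) |>
    dplyr::select("herb_id", "display_name", "endpoint", "value",
                  "provenance", "citation")

  sig_flavor <- rep_len(.signature_flavors, k)
  sig_nature <- rep_len(.signature_natures, k)
  traits <- tibble(
    herb_id = herb_ids,
    display_name = herb_ids,
    nature = factor(sig_nature[eff], levels = .nature_levels, ordered = TRUE),
    flavors = purrr::map(eff, ~ sig_flavor[.x]),
    meridians = rep(list(character()), n),
    actions = rep(list(character()), n)
  )

  structure(list(profiles = profiles, traits = traits,
                 true_labels = tibble(herb_id = herb_ids,
                                      cluster = as.integer(true)),
                 spec = spec),
            class = "synthetic_panel")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same herbs: 1 for identical partitions (up to label permutation), about 0
#' for independent ones, negative for less-than-chance agreement.
#'
#' @param labels_a,labels_b Tibbles with `herb_id` and `cluster`, or named
#'   vectors of labels. The two herb sets must coincide.
#' @return The adjusted Rand index, in \[-1, 1\].
#' @export
#' @examples
#' a <- c(x = 1, y = 1, z = 2)
#' adjusted_rand_index(a, c(x = 2, y = 2, z = 1))
adjusted_rand_index <- function(labels_a, labels_b) {
  as_named <- function(l) {
    if (is.data.frame(l)) stats::setNames(l$cluster, l$herb_id) else l
  }
  a <- as_named(labels_a)
  b <- as_named(labels_b)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || length(a) != length(b)) {
    abort("labelings must cover the same herb set")
  }
  b <- b[names(a)]
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
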