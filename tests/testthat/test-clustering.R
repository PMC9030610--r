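random_points <- function(n, d = 2, id_prefix = "p") {
  tibble::tibble(herb_id = sprintf("%s%02d", id_prefix, seq_len(n))) |>
    dplyr::bind_cols(stats::setNames(
      as.data.frame(matrix(stats::runif(n * d, 0, 150), n, d)),
      paste0("x", seq_len(d))))
}

test_that("degenerate k values behave as expected", {
  withr::with_seed(3, pts <- random_points(6))
  one <- kmeans_lloyd(pts, k = 1, restarts = 5, seed = 1)
  expect_equal(one$wss, wss_of <- sum(scale(as.matrix(pts[, -1]),
                                            scale = FALSE)^2),
               tolerance = 1e-9)
  expect_equal(unlist(one$centroids[, -1], use.names = FALSE),
               unname(colMeans(as.matrix(pts[, -1]))), tolerance = 1e-12)
  all_k <- kmeans_exact(pts, k = 6)
  expect_equal(all_k$wss, 0)
  expect_equal(dplyr::n_distinct(all_k$assignments$cluster), 6)
  expect_error(kmeans_lloyd(pts, k = 7), "exceed")
})

test_that("exact solver recovers three well-separated pairs", {
  pts <- tibble::tibble(
    herb_id = paste0("h", 1:6),
    x = c(0, 1, 100, 101, 0, 1),
    y = c(0, 1, 0, 1, 100, 101))
  fit <- canonical_labels(kmeans_exact(pts, k = 3))
  a <- tidy(fit)
  expect_equal(a$cluster[a$herb_id == "h1"], a$cluster[a$herb_id == "h2"])
  expect_equal(a$cluster[a$herb_id == "h3"], a$cluster[a$herb_id == "h4"])
  expect_equal(a$cluster[a$herb_id == "h5"], a$cluster[a$herb_id == "h6"])
  expect_equal(dplyr::n_distinct(a$cluster), 3)
})

test_that("duplicate points and zero-wss ties are handled", {
  pts <- tibble::tibble(herb_id = c("a", "b"), x = c(5, 5), y = c(2, 2))
  fit <- kmeans_exact(pts, k = 2)
  expect_equal(fit$wss, 0)
  # lexicographic tie rule: first herb in the first cluster
  expect_equal(tidy(fit)$cluster[tidy(fit)$herb_id == "a"], 1L)
})

test_that("panel clustering matches the known structure", {
  fit <- cluster_scores(fixture_scores(), "alpha-beta", k = 3, seed = 1)
  a <- tidy(fit)
  expect_equal(sort(as.integer(table(a$cluster))), c(3L, 4L, 8L))
  expect_setequal(a$herb_id[a$cluster == 1], most_active_cluster_ids())
  expect_setequal(a$herb_id[a$cluster == 2],
                  eicosanoid_selective_cluster_ids())
  # canonical cluster 1 centroid is the mean of its four members
  cen1 <- unlist(fit$centroids[fit$centroids$cluster == 1, c("alpha", "beta")])
  expect_equal(unname(cen1), c(mean(c(59, 28, 63, 2)), mean(c(45, 55, 14, 0))),
               tolerance = 1e-12)
})

test_that("Lloyd with restarts attains the exact optimum on the panel", {
  sc <- fixture_scores()
  ex <- cluster_scores(sc, "alpha-beta", algorithm = "exact")
  ll <- cluster_scores(sc, "alpha-beta", algorithm = "lloyd",
                       restarts = 100, seed = 42)
  expect_equal(ll$wss, ex$wss, tolerance = 1e-9)
  expect_equal(tidy(ll), tidy(ex))
})

test_that("lloyd wss is never below the exact optimum", {
  withr::with_seed(17, {
    for (i in 1:10) {
      pts <- random_points(sample(6:12, 1))
      ex <- kmeans_exact(pts, k = 3)
      ll <- kmeans_lloyd(pts, k = 3, restarts = 1, seed = i)
      expect_gte(ll$wss, ex$wss - 1e-9)
    }
  })
})

test_that("an independent solver cannot beat the exact optimum", {
  sc <- fixture_scores()
  pts <- sc[, c("herb_id", "alpha", "beta")]
  X <- as.matrix(pts[, -1])
  ex <- kmeans_exact(pts, k = 3)
  km <- withr::with_seed(5, stats::kmeans(X, 3, nstart = 100))
  expect_gte(km$tot.withinss, ex$wss - 1e-8)
  expect_equal(km$tot.withinss, ex$wss, tolerance = 1e-9)
})

test_that("row order does not change canonical assignments", {
  sc <- fixture_scores()
  base <- tidy(cluster_scores(sc, "alpha-beta", seed = 1))
  withr::with_seed(9, shuffled <- sc[sample(nrow(sc)), ])
  perm <- tidy(cluster_scores(shuffled, "alpha-beta", seed = 1))
  expect_equal(dplyr::arrange(perm, herb_id), dplyr::arrange(base, herb_id))
  # and for lloyd, whose seeding could otherwise depend on order
  base_l <- tidy(cluster_scores(sc, "alpha-beta", algorithm = "lloyd",
                                seed = 4))
  perm_l <- tidy(cluster_scores(shuffled, "alpha-beta", algorithm = "lloyd",
                                seed = 4))
  expect_equal(dplyr::arrange(perm_l, herb_id), dplyr::arrange(base_l, herb_id))
})

test_that("wss decreases monotonically within one Lloyd restart", {
  withr::with_seed(23, {
    for (i in 1:5) {
      pts <- random_points(20, d = 3)
      fit <- kmeans_lloyd(pts, k = 4, restarts = 1, seed = i)
      expect_true(all(diff(fit$trace) <= 1e-9))
    }
  })
})

test_that("result invariants: recomputable wss, centroids are member means", {
  withr::with_seed(31, pts <- random_points(14))
  for (fit in list(kmeans_exact(pts, 3),
                   kmeans_lloyd(pts, 3, restarts = 20, seed = 2))) {
    a <- tidy(fit)
    expect_true(all(!is.na(a$cluster)))
    expect_equal(dplyr::n_distinct(a$cluster), fit$k)  # no empty cluster
    X <- as.matrix(a[, c("x1", "x2")])
    recomputed <- sum(vapply(split(seq_len(nrow(X)), a$cluster), function(i) {
      sum(sweep(X[i, , drop = FALSE], 2,
                colMeans(X[i, , drop = FALSE]))^2)
    }, numeric(1)))
    expect_equal(fit$wss, recomputed, tolerance = 1e-9)
    for (cl in fit$centroids$cluster) {
      expect_equal(
        unlist(fit$centroids[fit$centroids$cluster == cl, c("x1", "x2")],
               use.names = FALSE),
        colMeans(X[a$cluster == cl, , drop = FALSE], ),
        tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("canonical labels order clusters by centroid norm, ties by member id", {
  pts <- tibble::tibble(herb_id = c("a", "b", "c", "d"),
                        x = c(0, 0, 3, 3), y = c(4, 4, 0, 0))
  fit <- canonical_labels(kmeans_exact(pts, k = 2))
  a <- tidy(fit)
  # centroid norms are 4 and 3, so the (3, 0) pair becomes cluster 1
  expect_equal(a$cluster[a$herb_id == "c"], 1L)
  # equal-norm tie: (0,5) vs (5,0); smallest member id wins
  pts2 <- tibble::tibble(herb_id = c("a", "z"), x = c(0, 5), y = c(5, 0))
  fit2 <- canonical_labels(kmeans_exact(pts2, k = 2))
  a2 <- tidy(fit2)
  expect_equal(a2$cluster[a2$herb_id == "a"], 1L)
})

test_that("exact solver refuses panels above the enumeration guard", {
  withr::with_seed(1, pts <- random_points(19))
  expect_error(kmeans_exact(pts, 3), "kmeans_lloyd")
  expect_error(cluster_scores(
    tibble::tibble(herb_id = "x", alpha = 1, beta = 2), "alpha-beta", k = 3),
    "exceed")
})

test_that("missing coordinates are refused at the solver level", {
  pts <- tibble::tibble(herb_id = c("a", "b", "c"), x = c(1, NA, 3),
                        y = c(1, 2, 3))
  expect_error(kmeans_exact(pts, 2), "finite")
})

test_that("tidy/glance/autoplot expose the expected surfaces", {
  fit <- cluster_scores(fixture_scores(), "alpha-beta")
  expect_named(tidy(fit), c("herb_id", "alpha", "beta", "cluster"))
  g <- glance(fit)
  expect_equal(g$n, 15)
  expect_equal(g$k, 3)
  expect_equal(g$algorithm, "exact")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("singleton-constrained search isolates the requested herb", {
  sc <- fixture_scores()
  pts <- sc[stats::complete.cases(sc[, c("alpha", "chi")]),
            c("herb_id", "alpha", "chi")]
  con <- singleton_constrained_partition(pts, "P_cocos", k = 3)
  a <- tidy(con)
  expect_equal(sum(a$cluster == a$cluster[a$herb_id == "P_cocos"]), 1)
  expect_gte(con$wss, kmeans_exact(pts, 3)$wss)
})
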