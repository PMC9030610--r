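# Quantifying the cluster-character overlay: are traditional characters
# (nature, flavors, selected actions) non-randomly distributed across the
# activity clusters? The original overlay is qualitative; the exact tests
# here are an engineering extension and are labelled as such in reports.

# action-token synonym map; values are regular expressions matched against
# the lower-cased action phrases
.action_synonyms <- list(
  expel_wind      = "expel wind|dispel wind",
  tonify_qi       = "tonify[a-z, -]*qi|invigorate[a-z, -]*qi|move qi",
  clear_heat      = "clear heat",
  remove_toxicity = "remove toxicity|relieve toxicity|dispel toxin|detoxi"
)

resolve_assignments <- function(assignments) {
  if (inherits(assignments, "herb_clusters")) assignments <- tidy(assignments)
  if (!all(c("herb_id", "cluster") %in% names(assignments))) {
    abort("assignments must have columns herb_id and cluster")
  }
  assignments[, c("herb_id", "cluster")]
}

# logical carrier vector for a trait token over a trait table
herb_has_trait <- function(traits, trait) {
  if (trait %in% .flavor_vocab) {
    purrr::map_lgl(traits$flavors, ~ trait %in% .x)
  } else if (trait %in% c("cold", "neutral", "warm")) {
    collapse_nature(traits$nature) == trait
  } else if (trait %in% .nature_levels) {
    as.character(traits$nature) == trait
  } else {
    pattern <- .action_synonyms[[trait]] %||% gsub("_", " ", trait, fixed = TRUE)
    purrr::map_lgl(traits$actions,
                   ~ any(stringr::str_detect(.x, pattern)))
  }
}

#' Build a trait-by-cluster contingency table
#'
#' Counts, for one trait token, how many herbs in each cluster carry it. A
#' trait token is a flavor (`bitter`, `sweet`, ...), a collapsed nature
#' (`cold`, `neutral`, `warm`; full ordinal levels also accepted), or an
#' action token (`expel_wind`, `tonify_qi`, `clear_heat`, `remove_toxicity`,
#' or any `underscored_phrase` matched against the action strings). Herbs
#' with an unknown (NA) trait field are excluded and listed in the
#' `excluded` attribute.
#'
#' @param assignments A `herb_clusters` object or a tibble with `herb_id`,
#'   `cluster`.
#' @param traits Trait table from [read_trait_table()].
#' @param trait Trait token.
#' @return A 2 x k integer matrix (rows `has`, `lacks`; columns the cluster
#'   labels) with attributes `trait` and `excluded`.
#' @export
#' @examples
#' scores <- score_panel(read_activity_table(herbvec_example("activity")))
#' cl <- cluster_scores(scores, "alpha-beta")
#' build_contingency(cl, read_trait_table(herbvec_example("traits")), "bitter")
build_contingency <- function(assignments, traits, trait) {
  assignments <- resolve_assignments(assignments)
  df <- dplyr::inner_join(assignments, traits, by = "herb_id")
  known <- if (trait %in% c(.nature_levels, "warm", "cold", "neutral")) {
    !is.na(df$nature)
  } else {
    rep(TRUE, nrow(df))
  }
  excluded <- df$herb_id[!known]
  df <- df[known, ]
  has <- herb_has_trait(df, trait)
  if (!any(has)) {
    abort(paste0("trait '", trait, "' is carried by no clustered herb"))
  }
  labs <- sort(unique(df$cluster))
  tab <- vapply(labs, function(l) {
    c(has = sum(has & df$cluster == l), lacks = sum(!has & df$cluster == l))
  }, integer(2))
  colnames(tab) <- labs
  structure(tab, trait = trait, excluded = excluded)
}

#' Exact test of association for a 2 x k contingency table
#'
#' For k = 2 the two-sided Fisher (hypergeometric) exact p-value. For k > 2,
#' the exact conditional p-value (probability ordering) when the margins keep
#' the table count enumerable, otherwise a Monte-Carlo permutation p-value
#' over cluster labels with a fixed seed. Degenerate margins (an empty row
#' or column) give p = 1 with a warning.
#'
#' @param table 2 x k matrix of non-negative counts (e.g. from
#'   [build_contingency()]).
#' @param seed Integer seed for the Monte-Carlo branch.
#' @param mc_draws Monte-Carlo draws (default 1e5).
#' @param max_tables Enumeration threshold on the (upper bound of the) number
#'   of tables with the observed margins (default 1e6).
#' @return A p-value in (0, 1].
#' @export
exact_association_test <- function(table, seed = 1L, mc_draws = 1e5,
                                   max_tables = 1e6) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || any(table < 0) || any(table != round(table))) {
    abort("table must be a 2 x k matrix of non-negative counts")
  }
  storage.mode(table) <- "integer"
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warn("degenerate margins (empty row or column); p = 1")
    return(1)
  }
  if (ncol(table) == 2) {
    return(min(stats::fisher.test(table)$p.value, 1))
  }
  n_tables_bound <- prod(pmin(colSums(table), rowSums(table)[1]) + 1)
  p <- if (n_tables_bound <= max_tables) {
    stats::fisher.test(table, workspace = 2e7)$p.value
  } else {
    withr::with_seed(seed, {
      stats::fisher.test(table, simulate.p.value = TRUE, B = mc_draws)$p.value
    })
  }
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values; the
#' resulting q-values are monotone in p and capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

default_enrichment_traits <- function(traits) {
  natures <- unique(collapse_nature(traits$nature))
  flavors <- sort(unique(unlist(traits$flavors)))
  actions <- names(.action_synonyms)
  actions <- actions[purrr::map_lgl(actions, function(a) {
    any(herb_has_trait(traits, a))
  })]
  c(sort(natures), flavors, actions)
}

#' Trait enrichment across clusters
#'
#' For every tested trait and cluster, compares carrier counts inside vs
#' outside the cluster with a two-sided Fisher exact test, and adjusts the
#' whole family of trait-by-cluster p-values by Benjamini-Hochberg. Odds
#' ratios use a 0.5 continuity correction when any cell is zero. This
#' quantification goes beyond the original qualitative overlay; pair it with
#' [cluster_overlay()] for the descriptive composition.
#'
#' @inheritParams build_contingency
#' @param trait_tokens Trait tokens to test; defaults to the collapsed
#'   natures and flavors present in `traits` plus the standard action tokens
#'   (`expel_wind`, `tonify_qi`, `clear_heat`, `remove_toxicity`) carried by
#'   at least one herb.
#' @param seed Seed for any Monte-Carlo branches.
#' @return A tibble: `trait`, `cluster`, `count_in`, `total_in`, `count_out`,
#'   `total_out`, `odds_ratio`, `p_value`, `q_value`.
#' @export
test_trait_enrichment <- function(assignments, traits, trait_tokens = NULL,
                                  seed = 1L) {
  assignments <- resolve_assignments(assignments)
  if (is.null(trait_tokens)) {
    trait_tokens <- default_enrichment_traits(
      dplyr::semi_join(traits, assignments, by = "herb_id"))
  }
  rows <- purrr::map_dfr(trait_tokens, function(trait) {
    tab <- build_contingency(assignments, traits, trait)
    purrr::map_dfr(colnames(tab), function(cl) {
      count_in <- tab["has", cl]
      total_in <- sum(tab[, cl])
      count_out <- sum(tab["has", ]) - count_in
      total_out <- sum(tab) - total_in
      m <- matrix(c(count_in, total_in - count_in,
                    count_out, total_out - count_out), nrow = 2)
      or_m <- if (any(m == 0)) m + 0.5 else m
      tibble(
        trait = trait, cluster = as.integer(cl),
        count_in = as.integer(count_in), total_in = as.integer(total_in),
        count_out = as.integer(count_out), total_out = as.integer(total_out),
        odds_ratio = (or_m[1, 1] * or_m[2, 2]) / (or_m[2, 1] * or_m[1, 2]),
        p_value = exact_association_test(m, seed = seed)
      )
    })
  })
  rows$q_value <- bh_adjust(rows$p_value)
  rows
}

#' Qualitative composition of each cluster
#'
#' The descriptive counterpart of [test_trait_enrichment()]: per cluster, the
#' member herbs and the counts of collapsed natures and flavors among them,
#' so statements like "all members of the most active cluster are bitter and
#' cold" can be read off directly.
#'
#' @inheritParams build_contingency
#' @return A tibble with one row per cluster: `cluster`, `n`, `members`,
#'   `natures`, `flavors` (counts formatted as `token n/N`).
#' @export
cluster_overlay <- function(assignments, traits) {
  assignments <- resolve_assignments(assignments)
  df <- dplyr::inner_join(assignments, traits, by = "herb_id")
  fmt_counts <- function(tokens, n) {
    tab <- sort(table(tokens), decreasing = TRUE)
    paste(sprintf("%s %d/%d", names(tab), tab, n), collapse = ", ")
  }
  df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      members = paste(sort(.data$herb_id), collapse = ", "),
      natures = fmt_counts(collapse_nature(.data$nature), dplyr::n()),
      flavors = fmt_counts(unlist(.data$flavors), dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
}

format_overlay <- function(overlay) {
  c("cluster composition overlay (descriptive; scores: 0 = maximal inhibition,",
    "so cluster 1 is the most active). Enrichment statistics, where written,",
    "are an extension beyond the original qualitative overlay.",
    "",
    unlist(purrr::pmap(overlay, function(cluster, n, members, natures, flavors) {
      c(sprintf("cluster %d (n = %d): %s", cluster, n, members),
        sprintf("  natures: %s", natures),
        sprintf("  flavors: %s", flavors))
    })))
}
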