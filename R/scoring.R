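# Normalization to the percent-of-control scale and the vector-magnitude
# activity scores: each herb's assay values over a chosen endpoint subset are
# read as a vector in activity space and summarised by its Euclidean norm.
# On this scale 0 = maximal inhibition, so SMALL magnitudes mean HIGH
# combined activity.

#' Convert percent inhibition to percent of control
#'
#' Source assays commonly report percent inhibition (100 = complete
#' inhibition). The analysis scale is percent of control remaining
#' (0 = maximal inhibition, 100 = no effect), i.e. `100 - inhibition`.
#' Negative inhibition (enhancement) maps above 100.
#'
#' @param pct_inhibition Numeric vector of percent-inhibition values.
#' @return Numeric vector on the percent-of-control scale.
#' @export
#' @examples
#' inhibition_to_remaining(c(100, 0, -49))
inhibition_to_remaining <- function(pct_inhibition) {
  if (!is.numeric(pct_inhibition)) abort("pct_inhibition must be numeric")
  if (any(!is.finite(pct_inhibition))) abort("pct_inhibition must be finite")
  100 - pct_inhibition
}

#' Normalise raw endpoint readings to percent of control
#'
#' @param treated Numeric vector of treated readings.
#' @param control Numeric vector (or scalar) of control readings; must be
#'   positive.
#' @return `100 * treated / control`.
#' @export
#' @examples
#' raw_to_percent_of_control(c(0, 5, 14.9), 10)
raw_to_percent_of_control <- function(treated, control) {
  if (!is.numeric(treated) || !is.numeric(control)) {
    abort("treated and control must be numeric")
  }
  if (any(!is.finite(control)) || any(control <= 0)) {
    abort("control readings must be finite and > 0")
  }
  100 * treated / control
}

# nearest integer, ties away from zero (reproduces 122.35 -> 122,
# 102.62 -> 103, 2.24 -> 2 on the example panel)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Define a vector space over assay endpoints
#'
#' A named subset of panel endpoints whose values form the activity vector to
#' be summarised by its Euclidean magnitude. The missing policy decides what
#' happens when a herb lacks some endpoint: `drop_herb` (default) returns a
#' missing score, `available_case` uses the endpoints that are present.
#'
#' @param name Score name (e.g. `"alpha"`, `"beta"`, `"chi"`).
#' @param endpoints Character vector of endpoint ids, non-empty, no duplicates.
#' @param missing_policy `"drop_herb"` or `"available_case"`.
#' @return A `vector_space` object.
#' @export
#' @examples
#' vector_space("beta", c("L5", "COX1"))
vector_space <- function(name, endpoints,
                         missing_policy = c("drop_herb", "available_case")) {
  missing_policy <- match.arg(missing_policy)
  if (length(endpoints) == 0) abort("endpoints must be non-empty")
  if (anyDuplicated(endpoints)) abort("endpoints must not contain duplicates")
  structure(list(name = name, endpoints = as.character(endpoints),
                 missing_policy = missing_policy),
            class = "vector_space")
}

#' Default score definitions
#'
#' The three standard scores: `alpha` over the two lipid-peroxidation assays
#' (LNE, LE), `beta` over the two core eicosanoid assays (L5, COX1), and
#' `chi` over all three eicosanoid assays (L5, COX1, L12). The published
#' magnitude table is best reproduced with the two-endpoint `alpha`; the
#' three-endpoint variant `c("LNE", "LE", "XO")` that the accompanying text
#' describes is available through `alpha_endpoints` (see the vignette for the
#' documented inconsistency).
#'
#' @param alpha_endpoints,beta_endpoints,chi_endpoints Endpoint id sets.
#' @param missing_policy Applied to all three spaces; `drop_herb` mirrors the
#'   reduced-panel convention (herbs lacking L12 get no `chi` score).
#' @return Named list of [vector_space()] objects.
#' @export
default_spaces <- function(alpha_endpoints = c("LNE", "LE"),
                           beta_endpoints = c("L5", "COX1"),
                           chi_endpoints = c("L5", "COX1", "L12"),
                           missing_policy = "drop_herb") {
  list(alpha = vector_space("alpha", alpha_endpoints, missing_policy),
       beta  = vector_space("beta",  beta_endpoints,  missing_policy),
       chi   = vector_space("chi",   chi_endpoints,   missing_policy))
}

#' Euclidean magnitude of one herb's activity vector
#'
#' @param profile Either a long activity tibble for a single herb (columns
#'   `endpoint`, `value`) or a named numeric vector of endpoint values.
#' @param spec A [vector_space()].
#' @return A list with `score` (unrounded Euclidean norm, `NA` when the
#'   missing policy leaves no usable vector) and `endpoints_used`.
#' @export
#' @examples
#' vector_magnitude(c(LNE = 88, LE = 85), vector_space("alpha", c("LNE", "LE")))
vector_magnitude <- function(profile, spec) {
  stopifnot(inherits(spec, "vector_space"))
  v <- if (is.data.frame(profile)) {
    if (anyDuplicated(profile$endpoint)) {
      abort("profile must contain a single herb (duplicated endpoints found)")
    }
    stats::setNames(profile$value, profile$endpoint)
  } else {
    profile
  }
  vals <- v[spec$endpoints]
  names(vals) <- spec$endpoints
  present <- spec$endpoints[!is.na(vals)]
  if (length(present) == 0 ||
      (spec$missing_policy == "drop_herb" &&
       length(present) < length(spec$endpoints))) {
    return(list(score = NA_real_, endpoints_used = character()))
  }
  if (any(vals[present] < 0)) abort("activity values must be non-negative")
  list(score = sqrt(sum(vals[present]^2)), endpoints_used = present)
}

#' Score a panel of herbs
#'
#' Computes one magnitude score per herb per vector space and returns a
#' herb-level score table. Herbs failing a space's missing policy carry `NA`
#' for that score.
#'
#' @param activity Long activity tibble ([read_activity_table()]).
#' @param spaces Named list of [vector_space()] objects (default
#'   [default_spaces()]).
#' @param rounding `"nearest"` (nearest integer, ties away from zero) or
#'   `"none"`.
#' @param measured_only If `TRUE`, values with `provenance == "literature"`
#'   are masked to missing before scoring, so the sensitivity of downstream
#'   results to literature substitutions can be quantified.
#' @return A tibble with `herb_id`, `display_name`, one numeric column per
#'   space, and one `endpoints_used_<space>` character column per space
#'   (endpoints joined by `+`, `NA` for unscored herbs).
#' @export
#' @examples
#' score_panel(read_activity_table(herbvec_example("activity")))
score_panel <- function(activity, spaces = default_spaces(),
                        rounding = c("nearest", "none"),
                        measured_only = FALSE) {
  rounding <- match.arg(rounding)
  if (is.null(names(spaces)) || any(!nzchar(names(spaces)))) {
    names(spaces) <- purrr::map_chr(spaces, "name")
  }
  if (measured_only) {
    activity <- activity |>
      dplyr::mutate(
        value = dplyr::if_else(.data$provenance == "literature",
                               NA_real_, .data$value),
        provenance = dplyr::if_else(.data$provenance == "literature",
                                    "missing", .data$provenance))
  }
  herbs <- dplyr::distinct(activity, .data$herb_id, .data$display_name)
  out <- herbs
  for (nm in names(spaces)) {
    spec <- spaces[[nm]]
    res <- purrr::map(herbs$herb_id, function(h) {
      vector_magnitude(activity[activity$herb_id == h,
                                c("endpoint", "value")], spec)
    })
    score <- purrr::map_dbl(res, "score")
    if (rounding == "nearest") score <- round_half_away(score)
    out[[nm]] <- score
    out[[paste0("endpoints_used_", nm)]] <- purrr::map_chr(
      res, function(r) {
        if (length(r$endpoints_used) == 0) NA_character_
        else paste(r$endpoints_used, collapse = "+")
      })
  }
  out
}

#' Write a score table
#'
#' Tab-separated output with missing scores coded `-`.
#'
#' @param scores Tibble from [score_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores |>
    dplyr::mutate(dplyr::across(
      dplyr::where(is.numeric),
      ~ dplyr::if_else(is.na(.x), "-", format(.x, scientific = FALSE,
                                              trim = TRUE))))
  out[is.na(out)] <- "-"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
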