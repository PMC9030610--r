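#' Default assay panel
#'
#' The six-endpoint panel used throughout: three antioxidant assays (LNE,
#' non-enzymatic lipid peroxidation; LE, enzymatic lipid peroxidation; XO,
#' xanthine oxidase superoxide generation) and three eicosanoid-biosynthesis
#' assays (L5, 5-lipoxygenase; COX1, cyclooxygenase-1; L12, 12-lipoxygenase).
#' All values are percent of control remaining: 0 means maximal inhibition,
#' 100 no effect, and values above 100 enhancement (e.g. pro-oxidant
#' behaviour in the enzymatic lipid-peroxidation model).
#'
#' @return A tibble with columns `id`, `label`, `group`.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  tibble(
    id = c("LNE", "LE", "XO", "L5", "COX1", "L12"),
    label = c(
      "lipid peroxidation, non-enzymatic (Fe2+/ascorbate)",
      "lipid peroxidation, enzymatic (CCl4/NADPH)",
      "xanthine oxidase / hypoxanthine superoxide generation",
      "5-lipoxygenase (5-HETE/LTB4, rat PMN leukocytes)",
      "cyclooxygenase-1 (12-HHTrE, human platelets)",
      "12-lipoxygenase (12-HETE, human platelets)"
    ),
    group = c("antioxidant", "antioxidant", "antioxidant",
              "eicosanoid", "eicosanoid", "eicosanoid")
  )
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("id", "group") %in% names(panel)))
  if (anyDuplicated(panel$id)) abort("panel endpoint ids must be unique")
  if (any(is.na(panel$group)) ||
      !all(panel$group %in% c("antioxidant", "eicosanoid"))) {
    abort("every panel endpoint needs group 'antioxidant' or 'eicosanoid'")
  }
  invisible(panel)
}

#' Paths to the packaged example tables
#'
#' Locations of the two packaged fixtures: the 15-herb, 6-endpoint activity
#' table (percent of control, with literature-substituted cells tagged
#' `[lit:...]`) and the matching herb character table (nature, flavors,
#' meridians, actions).
#'
#' @param which `"activity"` or `"traits"`.
#' @return A file path.
#' @export
#' @examples
#' read_activity_table(herbvec_example("activity"))
herbvec_example <- function(which = c("activity", "traits")) {
  which <- match.arg(which)
  fn <- switch(which,
               activity = "table2_activity.tsv",
               traits = "table1_traits.tsv")
  system.file("extdata", fn, package = "herbvec", mustWork = TRUE)
}
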