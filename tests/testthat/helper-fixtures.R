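# shared fixture accessors and frozen reference values

fixture_activity <- function() {
  read_activity_table(herbvec_example("activity"))
}

fixture_traits <- function() {
  read_trait_table(herbvec_example("traits"))
}

fixture_scores <- function(...) {
  score_panel(fixture_activity(), ...)
}

# the printed magnitude columns of the packaged 15-herb panel (alpha over the
# published column; beta over L5/COX1; chi over L5/COX1/L12, dash = missing)
printed_magnitudes <- function() {
  tibble::tribble(
    ~herb_id,         ~alpha, ~beta, ~chi,
    "A_dahurica",        191,   101,   NA,
    "A_pubescens",       122,    85,  119,
    "A_sinensis",        133,     0,   NA,
    "A_membranaceus",    119,    46,  111,
    "A_macrocephala",    141,   103,  150,
    "C_pilosula",        132,    91,   NA,
    "C_chinensis",        60,    45,   54,
    "C_aromatica",       120,   140,  176,
    "F_suspensa",         28,    55,  131,
    "L_edodes",          125,   124,  154,
    "P_lactiflora",       97,    78,  124,
    "P_amurense",         63,    14,   38,
    "P_cocos",           146,    46,   64,
    "R_glutinosa",       117,   121,  170,
    "S_baicalensis",       2,     0,   NA
  )
}

# herbs whose printed alpha equals the two-endpoint (LNE, LE) norm after
# nearest-integer rounding; the other four are documented inconsistencies
# (A_dahurica follows the three-endpoint definition; the remaining three are
# off by one, consistent with magnitudes computed on unrounded components)
alpha_consistent_herbs <- function() {
  setdiff(printed_magnitudes()$herb_id,
          c("A_dahurica", "A_sinensis", "C_pilosula", "C_chinensis"))
}

# wide herb-by-coordinate tibble from a synthetic panel's long profiles
panel_points <- function(panel) {
  tidyr::pivot_wider(panel$profiles[, c("herb_id", "endpoint", "value")],
                     names_from = "endpoint", values_from = "value")
}

most_active_cluster_ids <- function() {
  c("C_chinensis", "F_suspensa", "P_amurense", "S_baicalensis")
}

eicosanoid_selective_cluster_ids <- function() {
  c("A_sinensis", "A_membranaceus", "P_cocos")
}
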