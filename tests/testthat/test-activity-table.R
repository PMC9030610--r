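test_that("activity rows parse with values and measured provenance", {
  act <- fixture_activity()
  cc <- dplyr::filter(act, herb_id == "C_chinensis")
  expect_equal(stats::setNames(cc$value, cc$endpoint),
               c(LNE = 57, LE = 17, XO = 79, L5 = 44, COX1 = 11, L12 = 30))
  expect_true(all(cc$provenance == "measured"))
  expect_true(all(is.na(cc$citation)))
})

test_that("missing cells become NA with missing provenance", {
  act <- fixture_activity()
  sb <- dplyr::filter(act, herb_id == "S_baicalensis")
  expect_true(all(is.na(sb$value[sb$endpoint %in% c("XO", "L12")])))
  expect_equal(sb$provenance[sb$endpoint %in% c("XO", "L12")],
               c("missing", "missing"))
  expect_equal(sb$value[sb$endpoint == "LNE"], 2)
})

test_that("literature suffix notation parses into provenance + citation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tdisplay_name\tLNE\tCOX1",
               "h1\tHerb one\t12.5\t25[lit:hwang]"), path)
  act <- read_activity_table(path)
  cox <- dplyr::filter(act, endpoint == "COX1")
  expect_equal(cox$value, 25)
  expect_equal(cox$provenance, "literature")
  expect_equal(cox$citation, "hwang")
  # unlisted panel endpoints are filled as missing
  expect_equal(sum(act$provenance == "missing"), 4)
})

test_that("schema and validation errors are raised", {
  bad_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tLNE\tBOGUS", "h1\t1\t2"), bad_col)
  expect_error(read_activity_table(bad_col), "unknown endpoint")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tLNE", "h1\t-3"), neg)
  expect_error(read_activity_table(neg), "negative")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tLNE", "h1\t1", "h1\t2"), dup)
  expect_error(read_activity_table(dup), "duplicate")
})

test_that("header-only file yields an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("herb_id\tdisplay_name\tLNE\tLE", path)
  act <- read_activity_table(path)
  expect_equal(nrow(act), 0)
})

test_that("comma-delimited input and missing codes '', '-', 'NA' are accepted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("herb_id,LNE,LE,XO", "h1,5,-,NA", "h2,,7,8"), path)
  act <- read_activity_table(path)
  expect_equal(sum(act$provenance == "missing"),
               3 + 2 * 3)  # 3 coded missing + L5/COX1/L12 for both herbs
  expect_equal(act$value[act$herb_id == "h2" & act$endpoint == "LE"], 7)
})

test_that("packaged panel has 15 herbs, 6 endpoints, 5 stored missing cells", {
  act <- fixture_activity()
  expect_equal(dplyr::n_distinct(act$herb_id), 15)
  expect_equal(sort(unique(act$endpoint)), sort(default_panel()$id))
  miss <- dplyr::filter(act, provenance == "missing")
  expect_equal(nrow(miss), 5)
  expect_setequal(
    paste(miss$herb_id, miss$endpoint),
    c("A_dahurica L12", "A_sinensis L12", "C_pilosula L12",
      "S_baicalensis XO", "S_baicalensis L12"))
  lit <- dplyr::filter(act, provenance == "literature")
  expect_equal(nrow(lit), 5)
  expect_true(all(!is.na(lit$citation)))
})

test_that("write/read round trip preserves values, missingness, provenance", {
  act <- fixture_activity()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(act, path)
  back <- read_activity_table(path)
  expect_equal(back, act)
  # and values above 100 survive (enhancement is representable)
  expect_equal(back$value[back$herb_id == "A_dahurica" & back$endpoint == "LE"],
               149)
})

test_that("trait properties tokenize into nature, flavors, meridians", {
  tr <- fixture_traits()
  cc <- tr[tr$herb_id == "C_chinensis", ]
  expect_equal(as.character(cc$nature), "cold")
  expect_equal(cc$flavors[[1]], "bitter")
  expect_setequal(cc$meridians[[1]],
                  c("heart", "stomach", "large_intestine", "liver"))

  pc <- tr[tr$herb_id == "P_cocos", ]
  expect_equal(as.character(pc$nature), "neutral")
  expect_setequal(pc$flavors[[1]], c("sweet", "bland"))

  ap <- tr[tr$herb_id == "A_pubescens", ]
  expect_equal(as.character(ap$nature), "slightly_warm")
  expect_setequal(ap$flavors[[1]], c("pungent", "bitter"))
  # "slightly pungent" contributes the flavor, not a nature
  fs <- tr[tr$herb_id == "F_suspensa", ]
  expect_setequal(fs$flavors[[1]], c("bitter", "pungent"))
  expect_equal(as.character(fs$nature), "cold")
})

test_that("trait parsing warns on unknown flavors, errors without a nature", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tproperties", "h1\tBitter, salty, cold."), path)
  expect_warning(tr <- read_trait_table(path), "salty")
  expect_equal(tr$flavors[[1]], "bitter")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tproperties", "h1\tBitter, sweet."), path2)
  expect_error(read_trait_table(path2), "nature")
})

test_that("explicit nature/flavors columns are accepted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb_id\tnature\tflavors",
               "h1\tslightly warm\tpungent, bitter"), path)
  tr <- read_trait_table(path)
  expect_equal(as.character(tr$nature), "slightly_warm")
  expect_setequal(tr$flavors[[1]], c("pungent", "bitter"))
})

test_that("join matches herbs, reports orphans, errors on disjoint ids", {
  act <- fixture_activity()
  tr <- fixture_traits()
  joined <- join_panel(act, tr)
  expect_equal(dplyr::n_distinct(joined$herb_id), 15)
  expect_equal(nrow(attr(joined, "orphans")), 0)

  extra <- dplyr::bind_rows(tr, dplyr::mutate(tr[1, ], herb_id = "X_orphan"))
  joined2 <- join_panel(act, extra)
  expect_equal(dplyr::n_distinct(joined2$herb_id), 15)
  expect_equal(attr(joined2, "orphans")$herb_id, "X_orphan")
  expect_equal(attr(joined2, "orphans")$source, "traits")

  tr_disjoint <- dplyr::mutate(tr, herb_id = paste0("zzz_", herb_id))
  expect_error(join_panel(act, tr_disjoint), "no herb_id shared")
})

test_that("nature collapse maps the six levels onto cold/neutral/warm", {
  expect_equal(collapse_nature(c("cold", "slightly_cold", "neutral",
                                 "slightly_warm", "warm", "hot")),
               c("cold", "cold", "neutral", "warm", "warm", "warm"))
  expect_error(collapse_nature("tepid"), "unknown nature")
})
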