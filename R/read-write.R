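# Reading, validating and writing the herb x assay activity table and the
# herb x character table. Activity tables travel in long (tidy) form inside
# the package: one row per herb x endpoint with value + provenance.

.missing_codes <- c("-", "", "NA")

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_chr <- function(path) {
  readr::read_delim(path, delim = detect_delim(path),
                    col_types = readr::cols(.default = readr::col_character()),
                    na = character(), trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

# Parse one activity cell. Accepts plain numbers, the missing codes, and the
# literature-substitution suffix notation "25[lit:hwang]".
parse_activity_cell <- function(x) {
  x <- trimws(x %||% "")
  if (x %in% .missing_codes) {
    return(list(value = NA_real_, provenance = "missing",
                citation = NA_character_))
  }
  m <- stringr::str_match(x, "^([-0-9.eE+]+)\\s*\\[lit:([^]]+)\\]$")
  if (!is.na(m[1, 1])) {
    val <- suppressWarnings(as.numeric(m[1, 2]))
    if (is.na(val)) abort(paste0("cannot parse activity value: '", x, "'"))
    if (val < 0) abort(paste0("negative activity value: '", x, "'"))
    return(list(value = val, provenance = "literature",
                citation = trimws(m[1, 3])))
  }
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) abort(paste0("cannot parse activity value: '", x, "'"))
  if (val < 0) abort(paste0("negative activity value: '", x, "'"))
  list(value = val, provenance = "measured", citation = NA_character_)
}

#' Read a herb-by-assay activity table
#'
#' Reads a delimited text table (tab default, comma accepted) of
#' percent-of-control activity values (0 = maximal inhibition, 100 = no
#' effect, >100 = enhancement). Missing cells may be coded `-`, empty, or
#' `NA`; cells substituted from the literature may carry a provenance suffix
#' such as `25[lit:hwang]`, which is parsed into `provenance = "literature"`
#' plus a citation tag.
#'
#' @param path Path to the delimited file. Columns: `herb_id`, optionally
#'   `display_name`, then one column per panel endpoint id.
#' @param panel Endpoint definition table, as from [default_panel()]. Columns
#'   present in the file must be panel endpoints; panel endpoints absent from
#'   the file are filled as missing.
#' @return A long tibble with one row per herb and endpoint: `herb_id`,
#'   `display_name`, `endpoint`, `value`, `provenance` (`measured`,
#'   `literature` or `missing`) and `citation`.
#' @export
#' @examples
#' act <- read_activity_table(herbvec_example("activity"))
#' dplyr::filter(act, herb_id == "C_chinensis")
read_activity_table <- function(path, panel = default_panel()) {
  validate_panel(panel)
  raw <- read_delim_chr(path)
  if (!"herb_id" %in% names(raw)) abort("activity table needs a 'herb_id' column")
  meta_cols <- intersect(c("herb_id", "display_name"), names(raw))
  value_cols <- setdiff(names(raw), meta_cols)
  unknown <- setdiff(value_cols, panel$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown endpoint column(s): ", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(raw$herb_id)) {
    abort(paste0("duplicate herb_id: ",
                 paste(unique(raw$herb_id[duplicated(raw$herb_id)]),
                       collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(herb_id = character(), display_name = character(),
                  endpoint = character(), value = double(),
                  provenance = character(), citation = character()))
  }
  if (!"display_name" %in% names(raw)) raw$display_name <- raw$herb_id

  long <- tidyr::expand_grid(herb_id = raw$herb_id, endpoint = panel$id)
  cells <- purrr::pmap(long, function(herb_id, endpoint) {
    if (endpoint %in% value_cols) {
      parse_activity_cell(raw[[endpoint]][match(herb_id, raw$herb_id)])
    } else {
      list(value = NA_real_, provenance = "missing", citation = NA_character_)
    }
  })
  long |>
    dplyr::mutate(
      display_name = raw$display_name[match(.data$herb_id, raw$herb_id)],
      value = purrr::map_dbl(cells, "value"),
      provenance = purrr::map_chr(cells, "provenance"),
      citation = purrr::map_chr(cells, "citation")
    ) |>
    dplyr::select("herb_id", "display_name", "endpoint", "value",
                  "provenance", "citation")
}

#' Write an activity table
#'
#' Inverse of [read_activity_table()]: writes the wide tab-separated layout,
#' coding missing cells as `-` and literature-substituted cells with the
#' `value[lit:tag]` suffix, so that a write/read round trip preserves values,
#' missingness and provenance exactly.
#'
#' @param activity Long activity tibble as returned by [read_activity_table()].
#' @param path Output file path.
#' @param panel Endpoint definition table (fixes the column order).
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(activity, path, panel = default_panel()) {
  validate_panel(panel)
  fmt_cell <- function(value, provenance, citation) {
    if (provenance == "missing" || is.na(value)) return("-")
    txt <- format(value, scientific = FALSE, trim = TRUE)
    if (provenance == "literature") paste0(txt, "[lit:", citation, "]") else txt
  }
  wide <- activity |>
    dplyr::mutate(cell = purrr::pmap_chr(
      list(.data$value, .data$provenance, .data$citation), fmt_cell)) |>
    dplyr::select("herb_id", "display_name", "endpoint", "cell") |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "cell")
  cols <- c("herb_id", "display_name", intersect(panel$id, names(wide)))
  readr::write_tsv(wide[, cols], path, progress = FALSE)
  invisible(path)
}

# --- character (trait) table ------------------------------------------------

tokenize_phrase <- function(x) {
  x <- tolower(trimws(x %||% ""))
  x <- gsub("\\.$", "", x)
  x <- gsub("\\b(and|or)\\b", ",", x)
  toks <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  toks[nzchar(toks)]
}

parse_properties <- function(x, herb_id) {
  toks <- tokenize_phrase(x)
  nature <- character()
  flavors <- character()
  unknown <- character()
  for (tok in toks) {
    tok_us <- gsub(" +", "_", tok)
    if (tok_us %in% .nature_levels) {
      nature <- c(nature, tok_us)
    } else if (sub("^slightly ", "", tok) %in% .flavor_vocab) {
      flavors <- c(flavors, sub("^slightly ", "", tok))
    } else {
      unknown <- c(unknown, tok)
    }
  }
  if (length(nature) == 0) {
    abort(paste0("no recognizable nature token for herb '", herb_id,
                 "' in: '", x, "'"))
  }
  list(nature = nature[[1]], flavors = unique(flavors), unknown = unknown)
}

parse_token_set <- function(x, sep = ",") {
  x <- tolower(trimws(x %||% ""))
  x <- gsub("\\.$", "", x)
  if (sep == ",") x <- gsub("\\b(and|or)\\b", ",", x)
  toks <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  toks <- gsub(" +", "_", toks[nzchar(toks)])
  unique(toks)
}

#' Read a herb character table
#'
#' Reads the traditional-character table: one row per herb with its nature
#' (cold ... hot), flavors, meridians, and actions. Two layouts are accepted:
#' a free-text `properties` column (e.g. `"Bitter, slightly pungent, cold."`)
#' that is tokenized against the controlled nature and flavor vocabularies,
#' or explicit `nature` and `flavors` columns. Unknown flavor tokens are
#' collected into a warning, not an error; a row without a recognizable
#' nature token is an error.
#'
#' @param path Path to the delimited file (tab default, comma accepted).
#' @return A tibble with `herb_id`, `display_name`, `nature` (ordered factor
#'   over cold < slightly_cold < neutral < slightly_warm < warm < hot) and
#'   list-columns `flavors`, `meridians`, `actions` (lower-cased, underscored,
#'   deduplicated tokens; action tokens keep their spaces).
#' @export
#' @examples
#' traits <- read_trait_table(herbvec_example("traits"))
#' traits[traits$herb_id == "P_cocos", ]
read_trait_table <- function(path) {
  raw <- read_delim_chr(path)
  if (!"herb_id" %in% names(raw)) abort("trait table needs a 'herb_id' column")
  if (anyDuplicated(raw$herb_id)) abort("duplicate herb_id in trait table")
  if (!"display_name" %in% names(raw)) raw$display_name <- raw$herb_id
  unknown_all <- character()

  if ("properties" %in% names(raw)) {
    parsed <- purrr::map2(raw$properties, raw$herb_id, parse_properties)
    nature <- purrr::map_chr(parsed, "nature")
    flavors <- purrr::map(parsed, "flavors")
    unknown_all <- unlist(purrr::map(parsed, "unknown"))
  } else if (all(c("nature", "flavors") %in% names(raw))) {
    nature <- gsub(" +", "_", tolower(trimws(raw$nature)))
    bad <- !nature %in% .nature_levels
    if (any(bad)) {
      abort(paste0("no recognizable nature token for herb(s): ",
                   paste(raw$herb_id[bad], collapse = ", ")))
    }
    flavors <- purrr::map(raw$flavors, parse_token_set)
    unknown_all <- setdiff(unlist(flavors), .flavor_vocab)
    flavors <- purrr::map(flavors, intersect, y = .flavor_vocab)
  } else {
    abort("trait table needs either a 'properties' column or 'nature' + 'flavors'")
  }
  if (any(lengths(flavors) == 0)) {
    warn(paste0("herb(s) without recognized flavors: ",
                paste(raw$herb_id[lengths(flavors) == 0], collapse = ", ")))
  }
  if (length(unknown_all) > 0) {
    warn(paste0("unknown flavor token(s) ignored: ",
                paste(unique(unknown_all), collapse = ", ")))
  }
  meridians <- if ("meridians" %in% names(raw)) {
    purrr::map(raw$meridians, parse_token_set)
  } else {
    rep(list(character()), nrow(raw))
  }
  actions <- if ("actions" %in% names(raw)) {
    purrr::map(raw$actions, function(x) {
      toks <- trimws(strsplit(tolower(x %||% ""), ";", fixed = TRUE)[[1]])
      unique(toks[nzchar(toks)])
    })
  } else {
    rep(list(character()), nrow(raw))
  }
  tibble(
    herb_id = raw$herb_id,
    display_name = raw$display_name,
    nature = factor(nature, levels = .nature_levels, ordered = TRUE),
    flavors = flavors,
    meridians = meridians,
    actions = actions
  )
}

#' Join activity profiles with herb characters
#'
#' Inner join of the long activity table and the trait table on `herb_id`.
#' Herbs present in only one of the two tables are not an error: they are
#' dropped from the join and listed in the `orphans` attribute so the
#' reconciliation is auditable. An empty intersection is an error.
#'
#' @param activity Long activity tibble ([read_activity_table()]).
#' @param traits Trait tibble ([read_trait_table()]).
#' @return The joined long tibble (activity rows with the trait columns
#'   attached), with attribute `orphans`: a tibble of `herb_id`, `source`
#'   (`"activity"` or `"traits"`) for unmatched herbs.
#' @export
#' @examples
#' panel <- join_panel(read_activity_table(herbvec_example("activity")),
#'                     read_trait_table(herbvec_example("traits")))
#' dplyr::n_distinct(panel$herb_id)
join_panel <- function(activity, traits) {
  ids_a <- unique(activity$herb_id)
  ids_t <- unique(traits$herb_id)
  shared <- intersect(ids_a, ids_t)
  if (length(shared) == 0) abort("no herb_id shared between activity and trait tables")
  orphans <- dplyr::bind_rows(
    tibble(herb_id = setdiff(ids_a, ids_t), source = "activity"),
    tibble(herb_id = setdiff(ids_t, ids_a), source = "traits")
  )
  joined <- dplyr::inner_join(
    activity,
    dplyr::select(traits, -dplyr::any_of("display_name")),
    by = "herb_id"
  )
  attr(joined, "orphans") <- orphans
  joined
}
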