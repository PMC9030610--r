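# Single-call orchestration: score -> cluster -> associate -> report.
# Every numeric output is a deterministic function of (inputs, config, seed),
# and the run manifest records enough (config, seed, input hashes, versions)
# to re-execute a run.

#' Build a pipeline configuration
#'
#' @param activity Path to the activity table.
#' @param traits Path to the trait table, or `NULL` to skip the character
#'   overlay (then `association` must be `FALSE`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all stochastic stages.
#' @param k Number of clusters per space.
#' @param spaces Score planes to cluster (default both standard planes; herbs
#'   without an L12 value have no `chi` score and drop out of `alpha-chi`).
#' @param alpha_endpoints,beta_endpoints,chi_endpoints Endpoint sets for the
#'   three scores; see [default_spaces()].
#' @param missing_policy,rounding Passed to the scoring stage.
#' @param measured_only Mask literature-substituted values to missing.
#' @param algorithm,restarts,exact_max_n Clustering options, see
#'   [cluster_scores()].
#' @param association Run the trait-association stage.
#' @param enrichment_traits Trait tokens for [test_trait_enrichment()]
#'   (`NULL` = defaults).
#' @param figures Write scatterplot files (PDF plus a plotted-coordinate
#'   manifest TSV, which is the determinism surface for figures).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(activity, traits = NULL, out_dir,
                            seed = 1, k = 3,
                            spaces = c("alpha-beta", "alpha-chi"),
                            alpha_endpoints = c("LNE", "LE"),
                            beta_endpoints = c("L5", "COX1"),
                            chi_endpoints = c("L5", "COX1", "L12"),
                            missing_policy = "drop_herb",
                            rounding = "nearest",
                            measured_only = FALSE,
                            algorithm = "auto", restarts = 100,
                            exact_max_n = 18,
                            association = !is.null(traits),
                            enrichment_traits = NULL,
                            figures = TRUE) {
  if (!file.exists(activity)) abort(paste0("activity table not found: ", activity))
  if (association && is.null(traits)) {
    abort("association requires a trait table; set traits= or association = FALSE")
  }
  if (!is.null(traits) && !file.exists(traits)) {
    abort(paste0("trait table not found: ", traits))
  }
  structure(list(
    schema = "herbvec_config/1",
    activity = activity, traits = traits, out_dir = out_dir,
    seed = as.integer(seed), k = k, spaces = spaces,
    alpha_endpoints = alpha_endpoints, beta_endpoints = beta_endpoints,
    chi_endpoints = chi_endpoints, missing_policy = missing_policy,
    rounding = rounding, measured_only = measured_only,
    algorithm = algorithm, restarts = restarts, exact_max_n = exact_max_n,
    association = association, enrichment_traits = enrichment_traits,
    figures = figures
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file carries the same keys as [pipeline_config()] plus the
#' versioned `schema` key `herbvec_config/1`. Relative input paths are
#' resolved against the YAML file's directory. Configurations round-trip
#' losslessly through [write_pipeline_config()].
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "herbvec_config/1")) {
    abort("config file must declare schema: herbvec_config/1")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  args <- raw[setdiff(names(raw), "schema")]
  args$activity <- resolve(args$activity)
  args$traits <- resolve(args$traits)
  for (f in c("spaces", "alpha_endpoints", "beta_endpoints", "chi_endpoints")) {
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  }
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

space_axes <- function(space) strsplit(space, "-", fixed = TRUE)[[1]]

#' Run the full analysis pipeline
#'
#' Executes score -> cluster -> associate -> report and writes, under
#' `config$out_dir`: `scores.tsv`; per space `clusters_<space>.tsv`,
#' `centroids_<space>.tsv` and a `clusters_<space>.json` sidecar (seed,
#' algorithm, restarts, wss); for the `alpha-chi` space additionally the
#' best partition with the reported singleton herb isolated
#' (`clusters_alpha-chi_described.tsv`, see vignette); with association
#' enabled `enrichment_<space>.tsv` and `overlay_<space>.txt`; with figures
#' enabled `figure_<space>.pdf` and `figure_<space>_points.tsv`; and
#' `manifest.json` (config, seed, md5 input hashes, versions, per-stage row
#' counts). Reruns with the same inputs, config and seed produce
#' byte-identical text outputs. Any stage error aborts with a stage-tagged
#' message and removes files already written to `out_dir` by this run.
#'
#' @param config A `pipeline_config` (or path to a YAML config file).
#' @return Invisibly, a list with the in-memory results: `scores`, `clusters`
#'   (per space), `enrichment`, `overlay`, `files`.
#' @export
#' @examples
#' cfg <- pipeline_config(herbvec_example("activity"),
#'                        herbvec_example("traits"),
#'                        out_dir = tempfile("run"), figures = FALSE)
#' res <- run_pipeline(cfg)
#' res$scores
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out_path <- function(...) {
    p <- file.path(config$out_dir, ...)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  log_line <- function(...) message("[herbvec] ", ...)

  spaces_def <- default_spaces(config$alpha_endpoints, config$beta_endpoints,
                               config$chi_endpoints, config$missing_policy)

  activity <- stage("read", read_activity_table(config$activity))
  traits <- if (!is.null(config$traits)) {
    stage("read", read_trait_table(config$traits))
  }
  if (!is.null(traits)) stage("read", join_panel(activity, traits))
  log_line("read: ", dplyr::n_distinct(activity$herb_id), " herbs, ",
           dplyr::n_distinct(activity$endpoint), " endpoints")

  scores <- stage("score", score_panel(activity, spaces_def,
                                       rounding = config$rounding,
                                       measured_only = config$measured_only))
  enhancers <- activity$herb_id[!is.na(activity$value) & activity$value > 100]
  if (length(enhancers) > 0) {
    log_line("score: enhancer/pro-oxidant values (>100) in: ",
             paste(unique(enhancers), collapse = ", "))
  }
  stage("score", write_scores(scores, out_path("scores.tsv")))
  log_line("score: ", nrow(scores), " herbs scored")

  counts <- list(herbs = nrow(scores))
  clusters <- list()
  enrichment <- list()
  overlay <- list()
  for (space in config$spaces) {
    cl <- stage("cluster", cluster_scores(
      scores, space, k = config$k, algorithm = config$algorithm,
      restarts = config$restarts, seed = config$seed,
      exact_max_n = config$exact_max_n))
    clusters[[space]] <- cl
    stage("cluster", {
      readr::write_tsv(tidy(cl), out_path(paste0("clusters_", space, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(cl$centroids,
                       out_path(paste0("centroids_", space, ".tsv")),
                       progress = FALSE)
      jsonlite::write_json(
        list(space = space, seed = config$seed, algorithm = cl$algorithm,
             restarts = cl$restarts, k = cl$k, n = nrow(cl$assignments),
             wss = cl$wss, dropped = attr(cl, "dropped")),
        out_path(paste0("clusters_", space, ".json")),
        auto_unbox = TRUE, digits = NA)
    })
    if (space == "alpha-chi" && "P_cocos" %in% cl$assignments$herb_id) {
      # the originally reported reduced-panel partition isolates P. cocos;
      # report the best such constrained partition next to the optimum
      axes <- space_axes(space)
      pts <- scores[stats::complete.cases(scores[, c("herb_id", axes)]),
                    c("herb_id", axes)]
      described <- stage("cluster", singleton_constrained_partition(
        pts, "P_cocos", k = config$k))
      stage("cluster", readr::write_tsv(
        tidy(described),
        out_path(paste0("clusters_", space, "_described.tsv")),
        progress = FALSE))
    }
    counts[[paste0("clustered_", space)]] <- nrow(cl$assignments)
    log_line("cluster ", space, ": n = ", nrow(cl$assignments),
             ", wss = ", format(cl$wss))

    if (config$association) {
      enr <- stage("associate", test_trait_enrichment(
        cl, traits, trait_tokens = config$enrichment_traits,
        seed = config$seed))
      enrichment[[space]] <- enr
      ovl <- stage("associate", cluster_overlay(cl, traits))
      overlay[[space]] <- ovl
      stage("associate", {
        readr::write_tsv(enr, out_path(paste0("enrichment_", space, ".tsv")),
                         progress = FALSE)
        writeLines(format_overlay(ovl),
                   out_path(paste0("overlay_", space, ".txt")))
      })
      log_line("associate ", space, ": ", nrow(enr), " trait-cluster tests")
    }
    if (config$figures) {
      fig <- stage("report", plot_score_scatter(scores, cl, traits, space))
      stage("report", {
        readr::write_tsv(fig$data,
                         out_path(paste0("figure_", space, "_points.tsv")),
                         progress = FALSE)
        grDevices::pdf(out_path(paste0("figure_", space, ".pdf")),
                       width = 7, height = 5)
        print(fig)
        grDevices::dev.off()
      })
    }
  }

  stage("report", {
    manifest <- list(
      schema = "herbvec_run/1",
      config = unclass(config),
      inputs = as.list(tools::md5sum(stats::na.omit(
        c(config$activity, config$traits)))),
      counts = counts,
      wss = purrr::map(clusters, "wss"),
      versions = list(herbvec = as.character(utils::packageVersion("herbvec")),
                      r = paste(R.version$major, R.version$minor, sep = "."))
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  })
  log_line("report: manifest written to ", config$out_dir)

  invisible(list(scores = scores, clusters = clusters,
                 enrichment = enrichment, overlay = overlay,
                 files = written))
}

#' Scatterplot of herbs in a score plane
#'
#' One point per herb at its (alpha, beta) or (alpha, chi) scores, coloured
#' by collapsed nature (cold = blue, warm/hot = red, neutral = grey). When no
#' traits are supplied, all points use a neutral fallback colour with a
#' warning. Cluster hulls are drawn when a clustering is given. The axes are
#' raw magnitudes: low values mean high combined inhibition, which the
#' subtitle states explicitly.
#'
#' @param scores Score table from [score_panel()].
#' @param clusters Optional `herb_clusters` object for hull overlays.
#' @param traits Optional trait table for the nature colouring.
#' @param space Score plane, e.g. `"alpha-beta"`.
#' @return A ggplot object; its `data` holds the plotted coordinates.
#' @export
plot_score_scatter <- function(scores, clusters = NULL, traits = NULL,
                               space = "alpha-beta") {
  axes <- space_axes(space)
  if (!all(axes %in% names(scores))) {
    abort(paste0("space '", space, "' does not name two score columns"))
  }
  df <- scores[stats::complete.cases(scores[, axes]),
               c("herb_id", "display_name", axes)]
  if (nrow(df) < 2) abort("fewer than 2 herbs with both scores present")
  if (!is.null(traits) && any(df$herb_id %in% traits$herb_id)) {
    df$nature <- collapse_nature(
      traits$nature[match(df$herb_id, traits$herb_id)])
    df$nature[is.na(df$nature)] <- "unknown"
  } else {
    if (!is.null(traits)) warn("no herbs matched the trait table; using fallback colour")
    df$nature <- "unknown"
  }
  if (!is.null(clusters)) {
    df$cluster <- tidy(clusters)$cluster[match(df$herb_id,
                                               tidy(clusters)$herb_id)]
  }
  pal <- c(cold = "#2166ac", warm = "#b2182b", neutral = "grey55",
           unknown = "grey75")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]]))
  if (!is.null(clusters)) {
    hulls <- df[!is.na(df$cluster), ] |>
      dplyr::group_by(.data$cluster) |>
      dplyr::slice(grDevices::chull(.data[[axes[1]]], .data[[axes[2]]])) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_polygon(
      data = hulls,
      ggplot2::aes(group = .data$cluster),
      fill = NA, colour = "grey40", linetype = "dashed")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$nature), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$display_name),
                       size = 2.7, vjust = -0.9, check_overlap = TRUE) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(
      x = paste0(axes[1], " (antioxidant magnitude)"),
      y = paste0(axes[2], " (eicosanoid-inhibition magnitude)"),
      colour = "nature",
      subtitle = "percent-of-control magnitudes: 0 = maximal inhibition"
    ) +
    ggplot2::theme_minimal()
}
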