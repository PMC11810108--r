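## End-to-end pipeline orchestration: YAML configuration, staged
## execution, result tables and a reproducibility manifest.

.CONFIG_SCHEMA <- list(
  seed = NULL,
  output_dir = NULL,
  simulate = c("preset", "n_fields", "n_cells", "width", "height",
               "shell_probability", "seed"),
  input = c("tiffs"),
  preprocess = c("shading_scale_px", "background_radius_px"),
  segmentation = c("min_cell_area_px", "max_cell_area_px", "min_ib_area_px",
                   "intensity_k"),
  classification = c("drop_border_cells"),
  screen = c("alpha", "min_delta_points", "direction", "table",
             "wildtype"),
  association = c("probe_distance_px", "surrounded_threshold")
)

#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a nested list, checks every section and key
#' against the configuration schema (unknown keys are rejected by name)
#' and fills defaults.
#'
#' @param config YAML file path or named list.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), names(.CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    allowed <- .CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_dir)) stop("config requires output_dir")
  config
}

.configParams <- function(config) {
  pre <- config$preprocess %||% list()
  seg <- config$segmentation %||% list()
  asc <- config$association %||% list()
  cls <- config$classification %||% list()
  analysisParams(
    shadingScalePx = pre$shading_scale_px %||% 64,
    backgroundRadiusPx = pre$background_radius_px %||% 7,
    minCellAreaPx = seg$min_cell_area_px %||% 200,
    maxCellAreaPx = seg$max_cell_area_px %||% 5000,
    minIBAreaPx = seg$min_ib_area_px %||% 4,
    intensityK = seg$intensity_k %||% 6,
    probeDistancePx = asc$probe_distance_px %||% 3,
    surroundedThreshold = asc$surrounded_threshold %||% 0.5,
    dropBorderCells = cls$drop_border_cells %||% TRUE)
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline from a configuration
#'
#' Stages run in their fixed order: simulate (or ingest TIFFs) ->
#' preprocess -> segment -> classify -> screen and/or associate, as
#' configured. All result tables are written into `output_dir`, followed
#' by a run manifest (config hash, package version, per-file checksums,
#' timestamps, seed) written atomically last, so a manifest's presence
#' certifies a complete run. A stage failure aborts with the stage name.
#' Input files are never modified; the same configuration and seed
#' reproduce identical result tables.
#'
#' @param config YAML path or list, see [pipelineConfig()].
#' @param quiet suppress per-stage object-count logging.
#' @return invisibly, a list with `manifest` and the in-memory `results`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  config <- pipelineConfig(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message(sprintf(...))
  params <- .configParams(config)
  written <- character()
  emit <- function(tab, name) {
    p <- file.path(config$output_dir, name)
    writeResultTable(tab, p)
    written <<- c(written, p)
  }
  results <- list()

  ## stage: simulate / ingest
  fields <- NULL; truths <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    nF <- sim$n_fields %||% 1L
    law <- phaseCountLaw(sim$preset %||% "wildtype")
    fields <- vector("list", nF); truths <- vector("list", nF)
    for (i in seq_len(nF)) {
      sp <- fieldSpec(width = as.integer(sim$width %||% 1024L),
                      height = as.integer(sim$height %||% 1024L),
                      nCells = as.integer(sim$n_cells %||% 150L),
                      countLaw = law,
                      shellProbability = sim$shell_probability %||% 0,
                      seed = .deriveSeed(sim$seed %||% config$seed, i))
      fx <- tryCatch(generateField(sp),
                     error = function(e) stop("stage simulate, field ", i,
                                              ": ", conditionMessage(e)))
      fields[[i]] <- fx$field; truths[[i]] <- fx$truth
      log("simulate: field %d/%d, %d cells, %d inclusions planted", i, nF,
          nrow(groundTruthCells(fx$truth)),
          nrow(groundTruthInclusions(fx$truth)))
    }
  } else if (!is.null(config$input$tiffs)) {
    fields <- lapply(config$input$tiffs, readImageField)
    log("ingest: %d TIFF field(s)", length(fields))
  }

  ## stages: preprocess + segment + classify (+ associate) per field
  if (!is.null(fields)) {
    ana <- tryCatch(
      analyzeFields(fields, params),
      error = function(e) stop("stage analyze: ", conditionMessage(e)))
    results$cells <- ana$cells
    results$summary <- ana$summary
    if (!is.null(ana$cells) && nrow(ana$cells)) {
      emit(ana$cells, "cells.csv")
      log("classify: %d cells (%d border-flagged)", nrow(ana$cells),
          sum(ana$cells$border_flag))
    }
    if (!is.null(ana$inclusions) && nrow(ana$inclusions)) {
      emit(ana$inclusions, "inclusions.csv")
      log("segment: %d inclusions", nrow(ana$inclusions))
    }
    if (!is.null(ana$summary)) emit(ana$summary, "summary.csv")
    if (!is.null(ana$association) && nrow(ana$association)) {
      emit(ana$association, "association.csv")
      sa <- summarizeAssociation(ana$association)
      jsonlite::write_json(
        list(overall = sa$overall, n = sa$n),
        file.path(config$output_dir, "association_summary.json"),
        auto_unbox = TRUE, digits = NA)
      written <- c(written,
                   file.path(config$output_dir, "association_summary.json"))
      results$association <- ana$association
      log("associate: %d inclusions scored, %.1f%% surrounded", sa$n,
          100 * sa$overall)
    }
    if (!is.null(truths)) {
      planted <- do.call(rbind, lapply(seq_along(truths), function(i) {
        tc <- groundTruthCells(truths[[i]])
        if (nrow(tc)) cbind(field_id = sprintf("field%03d", i), tc)
        else NULL
      }))
      if (!is.null(planted)) emit(planted, "planted_cells.csv")
      results$truths <- truths
    }
  }

  ## stage: screen (tabular)
  if (!is.null(config$screen)) {
    scr <- config$screen
    tab <- if (!is.null(scr$table)) readScreenTable(scr$table)
           else stop("stage screen: config$screen$table is required")
    wt <- as.numeric(scr$wildtype %||%
                       stop("stage screen: config$screen$wildtype required"))
    crit <- hitCriteria(scr$alpha %||% 0.05,
                        scr$min_delta_points %||% 20,
                        scr$direction %||% "increase")
    calls <- tryCatch(callHits(tab, wt, crit),
                      error = function(e) stop("stage screen: ",
                                               conditionMessage(e)))
    emit(calls$hits, "hits.csv")
    jsonlite::write_json(calls$summary,
                         file.path(config$output_dir, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(config$output_dir, "screen_summary.json"))
    results$screen <- calls
    log("screen: %d of %d mutants called as hits", calls$summary$n_hits,
        calls$summary$n_mutants)
  }

  manifest <- list(
    config_hash = .md5OfObject(config),
    package_version = as.character(packageVersion("ibscreen")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p))))
  tmp <- file.path(config$output_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(config$output_dir, "manifest.json"))
  invisible(list(manifest = manifest, results = results))
}
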