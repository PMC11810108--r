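#' Analysis parameters for the field pipeline
#'
#' All tunables of the per-field analysis in one validated list. Defaults
#' follow the pipeline's declared operating point: shading smoothing at
#' 64 px (>= 4x the default cell radius), top-hat radius about 3x the mean
#' inclusion radius, cell areas 200-5000 px, inclusions of at least 4 px
#' detected at 6 MADs above the per-cell median, encirclement probed at
#' 3 px with majority (0.5) surround threshold.
#'
#' @param shadingScalePx shading smoothing scale (px).
#' @param backgroundRadiusPx top-hat disk radius (px).
#' @param minCellAreaPx,maxCellAreaPx retained cell area range (px).
#' @param minIBAreaPx minimum inclusion area (px).
#' @param intensityK per-cell robust threshold multiplier (MADs).
#' @param probeDistancePx encirclement probe distance (px).
#' @param surroundedThreshold encirclement fraction counting as surrounded.
#' @param dropBorderCells flag cells touching the field border and exclude
#'   them from summaries.
#' @return named list of parameters.
#' @export
analysisParams <- function(shadingScalePx = 64, backgroundRadiusPx = 7,
                           minCellAreaPx = 200, maxCellAreaPx = 5000,
                           minIBAreaPx = 4, intensityK = 6,
                           probeDistancePx = 3, surroundedThreshold = 0.5,
                           dropBorderCells = TRUE) {
  p <- list(shadingScalePx = shadingScalePx,
            backgroundRadiusPx = backgroundRadiusPx,
            minCellAreaPx = minCellAreaPx, maxCellAreaPx = maxCellAreaPx,
            minIBAreaPx = minIBAreaPx, intensityK = intensityK,
            probeDistancePx = probeDistancePx,
            surroundedThreshold = surroundedThreshold,
            dropBorderCells = dropBorderCells)
  stopifnot(all(vapply(p[1:8], function(x)
    is.numeric(x) && is.finite(x) && x >= 0, logical(1))))
  p
}

#' Run the full per-field analysis
#'
#' Chains the pipeline stages in their fixed order: shading correction,
#' background subtraction, cell segmentation (on the shading-corrected
#' aggregate channel), inclusion segmentation (on the background-
#' subtracted channel), mask combination into per-cell counts, Class 1/2/3
#' classification, and — when an organelle channel is present —
#' encirclement scoring against the organelle mask.
#'
#' @param field an [ImageField-class] with channel `"aggregate"` and
#'   optionally `"organelle"`.
#' @param params see [analysisParams()].
#' @param fieldId identifier used in all record tables.
#' @return list with `cellMask`, `ibMask`, `assignment`, `cells` (records),
#'   `inclusions`, `summary` (population summary or `NULL` when no cells),
#'   and `association` (records or `NULL`).
#' @examples
#' fx <- generateField(fieldSpec(width = 256L, height = 256L, nCells = 8L,
#'                               seed = 3L))
#' res <- analyzeField(fx$field)
#' res$summary
#' @export
analyzeField <- function(field, params = analysisParams(),
                         fieldId = "field1") {
  if (!"aggregate" %in% channelNames(field))
    stop("field must contain an 'aggregate' channel")
  pp <- preprocessField(field, params$shadingScalePx,
                        params$backgroundRadiusPx)
  corr <- getChannel(pp$corrected, "aggregate")
  spot <- getChannel(pp$spots, "aggregate")
  cellMask <- segmentCells(corr, params$minCellAreaPx, params$maxCellAreaPx)
  ibMask <- segmentInclusions(spot, cellMask, params$minIBAreaPx,
                              params$intensityK)
  assignment <- assignInclusions(cellMask, ibMask, image = corr)
  cells <- cellRecords(cellMask, assignment$counts, fieldId)
  if (!params$dropBorderCells) cells$border_flag <- FALSE
  summary <- if (nrow(cells) && any(!cells$border_flag))
    summarizePopulation(cells) else NULL
  association <- NULL
  if ("organelle" %in% channelNames(field) &&
      objectCount(ibMask) > 0L) {
    org <- organelleMask(getChannel(pp$corrected, "organelle"))
    association <- associationRecords(
      ibMask, assignment, cells, org,
      probeDistancePx = params$probeDistancePx,
      surroundedThreshold = params$surroundedThreshold, fieldId = fieldId)
  }
  list(cellMask = cellMask, ibMask = ibMask, assignment = assignment,
       cells = cells, inclusions = assignment$inclusions,
       summary = summary, association = association)
}

#' Analyze a list of fields and pool the records
#'
#' @param fields list of [ImageField-class] objects.
#' @param params see [analysisParams()].
#' @param fieldIds identifiers, one per field.
#' @return list with pooled `cells`, `inclusions`, `association`
#'   data.frames and the pooled population `summary`.
#' @export
analyzeFields <- function(fields, params = analysisParams(),
                          fieldIds = sprintf("field%03d",
                                             seq_along(fields))) {
  res <- Map(function(f, id) analyzeField(f, params, id), fields, fieldIds)
  cells <- do.call(rbind, lapply(res, `[[`, "cells"))
  inclusions <- do.call(rbind, lapply(res, function(r) {
    if (nrow(r$inclusions))
      cbind(field_id = r$cells$field_id[1] %||% "field", r$inclusions)
    else NULL
  }))
  assoc <- do.call(rbind, lapply(res, `[[`, "association"))
  summary <- if (!is.null(cells) && any(!cells$border_flag))
    summarizePopulation(cells) else NULL
  list(cells = cells, inclusions = inclusions, association = assoc,
       summary = summary, perField = res)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
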