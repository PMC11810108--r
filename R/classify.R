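## Class 1/2/3 phenotype assignment and population summaries.

.CLASS_LEVELS <- c("NO_IB", "CLASS1", "CLASS2", "CLASS3")

#' Classify a cell by its inclusion count
#'
#' The phenotype rule of the screen: a cell with exactly one inclusion is
#' Class 1, exactly two is Class 2, three or more is Class 3; a cell with
#' no inclusion is unclassed (`NO_IB`). Vectorized, total on non-negative
#' integers, and idempotent on its range.
#'
#' @param ibCount non-negative integer vector of per-cell inclusion counts.
#' @return factor with levels `NO_IB`, `CLASS1`, `CLASS2`, `CLASS3`.
#' @examples
#' classifyCell(c(0, 1, 2, 3, 7))
#' @export
classifyCell <- function(ibCount) {
  if (length(ibCount) && (any(!is.finite(ibCount)) || any(ibCount < 0) ||
                          any(ibCount != floor(ibCount))))
    stop("ibCount must contain non-negative integers")
  idx <- pmin(as.integer(ibCount), 3L) + 1L
  factor(.CLASS_LEVELS[idx], levels = .CLASS_LEVELS)
}

#' Build per-cell records from masks and counts
#'
#' Joins a cell mask with its per-cell inclusion counts into the tidy
#' record table used by all summaries. Cells touching the field border are
#' flagged (`border_flag`) and excluded from summaries, since their
#' inclusion complement may be truncated.
#'
#' @param cellMask [LabeledMask-class] of kind `"cell"`.
#' @param counts data.frame from [assignInclusions()] (`cell_label`,
#'   `ib_count`).
#' @param fieldId identifier recorded in the `field_id` column.
#' @return data.frame with columns `field_id`, `cell_label`, `ib_count`,
#'   `class_label`, `area_px`, `border_flag`.
#' @export
cellRecords <- function(cellMask, counts, fieldId = "field1") {
  stopifnot(maskKind(cellMask) == "cell")
  n <- objectCount(cellMask)
  lab <- maskLabels(cellMask)
  area <- tabulate(lab[lab > 0L], n)
  border <- .borderLabels(cellMask)
  cnt <- integer(n)
  cnt[counts$cell_label] <- counts$ib_count
  data.frame(field_id = rep(fieldId, n), cell_label = seq_len(n),
             ib_count = cnt, class_label = classifyCell(cnt),
             area_px = as.integer(area),
             border_flag = seq_len(n) %in% border)
}

#' Summarize a cell population
#'
#' Computes, over non-border cells: the number of cells, the number and
#' fraction bearing at least one inclusion, the Class 1/2/3 shares among
#' IB-bearing cells (the denominator convention of the screen's class
#' percentages), and the mean and SD of the inclusion count over
#' IB-bearing cells. Class shares sum to 1 whenever any IB-bearing cell is
#' present.
#'
#' @param records data.frame of cell records (see [cellRecords()]); only
#'   columns `ib_count` and (optionally) `border_flag` are used.
#' @return one-row data.frame: `n_cells`, `n_ib_bearing`,
#'   `fraction_with_ibs`, `class1_share`, `class2_share`, `class3_share`,
#'   `mean_count`, `sd_count`.
#' @examples
#' summarizePopulation(data.frame(ib_count = c(1, 2, 3)))
#' @export
summarizePopulation <- function(records) {
  if (!is.null(records$border_flag))
    records <- records[!records$border_flag, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no non-border cell records to summarize")
  .summarizeCountVector(as.integer(records$ib_count))
}

#' Summarize a time course of cell populations
#'
#' One population summary per time point, ordered by time.
#'
#' @param records list of per-time-point cell-record data.frames.
#' @param timeLabels numeric time labels (hours), one per point, unique.
#' @return data.frame with `time_label` plus the [summarizePopulation()]
#'   columns, one row per point, sorted by time.
#' @export
summarizeTimecourse <- function(records, timeLabels) {
  if (length(records) < 2L) stop("a time course needs at least 2 points")
  if (length(timeLabels) != length(records))
    stop("one time label per point required")
  if (anyDuplicated(timeLabels)) stop("duplicate time labels")
  ord <- order(timeLabels)
  out <- do.call(rbind, lapply(records[ord], summarizePopulation))
  cbind(time_label = timeLabels[ord], out)
}

#' Compare two cohorts of cell records
#'
#' Pairs the population summaries of two cohorts (e.g. young vs old
#' cells), reports the differences in prevalence and in mean inclusion
#' count, and tests both differences with the pooled-variance Student's
#' t-test. The replicate unit is the per-field summary by default (each
#' field is one biological replicate); per-cell testing of the count is
#' available with `unit = "cell"`.
#'
#' @param a,b cell-record data.frames (see [cellRecords()]).
#' @param unit `"field"` (t-test across per-field summaries) or `"cell"`
#'   (t-test across per-cell counts of IB-bearing cells).
#' @return list with `summary` (two-row data.frame, one per cohort),
#'   `delta_fraction_with_ibs`, `delta_mean_count` (b minus a), and
#'   `tests` (data.frame: metric, t, df, p).
#' @export
compareCohorts <- function(a, b, unit = c("field", "cell")) {
  unit <- match.arg(unit)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both cohorts must be non-empty")
  sa <- summarizePopulation(a); sb <- summarizePopulation(b)
  summary <- cbind(cohort = c("a", "b"), rbind(sa, sb))
  tests <- NULL
  if (unit == "field") {
    perField <- function(rec) {
      keep <- if (is.null(rec$border_flag)) rec else rec[!rec$border_flag, ]
      split(keep, keep$field_id)
    }
    fa <- lapply(perField(a), summarizePopulation)
    fb <- lapply(perField(b), summarizePopulation)
    pull <- function(l, col) vapply(l, function(s) s[[col]], numeric(1))
    tests <- rbind(
      .testRow("fraction_with_ibs", pull(fb, "fraction_with_ibs"),
               pull(fa, "fraction_with_ibs")),
      .testRow("mean_count", pull(fb, "mean_count"), pull(fa, "mean_count")))
  } else {
    ca <- a$ib_count[a$ib_count > 0]; cb <- b$ib_count[b$ib_count > 0]
    tests <- .testRow("mean_count", cb, ca)
  }
  list(summary = summary,
       delta_fraction_with_ibs = sb$fraction_with_ibs - sa$fraction_with_ibs,
       delta_mean_count = sb$mean_count - sa$mean_count,
       tests = tests)
}

.testRow <- function(metric, x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(data.frame(metric = metric, t = NA_real_, df = NA_real_,
                      p = NA_real_))
  tt <- studentTTest(x, y)
  data.frame(metric = metric, t = tt$t, df = tt$df, p = tt$p)
}
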