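## Intensity-based segmentation of cells and inclusion bodies, and the
## mask combination that yields per-cell inclusion counts.

## Otsu threshold on log-intensity, computed on the [0, 1]-normalized log
## image so the split is invariant to positive rescaling of the input.
.otsuLogThreshold <- function(image) {
  lo <- min(image)
  lg <- log1p(image - lo)
  rng <- range(lg)
  if (diff(rng) == 0) return(Inf)
  norm <- (lg - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
  ## back to intensity units
  expm1(th * diff(rng) + rng[1]) + lo
}

.relabelConsecutive <- function(lab) {
  storage.mode(lab) <- "integer"
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Segment cells from a preprocessed intensity image
#'
#' Threshold (Otsu on log-intensity) -> hole filling -> distance-transform
#' watershed to split touching cells -> area filter. A bimodality guard
#' returns an empty mask when foreground and background are not separated
#' by at least two pooled standard deviations (a background-only field has
#' no cells, not a spurious half-of-the-noise mask). Thresholds are
#' data-derived, so the mask is invariant to positive intensity scaling.
#'
#' @param image preprocessed (shading-corrected) 2-D grid.
#' @param minAreaPx,maxAreaPx retained object area range (px).
#' @param watershedTolerance minimum distance-map depth (px) separating
#'   two objects split by the watershed.
#' @return a [LabeledMask-class] of kind `"cell"`.
#' @export
segmentCells <- function(image, minAreaPx = 200, maxAreaPx = 5000,
                         watershedTolerance = 1) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  if (length(image) == 0L || diff(range(image)) == 0)
    return(labeledMask(matrix(0L, nrow(image), ncol(image)), "cell"))
  ## Otsu assumes a sizeable foreground class; on sparse fields it drifts
  ## into the background mode, so a robust background floor backs it up.
  ## Both statistics are data-derived, preserving scale invariance.
  th <- max(.otsuLogThreshold(image),
            stats::median(image) + 3 * stats::mad(image))
  fg <- image > th
  ## bimodality guard
  if (!any(fg) || all(fg))
    return(labeledMask(matrix(0L, nrow(image), ncol(image)), "cell"))
  sep <- mean(image[fg]) - mean(image[!fg])
  pooled <- sqrt((stats::var(image[fg]) + stats::var(image[!fg])) / 2)
  if (!is.na(pooled) && pooled > 0 && sep < 2 * pooled)
    return(labeledMask(matrix(0L, nrow(image), ncol(image)), "cell"))
  fg <- EBImage::fillHull(fg)
  dm <- EBImage::distmap(fg)
  lab <- EBImage::watershed(dm, tolerance = watershedTolerance, ext = 1L)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minAreaPx & areas <= maxAreaPx)
  lab[!(lab %in% keep)] <- 0L
  labeledMask(lab, "cell")
}

#' Segment inclusion bodies within segmented cells
#'
#' Candidate pixels exceed a robust per-cell threshold (per-cell median
#' plus `intensityK` times the per-cell MAD of the supplied image),
#' restricted to cell foreground. Connected candidates are labeled, small
#' regions dropped, and merged spots split by an intensity watershed whose
#' tolerance is a fraction of the candidate dynamic range (so the mask is
#' intensity-scale equivariant).
#'
#' @param image preprocessed grid; the pipeline passes the shading-
#'   corrected, background-subtracted channel.
#' @param cellMask [LabeledMask-class] of kind `"cell"` from the same field.
#' @param minAreaPx minimum inclusion area (px).
#' @param intensityK robust threshold multiplier (default 6 MADs).
#' @param splitTolerance watershed tolerance as a fraction of the
#'   candidate intensity range.
#' @param boundaryRimPx width of the rim just inside each cell boundary
#'   excluded from candidates: the top-hat background estimate is biased
#'   low on the ragged cell edge, leaving small bright residuals there
#'   that are edge artifacts, not inclusions.
#' @return a [LabeledMask-class] of kind `"inclusion"`.
#' @export
segmentInclusions <- function(image, cellMask, minAreaPx = 4,
                              intensityK = 6, splitTolerance = 0.2,
                              boundaryRimPx = 2) {
  lab <- maskLabels(cellMask)
  if (!all(dim(image) == dim(lab)))
    stop("image and cell mask shapes differ")
  if (maskKind(cellMask) != "cell") stop("cellMask must be of kind 'cell'")
  n <- objectCount(cellMask)
  empty <- labeledMask(matrix(0L, nrow(image), ncol(image)), "inclusion")
  if (n == 0L) return(empty)
  inCell <- lab > 0L
  if (boundaryRimPx > 0) {
    interior <- EBImage::erode(
      matrix(as.numeric(inCell), nrow(lab), ncol(lab)),
      EBImage::makeBrush(2L * as.integer(ceiling(boundaryRimPx)) + 1L,
                         "disc")) > 0
    inCell <- inCell & interior
    if (!any(inCell)) return(empty)
  }
  vals <- split(image[inCell], lab[inCell])
  med <- vapply(vals, stats::median, numeric(1))
  madv <- vapply(vals, stats::mad, numeric(1))
  thr <- med + intensityK * madv
  ## cells densely covered by spots inflate their own median/MAD past the
  ## spot peak; the pooled field-level robust threshold caps them
  fieldThr <- stats::median(image[inCell]) +
    intensityK * stats::mad(image[inCell])
  thr <- pmin(thr, fieldThr)
  cand <- matrix(FALSE, nrow(image), ncol(image))
  cand[inCell] <- image[inCell] > thr[lab[inCell]]
  if (!any(cand)) return(empty)
  comp <- EBImage::bwlabel(cand)
  areas <- tabulate(comp[comp > 0L])
  comp[!(comp %in% which(areas >= minAreaPx))] <- 0L
  if (!any(comp > 0L)) return(empty)
  ## split merged spots: watershed on masked intensity, normalized
  mask <- comp > 0L
  rng <- range(image[mask])
  topo <- matrix(0, nrow(image), ncol(image))
  if (diff(rng) > 0) {
    topo[mask] <- (image[mask] - rng[1]) / diff(rng) + 0.05
  } else topo[mask] <- 1
  ws <- EBImage::watershed(topo, tolerance = splitTolerance, ext = 1L)
  ws <- matrix(as.integer(ws), nrow(image), ncol(image))
  areas <- tabulate(ws[ws > 0L])
  ws[!(ws %in% which(areas >= minAreaPx))] <- 0L
  labeledMask(ws, "inclusion")
}

#' Combine cell and inclusion masks into ownership and per-cell counts
#'
#' Each inclusion is assigned to the cell label covering the plurality of
#' its pixels; ties between cells break to the smaller label, and an
#' inclusion whose pixels lie mostly on background gets owner 0 and is
#' excluded from counts (extracellular debris must not enter "IBs per
#' cell"). Assignment never creates or destroys inclusion labels.
#'
#' @param cellMask [LabeledMask-class] of kind `"cell"`.
#' @param ibMask [LabeledMask-class] of kind `"inclusion"`.
#' @param image optional intensity grid used for `mean_intensity`.
#' @return list with `inclusions` (one row per inclusion label:
#'   `ib_label`, `owner`, `area_px`, `centroid_row`, `centroid_col`,
#'   `mean_intensity`) and `counts` (one row per cell label: `cell_label`,
#'   `ib_count`).
#' @export
assignInclusions <- function(cellMask, ibMask, image = NULL) {
  if (maskKind(cellMask) != "cell" || maskKind(ibMask) != "inclusion")
    stop("assignInclusions needs one cell mask and one inclusion mask")
  clab <- maskLabels(cellMask); ilab <- maskLabels(ibMask)
  if (!all(dim(clab) == dim(ilab))) stop("mask shapes differ")
  nCells <- objectCount(cellMask); nIB <- objectCount(ibMask)
  counts <- data.frame(cell_label = seq_len(nCells),
                       ib_count = integer(nCells))
  inc <- data.frame(ib_label = integer(0), owner = integer(0),
                    area_px = integer(0), centroid_row = numeric(0),
                    centroid_col = numeric(0), mean_intensity = numeric(0))
  if (nIB == 0L) return(list(inclusions = inc, counts = counts))
  pos <- which(ilab > 0L)
  ib <- ilab[pos]
  under <- clab[pos]
  rows <- (pos - 1L) %% nrow(ilab) + 1L
  cols <- (pos - 1L) %/% nrow(ilab) + 1L
  owner <- integer(nIB)
  for (k in seq_len(nIB)) {
    sel <- ib == k
    tab <- table(under[sel])
    mx <- max(tab)
    top <- as.integer(names(tab)[tab == mx])
    nz <- top[top > 0L]
    owner[k] <- if (length(nz)) min(nz) else 0L
    ## strictly-majority background stays background
    if (0L %in% top && length(nz) && tab[["0"]] > max(tab[as.character(nz)]))
      owner[k] <- 0L
  }
  area <- tabulate(ib, nIB)
  cr <- as.numeric(rowsum(rows, ib)) / area
  cc <- as.numeric(rowsum(cols, ib)) / area
  mi <- if (is.null(image)) rep(NA_real_, nIB)
        else as.numeric(rowsum(image[pos], ib)) / area
  inc <- data.frame(ib_label = seq_len(nIB), owner = owner,
                    area_px = as.integer(area), centroid_row = cr,
                    centroid_col = cc, mean_intensity = mi)
  owned <- owner[owner > 0L]
  if (length(owned))
    counts$ib_count <- tabulate(owned, nCells)
  list(inclusions = inc, counts = counts)
}

## Region table (label, centroid, area, perimeter, mean intensity) for a
## labeled mask. Perimeter = number of region pixels with a 4-neighbour
## outside the region (image border counts as outside).
.regionTable <- function(mask, image = NULL) {
  lab <- maskLabels(mask)
  n <- objectCount(mask)
  if (n == 0L)
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      perimeter_px = integer(0), mean_intensity = numeric(0)))
  pos <- which(lab > 0L)
  l <- lab[pos]
  rows <- (pos - 1L) %% nrow(lab) + 1L
  cols <- (pos - 1L) %/% nrow(lab) + 1L
  area <- tabulate(l, n)
  cr <- as.numeric(rowsum(rows, l)) / area
  cc <- as.numeric(rowsum(cols, l)) / area
  perim <- tabulate(l[.boundarySelector(lab)[pos]], n)
  mi <- if (is.null(image)) rep(NA_real_, n)
        else as.numeric(rowsum(image[pos], l)) / area
  data.frame(label = seq_len(n), centroid_row = cr, centroid_col = cc,
             area_px = as.integer(area), perimeter_px = as.integer(perim),
             mean_intensity = mi)
}

## Logical matrix: TRUE where a labeled pixel has a 4-neighbour with a
## different label (or sits on the image border).
.boundarySelector <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  out <- matrix(FALSE, h, w)
  if (h == 0L || w == 0L) return(out)
  differs <- function(a, b) a != b
  out[1, ] <- TRUE; out[h, ] <- TRUE
  out[, 1] <- TRUE; out[, w] <- TRUE
  if (h > 1L) {
    d <- differs(lab[-1, , drop = FALSE], lab[-h, , drop = FALSE])
    out[-1, ] <- out[-1, , drop = FALSE] | d
    out[-h, ] <- out[-h, , drop = FALSE] | d
  }
  if (w > 1L) {
    d <- differs(lab[, -1, drop = FALSE], lab[, -w, drop = FALSE])
    out[, -1] <- out[, -1, drop = FALSE] | d
    out[, -w] <- out[, -w, drop = FALSE] | d
  }
  out & (lab > 0L)
}

## Cells whose mask touches the field border (their inclusion complement
## may be truncated; dropped before counting).
.borderLabels <- function(mask) {
  lab <- maskLabels(mask)
  sort(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])))
}
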