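## Illumination shading correction and background subtraction — the
## preprocessing applied to every channel before any thresholding.

## Block-mean reduction by integer factor f (partial edge blocks allowed).
.blockReduce <- function(m, f) {
  if (f <= 1L) return(m)
  ri <- (seq_len(nrow(m)) - 1L) %/% f
  ci <- (seq_len(ncol(m)) - 1L) %/% f
  sums <- rowsum(t(rowsum(m, ri)), ci)
  cnt <- outer(tabulate(ci + 1L), tabulate(ri + 1L))
  t(sums / cnt)
}

## Robust block reduction: per-block lower quantile. Bright objects (cells,
## spots) are upper-tail outliers of each block, so a low quantile tracks
## the illumination-modulated background level.
.blockQuantile <- function(m, f, prob = 0.25) {
  if (f <= 1L) return(m)
  ri <- (seq_len(nrow(m)) - 1L) %/% f
  ci <- (seq_len(ncol(m)) - 1L) %/% f
  nbr <- max(ri) + 1L; nbc <- max(ci) + 1L
  id <- outer(ri, ci * nbr, `+`) + 1L
  q <- vapply(split(as.vector(m), as.vector(id)),
              stats::quantile, numeric(1), probs = prob, names = FALSE)
  matrix(q[order(as.integer(names(q)))], nbr, nbc)
}

## Separable local-quadratic (Savitzky-Golay) smoothing. A local
## polynomial fit is exact for low-order polynomial surfaces — the typical
## form of illumination falloff — including at the field borders, where a
## truncated convolution kernel would bias the estimate.
.smoothSurface <- function(m, halfWindow) {
  smooth1 <- function(x) {
    n <- length(x)
    w <- min(2L * max(1L, as.integer(halfWindow)) + 1L,
             if (n %% 2L == 1L) n else n - 1L)
    if (w < 5L) return(x)
    signal::sgolayfilt(x, p = 2, n = w)
  }
  m2 <- apply(m, 2L, smooth1)
  t(apply(t(m2), 2L, smooth1))
}

## Bilinear upsampling from block centres to full resolution.
.upsampleBilinear <- function(m, nrow, ncol, f) {
  centers <- function(nBlocks, f, n) pmin((seq_len(nBlocks) - 0.5) * f, n)
  rc <- centers(base::nrow(m), f, nrow)
  cc <- centers(base::ncol(m), f, ncol)
  interpIdx <- function(knots, pts) {
    j <- findInterval(pts, knots, all.inside = TRUE)
    w <- (pts - knots[j]) / (knots[j + 1L] - knots[j])
    list(j = j, w = pmin(pmax(w, 0), 1))
  }
  ri <- interpIdx(rc, seq_len(nrow))
  ci <- interpIdx(cc, seq_len(ncol))
  a <- m[ri$j, ci$j, drop = FALSE]
  b <- m[ri$j + 1L, ci$j, drop = FALSE]
  cx <- m[ri$j, ci$j + 1L, drop = FALSE]
  d <- m[ri$j + 1L, ci$j + 1L, drop = FALSE]
  wr <- matrix(ri$w, nrow, ncol)
  wc <- matrix(ci$w, nrow, ncol, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) +
    cx * (1 - wr) * wc + d * wr * wc
}

#' Estimate a multiplicative shading (flat-field) surface from one image
#'
#' Retrospective single-image flat-fielding: the background level is
#' estimated per block as a lower quantile (bright cells and spots are
#' upper-tail outliers within a block), the coarse grid is smoothed by a
#' separable local-quadratic fit, upsampled bilinearly, and normalized to
#' mean 1. The quantile step makes the estimate robust to foreground
#' objects; the local polynomial fit is unbiased at the field borders,
#' where convolution kernels are truncated.
#'
#' @param image 2-D numeric grid, non-negative, not all zero.
#' @param smoothingScalePx smoothing scale in pixels; must be well above
#'   the object scale (validated as at least `4 * cellRadiusPx` when the
#'   cell radius is supplied).
#' @param cellRadiusPx optional known cell radius used to validate the
#'   smoothing scale.
#' @return a [ShadingModel-class]: strictly positive surface, mean 1.
#' @examples
#' img <- matrix(100, 64, 64)
#' shadingSurface(estimateShading(img, 16))[1, 1]   # uniform image -> 1
#' @export
estimateShading <- function(image, smoothingScalePx = 64,
                            cellRadiusPx = NULL) {
  if (!is.matrix(image) || any(!is.finite(image)))
    stop("image must be a finite numeric matrix")
  if (all(image == 0)) stop("shading undefined for an all-zero image")
  if (smoothingScalePx <= 0) stop("smoothingScalePx must be positive")
  if (!is.null(cellRadiusPx) && smoothingScalePx < 4 * cellRadiusPx)
    stop("smoothingScalePx must be at least 4 x the cell radius (",
         4 * cellRadiusPx, " px)")
  ## blocks at half the smoothing scale: big enough that objects are
  ## within-block outliers, small enough to track the falloff
  f <- max(2L, as.integer(floor(smoothingScalePx / 2)))
  coarse <- .blockQuantile(image, f, prob = 0.25)
  sm <- .smoothSurface(coarse, ceiling(smoothingScalePx / f))
  surface <- .upsampleBilinear(sm, nrow(image), ncol(image), f)
  surface <- surface / mean(surface)
  if (any(surface <= 0))
    stop("estimated shading surface is not strictly positive")
  new("ShadingModel", surface = surface)
}

#' Apply shading correction
#'
#' Divides the image elementwise by the model surface. Because the surface
#' has mean 1, the overall intensity scale is preserved.
#'
#' @param image 2-D numeric grid.
#' @param model a [ShadingModel-class] of matching shape.
#' @return corrected 2-D grid (non-negative when the input is).
#' @export
correctShading <- function(image, model) {
  s <- shadingSurface(model)
  if (!all(dim(image) == dim(s)))
    stop("image and shading model shapes differ")
  image / s
}

#' Subtract background by grayscale morphological opening
#'
#' The background estimate is the grayscale opening of the image with a
#' disk structuring element; subtracting it (a white top-hat) removes any
#' structure broader than the disk — the flat background pedestal and, at
#' the default radius, the cytoplasmic plateau of each cell — while
#' preserving spots smaller than the disk. Output is clipped at 0.
#'
#' @param image 2-D numeric grid.
#' @param radiusPx disk radius in pixels; must be positive and should
#'   exceed the largest inclusion radius so spots survive subtraction.
#'   Default in the pipeline is 3x the mean inclusion radius.
#' @return background-subtracted grid, non-negative.
#' @examples
#' subtractBackground(matrix(5, 16, 16), 3)[1, 1]  # constant -> 0
#' @export
subtractBackground <- function(image, radiusPx) {
  if (radiusPx <= 0) stop("radiusPx must be positive")
  if (!is.matrix(image) || any(!is.finite(image)))
    stop("image must be a finite numeric matrix")
  hi <- max(image)
  if (hi == 0) return(image * 0)
  ## EBImage grayscale morphology operates on [0, 1] ranges
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radiusPx)) + 1L,
                              shape = "disc")
  bg <- EBImage::opening(image / hi, brush) * hi
  pmax(image - bg, 0)
}

#' Preprocess all channels of a field
#'
#' Applies, in order, shading correction (surface estimated per channel
#' from the channel itself) and top-hat background subtraction. The
#' shading-corrected field is returned alongside the background-subtracted
#' one because the two downstream masks consume different stages: the cell
#' mask needs the cytoplasmic pedestal that the spot-scale top-hat
#' removes, while inclusion detection works on the top-hat image.
#'
#' @param field an [ImageField-class].
#' @param smoothingScalePx shading smoothing scale (px).
#' @param backgroundRadiusPx top-hat disk radius (px).
#' @return list with `corrected` (shading-corrected [ImageField-class])
#'   and `spots` (shading-corrected then background-subtracted field).
#' @export
preprocessField <- function(field, smoothingScalePx = 64,
                            backgroundRadiusPx = 7) {
  corrected <- lapply(field@channels, function(ch)
    correctShading(ch, estimateShading(ch, smoothingScalePx)))
  spots <- lapply(corrected, subtractBackground, radiusPx = backgroundRadiusPx)
  list(corrected = imageField(corrected, field@pixelSizeUm,
                              paste0(field@provenance, "|shading-corrected")),
       spots = imageField(spots, field@pixelSizeUm,
                          paste0(field@provenance, "|background-subtracted")))
}
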