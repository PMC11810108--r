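# Small fixtures shared across test files; everything is generated in
# code at test time.

# compact field: quick to generate and analyze, same statistics otherwise
smallSpec <- function(nCells = 12L, seed = 1L, ...) {
  fieldSpec(width = 320L, height = 320L, nCells = nCells, seed = seed, ...)
}

# noise-free, unshaded spec for geometric tests
cleanSpec <- function(nCells = 6L, seed = 1L, ...) {
  smallSpec(nCells = nCells, seed = seed, shadingAmplitude = 0,
            noiseSD = 0, ...)
}

# match planted cells to measured cells by nearest centroid; returns
# data.frame of planted count vs measured count for confidently matched
# cells (centroid within 3 px)
matchCounts <- function(truth, result) {
  tc <- groundTruthCells(truth)
  rt <- ibscreen:::.regionTable(result$cellMask)
  if (nrow(rt) == 0L || nrow(tc) == 0L)
    return(data.frame(planted = integer(0), measured = integer(0)))
  d2 <- outer(tc$center_row, rt$centroid_row, `-`)^2 +
    outer(tc$center_col, rt$centroid_col, `-`)^2
  idx <- apply(d2, 1L, which.min)
  ok <- sqrt(d2[cbind(seq_len(nrow(tc)), idx)]) < 3
  data.frame(planted = tc$planted_count[ok],
             measured = result$cells$ib_count[rt$label[idx[ok]]])
}

# render a bare synthetic image: flat pedestal plus Gaussian spots
spotImage <- function(nrow, ncol, pedestal, centers, amp, sigma) {
  img <- matrix(pedestal, nrow, ncol)
  for (k in seq_len(nrow(centers))) {
    rr <- outer((seq_len(nrow) - centers[k, 1])^2,
                (seq_len(ncol) - centers[k, 2])^2, `+`)
    img <- img + amp * exp(-rr / (2 * sigma^2))
  }
  img
}

# disk mask helper
diskMask <- function(nrow, ncol, center, radius) {
  outer((seq_len(nrow) - center[1])^2,
        (seq_len(ncol) - center[2])^2, `+`) <= radius^2
}
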