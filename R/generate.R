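## Synthetic two-channel microscopy fields with exact planted ground truth.
##
## Geometry model: cells are non-overlapping ellipses (axis ratio drawn in
## [1.0, 1.4], rejection-sampled placement); inclusions are 2-D Gaussian
## spots (sigma = radius / 2) clipped to the owner cell, with centres kept
## at least one IB diameter apart so planted counts are resolvable.
## Channel 2 renders organelle shells as partial annuli (270-360 degree
## arcs) around a configurable fraction of inclusions. Illumination is a
## separable quadratic bowl (1 at centre, 1 - amplitude at corners),
## multiplicative; noise is additive Gaussian, clipped at 0 and quantized
## to 16 bits.

## Hierarchical seed stream: one global seed, per-field seeds derived by a
## fixed affine map so fields are reproducible independent of generation
## order. Kept below 2^31 (R integers are 32-bit).
.deriveSeed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(k) * 16807) %%
               2147483629) + 1L
}

.shadingBowl <- function(nrow, ncol, amplitude) {
  ur <- if (nrow > 1) (2 * seq_len(nrow) - (nrow + 1)) / (nrow - 1) else 0
  uc <- if (ncol > 1) (2 * seq_len(ncol) - (ncol + 1)) / (ncol - 1) else 0
  1 - amplitude * outer(ur^2, uc^2, `+`) / 2
}

## Rejection-sample non-overlapping ellipse geometry for spec@nCells cells.
.sampleCellGeometry <- function(spec) {
  n <- spec@nCells
  out <- data.frame(cell_id = integer(0), center_row = numeric(0),
                    center_col = numeric(0), axis_a = numeric(0),
                    axis_b = numeric(0), theta = numeric(0),
                    radius_px = numeric(0))
  if (n == 0L) return(out)
  r <- pmax(4, rnorm(n, spec@cellRadiusMean, spec@cellRadiusSD))
  q <- runif(n, 1.0, 1.4)
  a <- r * sqrt(q); b <- r / sqrt(q)
  theta <- runif(n, 0, pi)
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    margin <- a[i] + 2
    if (2 * margin >= spec@height || 2 * margin >= spec@width)
      stop("field too small for cells of radius ", round(a[i], 1), " px")
    placed <- FALSE
    for (try in seq_len(100L)) {
      cr <- runif(1, margin, spec@height - margin)
      cc <- runif(1, margin, spec@width - margin)
      if (i == 1L || all((rows[seq_len(i - 1L)] - cr)^2 +
                           (cols[seq_len(i - 1L)] - cc)^2 >
                           (a[seq_len(i - 1L)] + a[i] + 2)^2)) {
        rows[i] <- cr; cols[i] <- cc; placed <- TRUE; break
      }
    }
    if (!placed) {
      dens <- round(0.4 * spec@height * spec@width /
                      (pi * (spec@cellRadiusMean * 1.2 + 2)^2))
      stop("cell placement failed after 100 retries at cell ", i, " of ", n,
           "; achievable density for this field is roughly ", dens, " cells")
    }
  }
  data.frame(cell_id = seq_len(n), center_row = rows, center_col = cols,
             axis_a = a, axis_b = b, theta = theta, radius_px = r)
}

## Place `count` IB centres inside an ellipse, pairwise separated by at
## least the sum of their radii (about one IB diameter) plus `extraSep`.
## When organelle shells are rendered, extraSep keeps the shell annuli of
## distinct IBs from overlapping, so the planted surrounded/not-surrounded
## dichotomy stays crisp for the encirclement scorer. IBs that cannot be
## placed after 200 retries are dropped; the planted count reflects what
## was actually rendered.
.placeIBsInCell <- function(cell, count, radii, extraSep = 0,
                            nCandidates = 60L) {
  keep <- logical(count)
  px <- numeric(count); py <- numeric(count)
  for (j in seq_len(count)) {
    ma <- cell$axis_a - (radii[j] + 1)
    mb <- cell$axis_b - (radii[j] + 1)
    if (ma <= 0 || mb <= 0) next
    ## best-candidate (farthest-point) sampling: plain rejection jams well
    ## below the geometric capacity at high planted counts
    p <- sqrt(runif(nCandidates)); phi <- runif(nCandidates, 0, 2 * pi)
    ex <- p * cos(phi) * ma; ey <- p * sin(phi) * mb
    rr <- cell$center_row + ex * cos(cell$theta) - ey * sin(cell$theta)
    cc <- cell$center_col + ex * sin(cell$theta) + ey * cos(cell$theta)
    prev <- which(keep[seq_len(j - 1L)])
    if (!length(prev)) {
      px[j] <- rr[1]; py[j] <- cc[1]; keep[j] <- TRUE
    } else {
      margin <- vapply(seq_len(nCandidates), function(k)
        min(sqrt((px[prev] - rr[k])^2 + (py[prev] - cc[k])^2) -
              (radii[prev] + radii[j] + extraSep)), numeric(1))
      best <- which.max(margin)
      if (margin[best] >= 0) {
        px[j] <- rr[best]; py[j] <- cc[best]; keep[j] <- TRUE
      }
    }
  }
  data.frame(center_row = px[keep], center_col = py[keep],
             radius_px = radii[keep])
}

## Deterministic signal rendering (no shading, no noise).
.renderSignal <- function(spec, cells, ibs) {
  h <- spec@height; w <- spec@width
  ch1 <- matrix(spec@backgroundLevel, h, w)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    r0 <- max(1L, floor(cl$center_row - cl$axis_a - 1))
    r1 <- min(h, ceiling(cl$center_row + cl$axis_a + 1))
    c0 <- max(1L, floor(cl$center_col - cl$axis_a - 1))
    c1 <- min(w, ceiling(cl$center_col + cl$axis_a + 1))
    dr <- (r0:r1) - cl$center_row
    dc <- (c0:c1) - cl$center_col
    DR <- matrix(dr, length(dr), length(dc))
    DC <- matrix(dc, length(dr), length(dc), byrow = TRUE)
    u <- (DR * cos(cl$theta) + DC * sin(cl$theta)) / cl$axis_a
    v <- (-DR * sin(cl$theta) + DC * cos(cl$theta)) / cl$axis_b
    inside <- (u^2 + v^2) <= 1
    block <- ch1[r0:r1, c0:c1]
    block[inside] <- block[inside] + spec@cellIntensity
    ch1[r0:r1, c0:c1] <- block
  }
  if (nrow(ibs)) {
    for (j in seq_len(nrow(ibs))) {
      ib <- ibs[j, ]
      cl <- cells[cells$cell_id == ib$cell_id, ]
      sigma <- ib$radius_px / 2
      pr <- max(2L, ceiling(3 * sigma))
      r0 <- max(1L, floor(ib$center_row - pr))
      r1 <- min(h, ceiling(ib$center_row + pr))
      c0 <- max(1L, floor(ib$center_col - pr))
      c1 <- min(w, ceiling(ib$center_col + pr))
      dr <- (r0:r1) - ib$center_row
      dc <- (c0:c1) - ib$center_col
      DR <- matrix(dr, length(dr), length(dc))
      DC <- matrix(dc, length(dr), length(dc), byrow = TRUE)
      g <- spec@ibIntensity * exp(-(DR^2 + DC^2) / (2 * sigma^2))
      ## clip to the owner cell
      ur <- DR + ib$center_row - cl$center_row
      uc <- DC + ib$center_col - cl$center_col
      u <- (ur * cos(cl$theta) + uc * sin(cl$theta)) / cl$axis_a
      v <- (-ur * sin(cl$theta) + uc * cos(cl$theta)) / cl$axis_b
      g[(u^2 + v^2) > 1] <- 0
      ch1[r0:r1, c0:c1] <- ch1[r0:r1, c0:c1] + g
    }
  }
  ch2 <- NULL
  if (spec@shellProbability > 0) {
    ch2 <- matrix(spec@backgroundLevel, h, w)
    shellIBs <- ibs[ibs$shell, , drop = FALSE]
    for (j in seq_len(nrow(shellIBs))) {
      ib <- shellIBs[j, ]
      rin <- ib$radius_px + spec@shellGapPx
      rout <- rin + spec@shellThicknessPx
      r0 <- max(1L, floor(ib$center_row - rout - 1))
      r1 <- min(h, ceiling(ib$center_row + rout + 1))
      c0 <- max(1L, floor(ib$center_col - rout - 1))
      c1 <- min(w, ceiling(ib$center_col + rout + 1))
      dr <- (r0:r1) - ib$center_row
      dc <- (c0:c1) - ib$center_col
      DR <- matrix(dr, length(dr), length(dc))
      DC <- matrix(dc, length(dr), length(dc), byrow = TRUE)
      d <- sqrt(DR^2 + DC^2)
      ang <- (atan2(DC, DR)) %% (2 * pi)
      darc <- (ang - ib$arc_start) %% (2 * pi)
      hit <- d >= rin & d <= rout & darc <= ib$arc_span
      block <- ch2[r0:r1, c0:c1]
      block[hit] <- pmax(block[hit],
                         spec@backgroundLevel + spec@shellIntensity)
      ch2[r0:r1, c0:c1] <- block
    }
  }
  list(aggregate = ch1, organelle = ch2)
}

.finalizeChannel <- function(signal, bowl, noiseSD) {
  x <- signal * bowl
  if (noiseSD > 0)
    x <- x + matrix(rnorm(length(x), 0, noiseSD), nrow(x), ncol(x))
  pmin(round(pmax(x, 0)), 65535)
}

## Planted population summary from a vector of per-cell counts.
.summarizeCountVector <- function(counts) {
  n <- length(counts)
  bearing <- counts[counts > 0L]
  k <- length(bearing)
  data.frame(
    n_cells = n, n_ib_bearing = k,
    fraction_with_ibs = if (n > 0) k / n else NA_real_,
    class1_share = if (k > 0) mean(bearing == 1L) else NA_real_,
    class2_share = if (k > 0) mean(bearing == 2L) else NA_real_,
    class3_share = if (k > 0) mean(bearing >= 3L) else NA_real_,
    mean_count = if (k > 0) mean(bearing) else NA_real_,
    sd_count = if (k > 1) sd(bearing) else NA_real_
  )
}

#' Generate one synthetic field with planted ground truth
#'
#' Renders one two-channel field per the generative model of the package
#' (see the methods vignette): non-overlapping elliptical cells, Gaussian
#' inclusion spots with per-cell counts drawn from `spec@countLaw`,
#' optional organelle shells in channel 2, a multiplicative illumination
#' bowl and additive Gaussian noise, quantized to 16-bit. The same spec
#' (including its seed) regenerates the field bit-for-bit.
#'
#' @param spec a [FieldSpec-class].
#' @return a list with elements `field` ([ImageField-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' fx <- generateField(fieldSpec(width = 256L, height = 256L, nCells = 10L,
#'                               seed = 7L))
#' fx$truth
#' @export
generateField <- function(spec) {
  validObject(spec)
  res <- withr::with_seed(spec@seed, {
    cells <- .sampleCellGeometry(spec)
    counts <- .drawCounts(spec@countLaw, nrow(cells))
    ## with shells on, keep distinct shell annuli from overlapping
    ## (plus a 2 px guard)
    extraSep <- if (spec@shellProbability > 0)
      2 * (spec@shellGapPx + spec@shellThicknessPx) + 2 else 0
    ibrows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      if (counts[i] > 0L) {
        radii <- pmax(1, rnorm(counts[i], spec@ibRadiusMean, spec@ibRadiusSD))
        placed <- .placeIBsInCell(cells[i, ], counts[i], radii, extraSep)
        if (nrow(placed)) placed$cell_id <- cells$cell_id[i]
        ibrows[[i]] <- placed
      }
    }
    ibs <- do.call(rbind, ibrows[!vapply(ibrows, is.null, logical(1))])
    if (is.null(ibs))
      ibs <- data.frame(center_row = numeric(0), center_col = numeric(0),
                        radius_px = numeric(0), cell_id = integer(0))
    ## planted count = what was actually rendered
    placedCounts <- integer(nrow(cells))
    if (nrow(ibs)) {
      tab <- table(factor(ibs$cell_id, levels = cells$cell_id))
      placedCounts <- as.integer(tab)
    }
    nIB <- nrow(ibs)
    ibs$ib_id <- seq_len(nIB)
    ibs$shell <- if (nIB) runif(nIB) < spec@shellProbability else logical(0)
    ibs$arc_start <- if (nIB) runif(nIB, 0, 2 * pi) else numeric(0)
    ibs$arc_span <- if (nIB) runif(nIB, 270, 360) * pi / 180 else numeric(0)
    sig <- .renderSignal(spec, cells, ibs)
    bowl <- .shadingBowl(spec@height, spec@width, spec@shadingAmplitude)
    channels <- list(aggregate = .finalizeChannel(sig$aggregate, bowl,
                                                  spec@noiseSD))
    if (!is.null(sig$organelle))
      channels$organelle <- .finalizeChannel(sig$organelle, bowl,
                                             spec@noiseSD)
    list(cells = cells, ibs = ibs, counts = placedCounts,
         channels = channels)
  })
  cells <- res$cells
  cells$planted_count <- res$counts
  cells$planted_class <- classifyCell(res$counts)
  ibs <- res$ibs[, c("ib_id", "cell_id", "center_row", "center_col",
                     "radius_px", "shell", "arc_start", "arc_span"),
                 drop = FALSE]
  field <- imageField(res$channels,
                      provenance = sprintf("synthetic(seed=%d)", spec@seed))
  truth <- new("GroundTruth", cells = cells, inclusions = ibs,
               summary = .summarizeCountVector(res$counts))
  list(field = field, truth = truth)
}

#' Generate a growth-phase time course of synthetic fields
#'
#' One entry per preset, in the given order (e.g. lag through stationary,
#' emulating sampling every few hours of cultivation), each with
#' `fieldsPerPoint` independently seeded fields.
#'
#' @param presets ordered list of [PhasePreset-class] objects (or preset
#'   names).
#' @param fieldsPerPoint fields generated per time point.
#' @param seed global seed; per-field seeds are derived from it.
#' @param template a [FieldSpec-class] providing all non-count-law
#'   parameters.
#' @return list of points, each a list with `label`, `fields`, `truths`,
#'   and the pooled `planted` summary.
#' @export
generateTimecourse <- function(presets, fieldsPerPoint = 1L, seed = 1L,
                               template = fieldSpec()) {
  if (length(presets) == 0L) stop("at least one preset required")
  presets <- lapply(presets, function(p)
    if (is.character(p)) phasePreset(p) else p)
  out <- vector("list", length(presets))
  for (k in seq_along(presets)) {
    p <- presets[[k]]
    fields <- vector("list", fieldsPerPoint)
    truths <- vector("list", fieldsPerPoint)
    for (f in seq_len(fieldsPerPoint)) {
      sp <- template
      sp@countLaw <- p@countLaw
      sp@seed <- .deriveSeed(seed, k * 1000L + f)
      fx <- generateField(sp)
      fields[[f]] <- fx$field; truths[[f]] <- fx$truth
    }
    counts <- unlist(lapply(truths, function(t) groundTruthCells(t)$planted_count))
    out[[k]] <- list(label = p@name, fields = fields, truths = truths,
                     planted = .summarizeCountVector(as.integer(counts)))
  }
  out
}

#' Generate a young-versus-old synthetic aging cohort
#'
#' Two arms of fields totalling `cellsPerArm` cells each, generated from
#' the `young` and `old` presets (prevalence 27% vs 61% of cells with
#' inclusions; 2.64 vs 4.91 mean inclusions per IB-bearing cell).
#'
#' Replicatively aged yeast cells are substantially enlarged, so the old
#' arm uses a larger cell radius by default (`oldCellRadiusScale`); this
#' also gives the crowded old cells the geometric room to carry their full
#' planted inclusion load (mean 4.91 per IB-bearing cell) without
#' placement truncation.
#'
#' @param young,old [PhasePreset-class] objects or preset names.
#' @param cellsPerArm total planted cells per arm.
#' @param seed global seed.
#' @param template [FieldSpec-class] for everything but the count law.
#' @param oldCellRadiusScale factor applied to the template cell radius in
#'   the old arm.
#' @return list with `young` and `old` arms (each `fields`, `truths`,
#'   pooled `planted` summary).
#' @export
generateAgingCohort <- function(young = "young", old = "old",
                                cellsPerArm = 500L, seed = 1L,
                                template = fieldSpec(),
                                oldCellRadiusScale = 1.3) {
  arms <- list(young = if (is.character(young)) phasePreset(young) else young,
               old = if (is.character(old)) phasePreset(old) else old)
  oldTemplate <- template
  oldTemplate@cellRadiusMean <- template@cellRadiusMean * oldCellRadiusScale
  oldTemplate@cellRadiusSD <- template@cellRadiusSD * oldCellRadiusScale
  out <- list()
  for (ai in seq_along(arms)) {
    p <- arms[[ai]]
    template <- if (names(arms)[ai] == "old") oldTemplate else template
    remaining <- as.integer(cellsPerArm)
    fields <- list(); truths <- list(); f <- 0L
    while (remaining > 0L) {
      f <- f + 1L
      sp <- template
      sp@countLaw <- p@countLaw
      sp@nCells <- min(sp@nCells, remaining)
      sp@seed <- .deriveSeed(seed, ai * 100000L + f)
      fx <- generateField(sp)
      fields[[f]] <- fx$field; truths[[f]] <- fx$truth
      remaining <- remaining - sp@nCells
    }
    counts <- unlist(lapply(truths, function(t) groundTruthCells(t)$planted_count))
    out[[names(arms)[ai]]] <-
      list(fields = fields, truths = truths,
           planted = .summarizeCountVector(as.integer(counts)))
  }
  out
}

#' Generate a simulated replicate screen table
#'
#' Non-hit mutants are measured around the wild-type baseline, planted hit
#' mutants around baseline + `hitShift`; replicate noise is i.i.d.
#' Gaussian. Percentages falling outside `[0, 100]` are clipped with a
#' warning. The wild-type strain is measured with the same replicate
#' structure.
#'
#' @param spec a [ScreenSpec-class].
#' @return list with `measurements` (long data.frame: `mutant_id`,
#'   `replicate`, `class3_percent`), `wildtype` (numeric replicate vector),
#'   `plantedHits` (character vector of planted hit ids) and `spec`.
#' @examples
#' scr <- generateScreenDataset(screenSpec(nMutants = 100L,
#'                                         nHitsPlanted = 10L, seed = 1L))
#' head(scr$measurements)
#' @export
generateScreenDataset <- function(spec) {
  validObject(spec)
  withr::with_seed(spec@seed, {
    ids <- sprintf("mut%05d", seq_len(spec@nMutants))
    hits <- sort(sample.int(spec@nMutants, spec@nHitsPlanted))
    trueMean <- rep(spec@baselineClass3, spec@nMutants)
    trueMean[hits] <- trueMean[hits] + spec@hitShift
    if (any(trueMean < 0 | trueMean > 100)) {
      warning("planted means clipped to [0, 100]")
      trueMean <- pmin(pmax(trueMean, 0), 100)
    }
    vals <- rnorm(spec@nMutants * spec@nReplicates,
                  mean = rep(trueMean, each = spec@nReplicates),
                  sd = spec@replicateSD)
    if (any(vals < 0 | vals > 100)) {
      warning("replicate percentages clipped to [0, 100]")
      vals <- pmin(pmax(vals, 0), 100)
    }
    wt <- pmin(pmax(rnorm(spec@nReplicates, spec@baselineClass3,
                          spec@replicateSD), 0), 100)
    list(measurements = data.frame(
           mutant_id = rep(ids, each = spec@nReplicates),
           replicate = rep(seq_len(spec@nReplicates), spec@nMutants),
           class3_percent = vals),
         wildtype = wt,
         plantedHits = ids[hits],
         spec = spec)
  })
}
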