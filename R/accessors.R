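#' Construct a FieldSpec
#'
#' Defaults describe the study's standard acquisition: a 1024 x 1024 px
#' field with about 150 well-separated yeast-like cells of mean radius
#' 12 px, bright punctate inclusions of mean radius 2.2 px, a quadratic
#' illumination bowl of amplitude 0.25 and additive Gaussian noise of
#' SD 20 fluorescence units (spot peak SNR about 30). Per-field cell
#' density and magnification are configurable choices, not claims about
#' any particular instrument.
#'
#' @param width,height field size in pixels.
#' @param nCells number of cells to place.
#' @param cellRadiusMean,cellRadiusSD cell radius law (px).
#' @param cellIntensity,ibIntensity,backgroundLevel fluorescence amplitudes
#'   (additive; validity requires `ibIntensity > cellIntensity >
#'   backgroundLevel`).
#' @param ibRadiusMean,ibRadiusSD inclusion radius law (px).
#' @param countLaw per-cell IB-count law, see [countLaw()]; defaults to the
#'   `wildtype` preset law.
#' @param shellProbability fraction of IBs given an organelle shell in
#'   channel 2.
#' @param shellGapPx,shellThicknessPx annulus gap outside the IB boundary
#'   and annulus thickness (px).
#' @param shellIntensity channel-2 shell amplitude.
#' @param shadingAmplitude illumination falloff in `[0, 1)`.
#' @param noiseSD additive Gaussian noise SD.
#' @param seed integer seed.
#' @return a validated [FieldSpec-class] object.
#' @examples
#' spec <- fieldSpec(nCells = 20L, width = 256L, height = 256L, seed = 1L)
#' spec
#' @export
fieldSpec <- function(width = 1024L, height = 1024L, nCells = 150L,
                      cellRadiusMean = 12, cellRadiusSD = 1.5,
                      cellIntensity = 300, ibIntensity = 600,
                      backgroundLevel = 100,
                      ibRadiusMean = 2.2, ibRadiusSD = 0.3,
                      countLaw = phaseCountLaw("wildtype"),
                      shellProbability = 0,
                      shellGapPx = 1, shellThicknessPx = 2,
                      shellIntensity = 500,
                      shadingAmplitude = 0.25, noiseSD = 20,
                      seed = 1L) {
  new("FieldSpec",
      width = as.integer(width), height = as.integer(height),
      nCells = as.integer(nCells),
      cellRadiusMean = cellRadiusMean, cellRadiusSD = cellRadiusSD,
      cellIntensity = cellIntensity, ibIntensity = ibIntensity,
      backgroundLevel = backgroundLevel,
      ibRadiusMean = ibRadiusMean, ibRadiusSD = ibRadiusSD,
      countLaw = countLaw,
      shellProbability = shellProbability, shellGapPx = shellGapPx,
      shellThicknessPx = shellThicknessPx, shellIntensity = shellIntensity,
      shadingAmplitude = shadingAmplitude, noiseSD = noiseSD,
      seed = as.integer(seed))
}

#' Construct an ImageField
#'
#' @param channels named list of numeric matrices (same shape).
#' @param pixelSizeUm optional pixel size in micrometres.
#' @param provenance character scalar describing the source.
#' @return an [ImageField-class].
#' @export
imageField <- function(channels, pixelSizeUm = NULL, provenance = "unknown") {
  new("ImageField", channels = channels, pixelSizeUm = pixelSizeUm,
      provenance = provenance)
}

#' Construct a LabeledMask
#'
#' Relabels the given integer matrix to consecutive labels `1..n`
#' (preserving label order) and tags it with its kind.
#'
#' @param labels integer matrix, 0 = background.
#' @param kind `"cell"` or `"inclusion"`.
#' @return a [LabeledMask-class].
#' @export
labeledMask <- function(labels, kind) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  new("LabeledMask", labels = labels, kind = kind)
}

#' Construct a ScreenSpec
#'
#' Defaults mirror the screen's design: 3 independent replicates, a
#' wild-type baseline of 50% Class-3 cells at the screening time point,
#' hits shifted by +30 percentage points, replicate SD 5 points.
#'
#' @param nMutants number of mutants.
#' @param nHitsPlanted number of planted hit mutants.
#' @param baselineClass3 wild-type Class-3 percentage.
#' @param hitShift planted shift, percentage points.
#' @param replicateSD replicate noise SD, percentage points.
#' @param nReplicates replicates per strain (>= 2).
#' @param seed integer seed.
#' @return a validated [ScreenSpec-class].
#' @export
screenSpec <- function(nMutants = 5500L, nHitsPlanted = 84L,
                       baselineClass3 = 50, hitShift = 30,
                       replicateSD = 5, nReplicates = 3L, seed = 1L) {
  new("ScreenSpec", nMutants = as.integer(nMutants),
      nHitsPlanted = as.integer(nHitsPlanted),
      baselineClass3 = baselineClass3, hitShift = hitShift,
      replicateSD = replicateSD, nReplicates = as.integer(nReplicates),
      seed = as.integer(seed))
}

## ---- generics ----

#' @rdname channelNames
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Channel accessors
#'
#' `channelNames(x)` lists the channel names of an [ImageField-class];
#' `getChannel(x, name)` extracts one channel matrix.
#'
#' @param x an `ImageField`.
#' @param name channel name (or index).
#' @return `channelNames`: character vector; `getChannel`: numeric matrix.
#' @aliases channelNames getChannel
#' @export getChannel
#' @rdname channelNames
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

setMethod("channelNames", "ImageField", function(x) names(x@channels))

setMethod("getChannel", "ImageField", function(x, name) {
  if (is.character(name) && !name %in% names(x@channels))
    stop("no channel named '", name, "'")
  x@channels[[name]]
})

#' @rdname maskLabels
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' Mask accessors
#'
#' `maskLabels` returns the integer label matrix, `maskKind` the object
#' kind, `objectCount` the number of labeled objects.
#'
#' @param x a [LabeledMask-class].
#' @return label matrix / kind string / object count.
#' @aliases maskLabels maskKind objectCount
#' @export maskKind
#' @rdname maskLabels
setGeneric("maskKind", function(x) standardGeneric("maskKind"))

#' @rdname maskLabels
#' @export objectCount
setGeneric("objectCount", function(x) standardGeneric("objectCount"))

setMethod("maskLabels", "LabeledMask", function(x) x@labels)
setMethod("maskKind", "LabeledMask", function(x) x@kind)
setMethod("objectCount", "LabeledMask", function(x) max(0L, x@labels))

#' @rdname groundTruthCells
#' @export
setGeneric("groundTruthCells", function(x) standardGeneric("groundTruthCells"))

#' Ground-truth accessors
#'
#' Planted per-cell and per-inclusion records and the planted population
#' summary of a synthetic field.
#'
#' @param x a [GroundTruth-class].
#' @return data.frame of planted records / one-row summary data.frame.
#' @aliases groundTruthCells groundTruthInclusions plantedSummary
#' @export groundTruthInclusions
#' @rdname groundTruthCells
setGeneric("groundTruthInclusions",
           function(x) standardGeneric("groundTruthInclusions"))

#' @rdname groundTruthCells
#' @export plantedSummary
setGeneric("plantedSummary", function(x) standardGeneric("plantedSummary"))

setMethod("groundTruthCells", "GroundTruth", function(x) x@cells)
setMethod("groundTruthInclusions", "GroundTruth", function(x) x@inclusions)
setMethod("plantedSummary", "GroundTruth", function(x) x@summary)

#' @rdname shadingSurface
#' @export
setGeneric("shadingSurface", function(x) standardGeneric("shadingSurface"))

#' Extract the multiplicative surface of a ShadingModel
#' @param x a [ShadingModel-class].
#' @return numeric matrix, mean 1, strictly positive.
#' @rdname shadingSurface
setMethod("shadingSurface", "ShadingModel", function(x) x@surface)

## ---- show methods ----

setMethod("show", "FieldSpec", function(object) {
  cat(sprintf("FieldSpec: %d x %d px, %d cells (r = %.1f +/- %.1f px)\n",
              object@width, object@height, object@nCells,
              object@cellRadiusMean, object@cellRadiusSD))
  cat(sprintf("  IBs: r = %.1f +/- %.1f px, count law '%s', shells p = %.2f\n",
              object@ibRadiusMean, object@ibRadiusSD,
              object@countLaw$type, object@shellProbability))
  cat(sprintf("  intensities bg/cell/ib = %g/%g/%g, shading %.2f, noise SD %g, seed %d\n",
              object@backgroundLevel, object@cellIntensity,
              object@ibIntensity, object@shadingAmplitude, object@noiseSD,
              object@seed))
})

setMethod("show", "ImageField", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ImageField: %d x %d px, channels: %s\n", d[1], d[2],
              paste(names(object@channels), collapse = ", ")))
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "LabeledMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledMask (%s): %d x %d px, %d objects\n",
              object@kind, d[1], d[2], objectCount(object)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells, %d inclusions planted\n",
              nrow(object@cells), nrow(object@inclusions)))
  if (nrow(object@summary)) {
    s <- object@summary
    cat(sprintf("  planted prevalence %.3f, mean count (IB-bearing) %.2f\n",
                s$fraction_with_ibs, s$mean_count))
  }
})

setMethod("show", "ScreenSpec", function(object) {
  cat(sprintf(
    "ScreenSpec: %d mutants (%d planted hits, +%g pts), baseline %g%%, SD %g, %d reps, seed %d\n",
    object@nMutants, object@nHitsPlanted, object@hitShift,
    object@baselineClass3, object@replicateSD, object@nReplicates,
    object@seed))
})

setMethod("show", "PhasePreset", function(object) {
  law <- object@countLaw
  cat(sprintf("PhasePreset '%s': %s law, prevalence %.2f\n",
              object@name, law$type, law$prevalence))
  sh <- plantedClassShares(law)
  cat(sprintf("  planted class shares (IB-bearing): C1 %.3f, C2 %.3f, C3 %.3f; mean count %.2f\n",
              sh["class1"], sh["class2"], sh["class3"],
              plantedMeanCount(law)))
})

setMethod("show", "ShadingModel", function(object) {
  d <- dim(object@surface)
  cat(sprintf("ShadingModel: %d x %d px surface, range [%.3f, %.3f], mean 1\n",
              d[1], d[2], min(object@surface), max(object@surface)))
})
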