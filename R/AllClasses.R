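#' @import methods
#' @importFrom stats median mad rnorm runif var sd pt rnbinom rpois qnorm dpois pnorm setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion head
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' FieldSpec: generative parameters for one synthetic microscopy field
#'
#' A `FieldSpec` captures everything needed to render one two-channel
#' fluorescence field of yeast-like cells carrying punctate inclusion bodies
#' (IBs): field geometry, cell and spot sizes, fluorescence levels,
#' the per-cell IB-count law, organelle-shell parameters for channel 2,
#' illumination shading and noise, and the seed.
#'
#' Intensities are additive amplitudes in arbitrary fluorescence units:
#' a cytoplasm pixel sits at `backgroundLevel + cellIntensity`, an inclusion
#' peak at roughly `backgroundLevel + cellIntensity + ibIntensity`. The
#' planted contrast ordering `ibIntensity > cellIntensity > backgroundLevel`
#' is enforced by the validity method.
#'
#' @slot width,height field size in pixels.
#' @slot nCells number of cells to place (non-negative).
#' @slot cellRadiusMean,cellRadiusSD cell equivalent-radius law (pixels).
#' @slot cellIntensity,ibIntensity,backgroundLevel fluorescence amplitudes.
#' @slot ibRadiusMean,ibRadiusSD inclusion radius law (pixels).
#' @slot countLaw named list describing the per-cell IB-count law; see
#'   [countLaw()].
#' @slot shellProbability fraction of IBs rendered with an organelle shell
#'   in channel 2.
#' @slot shellGapPx,shellThicknessPx shell annulus geometry (pixels).
#' @slot shellIntensity channel-2 shell amplitude.
#' @slot shadingAmplitude multiplicative illumination falloff: the shading
#'   surface is 1 at the field centre and `1 - shadingAmplitude` at the
#'   corners. Must lie in `[0, 1)`.
#' @slot noiseSD additive Gaussian noise, fluorescence units.
#' @slot seed integer seed for the field's private random stream.
#'
#' @seealso [fieldSpec()], [generateField()], [phasePreset()]
#' @exportClass FieldSpec
setClass("FieldSpec",
  representation(
    width = "integer", height = "integer", nCells = "integer",
    cellRadiusMean = "numeric", cellRadiusSD = "numeric",
    cellIntensity = "numeric", ibIntensity = "numeric",
    backgroundLevel = "numeric",
    ibRadiusMean = "numeric", ibRadiusSD = "numeric",
    countLaw = "list",
    shellProbability = "numeric", shellGapPx = "numeric",
    shellThicknessPx = "numeric", shellIntensity = "numeric",
    shadingAmplitude = "numeric", noiseSD = "numeric",
    seed = "integer"
  )
)

setValidity("FieldSpec", function(object) {
  msg <- character()
  num <- c(
    width = object@width, height = object@height, nCells = object@nCells,
    cellRadiusMean = object@cellRadiusMean, cellRadiusSD = object@cellRadiusSD,
    cellIntensity = object@cellIntensity, ibIntensity = object@ibIntensity,
    backgroundLevel = object@backgroundLevel,
    ibRadiusMean = object@ibRadiusMean, ibRadiusSD = object@ibRadiusSD,
    shellProbability = object@shellProbability,
    shellGapPx = object@shellGapPx,
    shellThicknessPx = object@shellThicknessPx,
    shellIntensity = object@shellIntensity,
    shadingAmplitude = object@shadingAmplitude, noiseSD = object@noiseSD
  )
  if (any(!is.finite(num)))
    return(paste("non-finite spec fields:",
                 paste(names(num)[!is.finite(num)], collapse = ", ")))
  if (any(num < 0))
    msg <- c(msg, paste("negative spec fields:",
                        paste(names(num)[num < 0], collapse = ", ")))
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be positive")
  if (object@cellRadiusMean <= 0 || object@ibRadiusMean <= 0)
    msg <- c(msg, "cellRadiusMean and ibRadiusMean must be positive")
  if (object@shellProbability > 1)
    msg <- c(msg, "shellProbability must lie in [0, 1]")
  if (object@shadingAmplitude >= 1)
    msg <- c(msg, "shadingAmplitude must lie in [0, 1)")
  if (!(object@ibIntensity > object@cellIntensity &&
        object@cellIntensity > object@backgroundLevel))
    msg <- c(msg, "need ibIntensity > cellIntensity > backgroundLevel")
  lawmsg <- .validateCountLaw(object@countLaw)
  if (!is.null(lawmsg)) msg <- c(msg, lawmsg)
  if (length(msg)) msg else TRUE
})

#' ImageField: one multi-channel acquisition site
#'
#' Holds the per-channel 2-D intensity grids of one imaged field. Channels
#' are named numeric matrices sharing one shape; by convention channel
#' `"aggregate"` is the red inclusion-body channel and `"organelle"` the
#' green channel. Intensities are finite and non-negative.
#'
#' @slot channels named list of numeric matrices, identical dimensions.
#' @slot pixelSizeUm optional pixel size in micrometres (`NULL` if unknown).
#' @slot provenance character scalar: source path or generator description.
#'
#' @seealso [imageField()], [channelNames()], [getChannel()]
#' @exportClass ImageField
setClass("ImageField",
  representation(
    channels = "list",
    pixelSizeUm = "numericOrNULL",
    provenance = "character"
  )
)

setValidity("ImageField", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("all channels must be matrices")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims != dims[, 1]))
    return("all channels must share the same dimensions")
  for (m in ch) {
    if (any(!is.finite(m))) return("channel intensities must be finite")
    if (any(m < 0)) return("channel intensities must be non-negative")
  }
  TRUE
})

#' LabeledMask: integer-labeled segmentation of one field
#'
#' An integer matrix in which 0 marks background and `k >= 1` the pixels of
#' object `k`, together with the object kind (`"cell"` or `"inclusion"`).
#' Labels are consecutive `1..n`.
#'
#' @slot labels integer matrix of object labels (0 = background).
#' @slot kind `"cell"` or `"inclusion"`.
#'
#' @seealso [labeledMask()], [segmentCells()], [segmentInclusions()]
#' @exportClass LabeledMask
setClass("LabeledMask",
  representation(labels = "matrix", kind = "character")
)

setValidity("LabeledMask", function(object) {
  if (!object@kind %in% c("cell", "inclusion"))
    return("kind must be 'cell' or 'inclusion'")
  lab <- object@labels
  if (any(!is.finite(lab)) || any(lab < 0) || any(lab != floor(lab)))
    return("labels must be non-negative integers")
  u <- sort(unique(as.vector(lab[lab > 0])))
  if (length(u) && !identical(as.integer(u), seq_len(length(u))))
    return("labels must be consecutive 1..n")
  TRUE
})

#' GroundTruth: exact planted geometry and counts of a synthetic field
#'
#' Produced alongside every generated field: per-cell records (centre,
#' axes, planted IB count, planted class), per-IB records (owner cell,
#' centre, radius, shell flag), and the field-level planted summary.
#' The planted class is the classification rule applied to the planted
#' count, and the planted summary equals the aggregation of the per-cell
#' records, so the object is a fair oracle for recovery tests.
#'
#' @slot cells data.frame with columns `cell_id`, `center_row`, `center_col`,
#'   `axis_a`, `axis_b`, `theta`, `radius_px`, `planted_count`,
#'   `planted_class`.
#' @slot inclusions data.frame with columns `ib_id`, `cell_id`,
#'   `center_row`, `center_col`, `radius_px`, `shell`, `arc_start`,
#'   `arc_span`.
#' @slot summary one-row data.frame of planted population statistics (same
#'   columns as [summarizePopulation()]).
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(cells = "data.frame", inclusions = "data.frame",
                 summary = "data.frame")
)

setValidity("GroundTruth", function(object) {
  cl <- object@cells; ib <- object@inclusions
  if (nrow(ib) && !all(ib$cell_id %in% cl$cell_id))
    return("every inclusion must reference an existing cell")
  if (nrow(cl)) {
    expect <- classifyCell(cl$planted_count)
    if (!identical(as.character(cl$planted_class), as.character(expect)))
      return("planted_class must equal the classification rule applied to planted_count")
  }
  TRUE
})

#' ShadingModel: smooth multiplicative illumination surface
#'
#' A strictly positive surface, the same shape as the image it was
#' estimated from, normalized to mean 1. Dividing an image by the surface
#' performs retrospective flat-field (shading) correction.
#'
#' @slot surface numeric matrix, strictly positive, mean 1.
#'
#' @seealso [estimateShading()], [correctShading()]
#' @exportClass ShadingModel
setClass("ShadingModel", representation(surface = "matrix"))

setValidity("ShadingModel", function(object) {
  s <- object@surface
  if (any(!is.finite(s)) || any(s <= 0))
    return("shading surface must be finite and strictly positive")
  if (abs(mean(s) - 1) > 1e-6)
    return("shading surface must have mean 1")
  TRUE
})

#' ScreenSpec: generative parameters for a simulated replicate screen
#'
#' Describes a tabular genome-wide screen: each mutant is measured as a
#' Class-3 percentage in `nReplicates` independent replicates; planted hit
#' mutants are shifted by `hitShift` percentage points from the wild-type
#' baseline, and replicate noise is i.i.d. Gaussian with SD `replicateSD`.
#'
#' @slot nMutants positive integer.
#' @slot nHitsPlanted non-negative integer, at most `nMutants`.
#' @slot baselineClass3 wild-type Class-3 percentage (0-100).
#' @slot hitShift planted shift in percentage points.
#' @slot replicateSD replicate noise SD in percentage points.
#' @slot nReplicates integer >= 2 (the t-test is undefined below that).
#' @slot seed integer seed.
#'
#' @seealso [screenSpec()], [generateScreenDataset()]
#' @exportClass ScreenSpec
setClass("ScreenSpec",
  representation(
    nMutants = "integer", nHitsPlanted = "integer",
    baselineClass3 = "numeric", hitShift = "numeric",
    replicateSD = "numeric", nReplicates = "integer", seed = "integer"
  )
)

setValidity("ScreenSpec", function(object) {
  msg <- character()
  if (object@nMutants < 1L) msg <- c(msg, "nMutants must be positive")
  if (object@nHitsPlanted < 0L || object@nHitsPlanted > object@nMutants)
    msg <- c(msg, "nHitsPlanted must lie in [0, nMutants]")
  if (object@baselineClass3 < 0 || object@baselineClass3 > 100)
    msg <- c(msg, "baselineClass3 must lie in [0, 100]")
  if (object@replicateSD < 0) msg <- c(msg, "replicateSD must be non-negative")
  if (object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2 (t-test undefined otherwise)")
  if (length(msg)) msg else TRUE
})

#' PhasePreset: a named growth-phase or cohort condition
#'
#' Bundles a condition name with its per-cell IB-count law (including the
#' prevalence of IB-bearing cells). Presets encode the study conditions:
#' `lag`, `exponential` and `stationary` the growth-phase time course,
#' `young` and `old` the aging cohorts, and `wildtype`/`mutant` the screen
#' baseline and a strong maturation-defective mutant.
#'
#' @slot name condition name.
#' @slot countLaw per-cell IB count law; see [countLaw()].
#'
#' @seealso [phasePreset()], [plantedClassShares()]
#' @exportClass PhasePreset
setClass("PhasePreset",
  representation(name = "character", countLaw = "list")
)

setValidity("PhasePreset", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty scalar")
  lawmsg <- .validateCountLaw(object@countLaw)
  if (!is.null(lawmsg)) return(lawmsg)
  TRUE
})
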