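---
title: "Quantifying inclusion-body phenotypes in synthetic yeast microscopy fields"
author: "ibscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inclusion-body phenotypes in synthetic yeast microscopy fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibscreen)
```

## The measurement problem

Aggregation-prone proteins such as DsRed-tagged synphilin-1 (SY1) form
bright punctate inclusion bodies (IBs) in yeast. The number of inclusions
per cell is a maturation readout: young, healthy cultures start with many
small aggregates per cell and consolidate them over time into one or two
large deposits. The standard per-cell phenotype code is

* **Class 1** — exactly one inclusion,
* **Class 2** — exactly two inclusions,
* **Class 3** — three or more inclusions,

with cells carrying no inclusion left unclassed (`NO_IB`). Population
summaries follow two denominator conventions, and both are reported:
class shares are fractions *of IB-bearing cells* (the convention under
which a lag-phase culture shows ~96% Class 3), while the prevalence
`fraction_with_ibs` is a fraction of *all counted cells* (the convention
under which ~27% of young and ~61% of replicatively old cells carry
inclusions). In a genome-wide screen the per-condition Class-3 percentage
becomes the test statistic: a mutant is a hit when it differs from wild
type significantly (pooled Student's t-test, p <= 0.05) *and* by at least
20 percentage points.

No raw screen images are publicly deposited, so the package is validated
by planted-parameter recovery: a synthetic-field generator plants the
published population structure with exact ground truth, and the analysis
pipeline must recover it from pixels alone. Everything below documents
the generative model, the analysis operating point, and the places where
a design decision was genuinely open.

## The synthetic-field generator

`generateField()` renders one two-channel 16-bit field from a
`FieldSpec`:

* **Cells** are non-overlapping ellipses (axis ratio uniform in
  [1.0, 1.4], orientation uniform), placed by rejection sampling with at
  most 100 retries per cell; an overcrowded spec fails with the
  achievable density in the message. Defaults: 1024 x 1024 px, 150 cells
  of radius 12 +/- 1.5 px. Neither per-field density nor magnification is
  a published quantity; these are configurable choices.
* **Inclusions** are 2-D Gaussian spots (sigma = radius/2, default radius
  2.2 +/- 0.3 px, amplitude 600 units over a 300-unit cytoplasm on a
  100-unit background) clipped to the owner cell. Centres are kept at
  least one IB diameter apart by best-candidate (farthest-point)
  sampling; plain rejection sampling jams well below the geometric
  capacity, which truncated high planted counts. Spots that still cannot
  be placed are dropped and the ground truth records what was actually
  rendered.
* **Organelle shells** (channel 2) are partial annuli — arc coverage
  drawn uniformly in 270-360 degrees — hugging a Bernoulli-selected
  fraction of inclusions at a 1 px gap, 2 px thick. When shells are
  enabled, inclusion centres are additionally separated so that distinct
  shell annuli can never overlap (plus a 2 px guard): the planted
  surrounded/not-surrounded dichotomy must be crisp, otherwise a
  neighbour's shell sweeps through a non-shelled inclusion's probe zone
  and the planted labels stop being a fair oracle.
* **Illumination and noise.** A separable quadratic bowl (1 at the field
  centre, 1 - amplitude at the corners, default amplitude 0.25)
  multiplies the signal; additive Gaussian noise (SD 20 units, so spot
  peaks sit at SNR ~30) is clipped at zero and quantized to 16 bits.
* **Determinism.** One global seed feeds a fixed affine per-field seed
  map, so any field regenerates bit-for-bit independently of the order in
  which a batch was produced.

### Condition presets

Per-cell IB counts follow a *count law*: a prevalence (probability a cell
bears any inclusion) plus a conditional law on counts >= 1. The presets
plant the published summaries by construction, so the analytic shares and
moments of each law are the recovery oracle:

```{r presets}
phasePreset("lag")         # 4 hr culture: 96% Class 3 among IB-bearing
phasePreset("stationary")  # 48 hr: ~50% Class 1
phasePreset("young")       # prevalence 27%, counts 2.64 +/- 1.29
phasePreset("old")         # prevalence 61%, counts 4.91 +/- 3.32
```

`lag`, `exponential` (the ~50% Class-3 screening baseline at 16-20 hr,
also used as `wildtype`), and `stationary` are categorical laws;
`young`/`old` are shifted negative binomials with moments matched to the
printed mean +/- SD. `generateAgingCohort()` renders the old arm with
1.3x larger cells: replicatively aged yeast are substantially enlarged,
and the larger area is also what gives a crowded old cell the geometric
room to carry its full planted count load without truncation.

What the generator deliberately does **not** emulate: 3-D structure,
photobleaching, camera-specific noise, cell-to-cell brightness
variation, budding morphology, debris, and out-of-focus fields. Passing
recovery tests therefore demonstrate that the pipeline's operators are
correct and unbiased under the stated imaging model — not that they are
robust to every artefact of real microscopy.

## The analysis pipeline

`analyzeField()` chains the stages in a fixed order: shading correction,
background subtraction, cell segmentation, inclusion segmentation, mask
combination, classification, and (with an organelle channel) encirclement
scoring.

**Shading correction.** The multiplicative illumination surface is
estimated from the image itself (retrospective flat-fielding): the
background level of each 32 px block is taken as its lower quartile —
cells and spots are upper-tail outliers within a block — the coarse grid
is smoothed by a separable local-quadratic (Savitzky-Golay) fit,
upsampled bilinearly, and normalized to mean 1. A local polynomial fit is
exact for low-order illumination surfaces *including at field borders*,
where a truncated convolution kernel is biased; this is why the estimator
satisfies near-idempotence (re-correcting a corrected image changes it by
well under 1% RMS). Default smoothing scale: 64 px, at least four cell
radii.

**Background subtraction.** A white top-hat: grayscale opening with a
disk of radius 7 px (~3x the mean inclusion radius) is subtracted and the
result clipped at zero. The disk is larger than any spot but smaller than
a cell, so the top-hat removes both the flat background pedestal and the
cytoplasmic plateau, leaving spots on a near-zero base. Consequently the
*cell* mask is computed from the shading-corrected image (which retains
the cytoplasm pedestal) and the *inclusion* stage consumes the top-hat
image; both preprocessing operations are applied in the stated order.

**Cell segmentation.** Threshold, fill holes, split touching objects by
watershed on the distance transform, filter areas to [200, 5000] px. The
threshold is Otsu on log-intensity backed by a robust floor
(median + 3 MAD): Otsu assumes a sizeable foreground class and drifts
into the background mode on sparse fields. Both statistics are
data-derived, so the mask is invariant to positive rescaling of the
image. A bimodality guard (foreground/background separation of at least
two pooled SDs) keeps background-only fields empty. Cells touching the
field border are flagged and excluded from all summaries, since their
inclusion complement may be truncated.

**Inclusion segmentation.** Candidate pixels exceed a per-cell robust
threshold (median + 6 MAD of the top-hat image over the cell interior),
restricted to cell foreground minus a 2 px boundary rim — the top-hat
background estimate is biased low on the ragged cell edge and leaves
small bright residuals there that are not inclusions. Cells densely
covered by spots inflate their own median and MAD past the spot peak, so
the per-cell threshold is capped by the pooled field-level robust
threshold. Connected candidates below 4 px are dropped; merged spots are
split by a watershed on masked intensity whose tolerance is a fraction
(0.2) of the candidate dynamic range, preserving scale equivariance.

**Mask combination.** Each inclusion is assigned to the cell covering the
plurality of its pixels; ties between cells break deterministically to
the smaller label, and inclusions lying mostly on background get owner 0
and are excluded from counts (extracellular debris must not enter "IBs
per cell") while remaining in the region table. Assignment conserves
labels: owned plus unassigned always equals the number of inclusion
labels.

On default-SNR synthetic fields this operating point recovers per-cell
counts with ~99% exact agreement and measured-versus-planted correlation
above 0.99; the package's tests enforce the weaker floors of 90% and
0.95.

## Encirclement scoring

The mitochondrial-association readout in the source study was scored
visually. The package replaces it with an explicit metric: the
*encirclement score* of an inclusion is the fraction of its perimeter
pixels lying within a probe distance (default 3 px) of an
organelle-positive pixel, and an inclusion is *surrounded* when the score
reaches 0.5 (majority encirclement). The organelle mask is an Otsu
threshold of the corrected channel 2, floored at median + 6 MAD so that a
signal-free channel yields an empty mask rather than half the noise.
These defaults are declared operationalizations — no equivalence with the
original visual scoring is claimed, and only recovery of planted shell
fractions is asserted. The score is monotone in the probe distance and,
operating on masks, invariant to intensity scaling of either channel.

`summarizeAssociation()` reports the surrounded fraction overall and by
owner class, pairwise class comparisons by pooled t-test on per-field
class fractions, and a single `globalP`: the one-way F-test across all
classes. The global test is the protected answer to "do the three classes
associate equivalently?" — three marginal pairwise tests at the 5% level
would reject a true null about 14% of the time, and planted Bernoulli
fluctuation alone is enough to trip one of them.

## Screen statistics

`studentTTest()` is the pooled-variance two-sample Student's t
(df = n_a + n_b - 2, two-sided p), matching the equal-n triplicate design
of the screen; Welch would be defensible but the pooled form is what the
screen's analysis names, and the choice is switchable by calling R's own
`t.test` on the same tables. Degenerate inputs get their defined limits:
zero pooled variance with equal means is t = 0, p = 1; with unequal means
p = 0 under a warning. The dual criterion (`hitCriteria()`) is inclusive
at the significance gate (p <= 0.05), gates the effect in percentage
points — "at least 20%" read as an absolute difference of percentages,
since the relative reading contradicts the phrase itself — and defaults to
the `increase` direction, which is the direction of the published
confirmed list; both gates and the direction are configurable. No
multiple-testing correction is applied: the screen design controls false
positives through the effect-size gate, which dominates when replicate
noise is small against 20 points. `callHits()` vectorizes the same
arithmetic across thousands of mutants and is deterministic given its
inputs.

The simulated screen (`generateScreenDataset()`) draws non-hit mutants
around the wild-type baseline (50% Class 3 at the 20 hr screening point)
and planted hits at +30 points, with i.i.d. replicate noise of SD 5
points and 3 replicates — conditions under which the dual criterion
recovers the planted hit set exactly in most random draws; occasional
single-hit misses occur when the shared wild-type replicate mean drifts
high, which is visible in the per-seed hit counts.

## Numerical and interface conventions

* Pixel coordinates are R-native 1-based (row, col) indices everywhere,
  in memory and in exported CSV; mixing a 0-based export convention with
  1-based analysis code invites off-by-one errors.
* All intermediate arithmetic is double precision; quantization happens
  only when images are written as 16-bit TIFF (exact round trip for
  integer intensities in [0, 65535]).
* CSVs are written with 15 significant digits; screen tables are
  schema-checked on read and missing columns are reported by name.
* `runPipeline()` validates its YAML/list configuration against a closed
  schema (unknown keys are errors), never mutates inputs, logs per-stage
  object counts, and writes a manifest (config hash, package version,
  seed, per-file checksums) atomically as the final act of a run.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script regenerate everything they
measure: 20 fields of ~150 cells per growth-phase condition, 500-cell
aging cohorts per arm, 10 two-channel fields for association, and
5,500-mutant screen tables across 10 seeds. These sizes put the binomial
sampling error of each recovered share well inside its comparison band
while keeping a full run in the minutes range on a single core.

## Known limitations

* The segmentation substitutes fully specified standard operators for the
  unpublished internals of the original vendor software; equivalence with
  the original masks cannot be asserted, only recovery of planted truth.
* Recovery guarantees are stated under the generator's imaging model;
  heavy debris, strong focus gradients or dense cell clumping are out of
  its scope.
* The encirclement metric is 2-D; genuinely 3-D organelle wrapping is not
  modelled.
* Time-course points are independent fields; there is no tracking of
  individual cells over time.
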