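# Synthetic field and screen generators: determinism, conservation,
# closed-form agreement with the planted count laws.

test_that("generation is deterministic and byte-identical under a fixed seed", {
  sp <- smallSpec(seed = 33L, shellProbability = 0.5)
  a <- generateField(sp)
  b <- generateField(sp)
  expect_identical(a$field@channels, b$field@channels)
  expect_identical(groundTruthCells(a$truth), groundTruthCells(b$truth))
  expect_identical(groundTruthInclusions(a$truth),
                   groundTruthInclusions(b$truth))
  # a different seed changes the field
  c <- generateField(smallSpec(seed = 34L, shellProbability = 0.5))
  expect_false(identical(a$field@channels, c$field@channels))
})

test_that("an empty spec yields background-only images and empty ground truth", {
  fx <- generateField(smallSpec(nCells = 0L, seed = 5L))
  expect_identical(nrow(groundTruthCells(fx$truth)), 0L)
  expect_identical(nrow(groundTruthInclusions(fx$truth)), 0L)
  img <- getChannel(fx$field, "aggregate")
  # shading x background + noise only: nothing brighter than a few noise SDs
  sp <- smallSpec(nCells = 0L)
  expect_lt(max(img), sp@backgroundLevel + 6 * sp@noiseSD)
})

test_that("planted counts are conserved between cell and inclusion records", {
  fx <- generateField(smallSpec(nCells = 20L, seed = 9L))
  cells <- groundTruthCells(fx$truth)
  ibs <- groundTruthInclusions(fx$truth)
  expect_identical(sum(cells$planted_count), nrow(ibs))
  perCell <- table(factor(ibs$cell_id, levels = cells$cell_id))
  expect_identical(as.integer(perCell), cells$planted_count)
  # planted class equals the rule applied to the planted count
  expect_identical(cells$planted_class, classifyCell(cells$planted_count))
  # planted summary equals re-aggregation of per-cell records
  expect_equal(plantedSummary(fx$truth),
               ibscreen:::.summarizeCountVector(cells$planted_count))
})

test_that("invalid field specs are rejected by name", {
  expect_error(fieldSpec(shadingAmplitude = 1.2), "shadingAmplitude")
  expect_error(fieldSpec(cellIntensity = 700), "ibIntensity > cellIntensity")
  expect_error(fieldSpec(noiseSD = -1), "negative")
  expect_error(fieldSpec(noiseSD = NaN), "non-finite")
})

test_that("overcrowded fields fail with an explicit density message", {
  expect_error(generateField(fieldSpec(width = 128L, height = 128L,
                                       nCells = 200L, seed = 1L)),
               "achievable density")
})

test_that("empirical planted counts match truncated-Poisson moments", {
  # oracle: zero-truncated Poisson mean lambda/(1 - exp(-lambda))
  lambda <- 2.5
  law <- countLaw("poissonTruncated", prevalence = 1, lambda = lambda)
  muOracle <- lambda / (1 - exp(-lambda))
  expect_equal(plantedMeanCount(law), muOracle)
  counts <- withr::with_seed(7L, ibscreen:::.drawCounts(law, 500L))
  expect_true(all(counts >= 1L))
  se <- plantedSDCount(law) / sqrt(500)
  expect_lt(abs(mean(counts) - muOracle), 3 * se)
})

test_that("preset laws reproduce the printed population structure in closed form", {
  expect_equal(unname(plantedClassShares(phaseCountLaw("lag"))["class3"]),
               0.96)
  expect_equal(unname(plantedClassShares(phaseCountLaw("stationary"))["class1"]),
               0.50)
  expect_equal(plantedMeanCount(phaseCountLaw("young")), 2.64)
  expect_equal(plantedSDCount(phaseCountLaw("young")), 1.29)
  expect_equal(plantedMeanCount(phaseCountLaw("old")), 4.91)
  expect_equal(plantedSDCount(phaseCountLaw("old")), 3.32)
  expect_equal(phaseCountLaw("young")$prevalence, 0.27)
  expect_equal(phaseCountLaw("old")$prevalence, 0.61)
})

test_that("lag-preset IB-bearing cells are nearly all Class 3 by construction", {
  fx <- generateField(smallSpec(nCells = 25L, seed = 3L,
                                countLaw = phaseCountLaw("lag")))
  cells <- groundTruthCells(fx$truth)
  bearing <- cells$planted_count[cells$planted_count > 0]
  expect_gte(mean(bearing >= 3), 0.8)   # 0.96 in expectation
})

test_that("increasing shell probability increases the planted shell fraction", {
  frac <- vapply(c(0.2, 0.5, 0.9), function(p) {
    fx <- generateField(smallSpec(nCells = 25L, seed = 17L,
                                  shellProbability = p))
    mean(groundTruthInclusions(fx$truth)$shell)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("timecourse generation delegates per point and is reproducible", {
  tpl <- smallSpec(nCells = 15L)
  tc <- generateTimecourse(list("lag", "stationary"), fieldsPerPoint = 2L,
                           seed = 4L, template = tpl)
  expect_length(tc, 2L)
  expect_identical(tc[[1]]$label, "lag")
  expect_length(tc[[1]]$fields, 2L)
  # planted Class-3 share non-increasing along lag -> stationary
  expect_gte(tc[[1]]$planted$class3_share, tc[[2]]$planted$class3_share)
  tc2 <- generateTimecourse(list("lag", "stationary"), fieldsPerPoint = 2L,
                            seed = 4L, template = tpl)
  expect_identical(tc[[2]]$fields[[1]]@channels, tc2[[2]]$fields[[1]]@channels)
  expect_error(generateTimecourse(list(), 1L, 1L), "at least one preset")
})

test_that("aging cohort plants the configured prevalences and counts", {
  coh <- generateAgingCohort(cellsPerArm = 400L, seed = 2L,
                             template = smallSpec(nCells = 25L))
  py <- coh$young$planted; po <- coh$old$planted
  seY <- sqrt(0.27 * 0.73 / py$n_cells)
  seO <- sqrt(0.61 * 0.39 / po$n_cells)
  expect_lt(abs(py$fraction_with_ibs - 0.27), 3 * seY)
  expect_lt(abs(po$fraction_with_ibs - 0.61), 3 * seO)
  expect_lt(abs(py$mean_count - 2.64), 3 * 1.29 / sqrt(py$n_ib_bearing))
  # old counts can be truncated by cell geometry; allow the sampling band
  # around the law mean
  expect_lt(abs(po$mean_count - 4.91), 3 * 3.32 / sqrt(po$n_ib_bearing) + 0.15)
})

test_that("screen datasets plant baseline and shifted mutants as configured", {
  spec <- screenSpec(nMutants = 100L, nHitsPlanted = 10L, hitShift = 30,
                     replicateSD = 5, seed = 1L)
  scr <- generateScreenDataset(spec)
  expect_identical(length(scr$plantedHits), 10L)
  expect_identical(nrow(scr$measurements), 300L)
  m <- scr$measurements
  nonhit <- !(m$mutant_id %in% scr$plantedHits)
  grand <- mean(m$class3_percent[nonhit])
  se <- 5 / sqrt(sum(nonhit))
  expect_lt(abs(grand - 50), 3 * se)
  hitMeans <- mean(m$class3_percent[!nonhit])
  expect_gt(hitMeans, 70)
  # zero planted hits / zero shift degenerate cases share the baseline law
  s0 <- generateScreenDataset(screenSpec(nMutants = 50L, nHitsPlanted = 0L,
                                         seed = 3L))
  expect_identical(length(s0$plantedHits), 0L)
  expect_error(screenSpec(nReplicates = 1L), "nReplicates")
})

test_that("out-of-range screen percentages are clipped with a warning", {
  # both the planted means and some replicate draws clip
  expect_warning(expect_warning(
    scr <- generateScreenDataset(screenSpec(nMutants = 30L,
                                            nHitsPlanted = 10L,
                                            baselineClass3 = 90,
                                            hitShift = 30, seed = 2L)),
    "clipped"), "clipped")
  expect_true(all(scr$measurements$class3_percent <= 100))
})
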