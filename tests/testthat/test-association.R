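# Organelle mask and encirclement scoring.

# rasterized-geometry oracle: fraction of perimeter pixels of `ibLab`
# within `probe` of any TRUE pixel of `org`, by brute-force distance
bruteScore <- function(ibLab, org, probe) {
  per <- which(ibscreen:::.boundarySelector(ibLab))
  orgIdx <- which(org)
  if (!length(orgIdx)) return(0)
  pr <- (per - 1) %% nrow(ibLab) + 1; pc <- (per - 1) %/% nrow(ibLab) + 1
  orr <- (orgIdx - 1) %% nrow(org) + 1; oc <- (orgIdx - 1) %/% nrow(org) + 1
  cov <- vapply(seq_along(per), function(i)
    min(sqrt((orr - pr[i])^2 + (oc - pc[i])^2)) <= probe, logical(1))
  mean(cov)
}

annulus <- function(n, center, rin, rout, angles = c(0, 2 * pi)) {
  DR <- outer(seq_len(n) - center[1], rep(1, n))
  DC <- outer(rep(1, n), seq_len(n) - center[2])
  d <- sqrt(DR^2 + DC^2)
  a <- atan2(DC, DR) %% (2 * pi)
  d >= rin & d <= rout & a >= angles[1] & a <= angles[2]
}

test_that("complete shells score 1 and an empty channel scores 0", {
  ibLab <- matrix(0L, 64, 64)
  ibLab[diskMask(64, 64, c(32, 32), 4)] <- 1L
  ibs <- labeledMask(ibLab, "inclusion")
  full <- annulus(64, c(32, 32), 6, 8)
  expect_equal(encirclementScore(ibs, full, 3), 1)
  expect_equal(encirclementScore(ibs, matrix(FALSE, 64, 64), 3), 0)
})

test_that("a half shell scores about one half, matching the geometry oracle", {
  ibLab <- matrix(0L, 96, 96)
  ibLab[diskMask(96, 96, c(48, 48), 8)] <- 1L
  ibs <- labeledMask(ibLab, "inclusion")
  half <- annulus(96, c(48, 48), 10, 12, angles = c(0, pi))
  sc <- encirclementScore(ibs, half, 3)
  expect_equal(sc, bruteScore(ibLab, half, 3), tolerance = 1e-12)
  expect_equal(sc, 0.5, tolerance = 0.05)
})

test_that("scores are monotone in probe distance and degenerate IBs are defined", {
  ibLab <- matrix(0L, 64, 64)
  ibLab[diskMask(64, 64, c(32, 32), 3)] <- 1L
  ibs <- labeledMask(ibLab, "inclusion")
  ring <- annulus(64, c(32, 32), 8, 10, angles = c(0, 1.5 * pi))
  sc <- vapply(c(2, 4, 6, 9), function(p) encirclementScore(ibs, ring, p),
               numeric(1))
  expect_true(all(diff(sc) >= 0))
  # 1-px inclusion: scored over its own neighbourhood
  one <- matrix(0L, 16, 16); one[8, 8] <- 1L
  ring1 <- matrix(FALSE, 16, 16); ring1[8, 10] <- TRUE
  expect_equal(encirclementScore(labeledMask(one, "inclusion"), ring1, 3), 1)
})

test_that("organelle masks recover planted shells and stay empty on noise", {
  fx <- generateField(smallSpec(seed = 12L, shellProbability = 1))
  pp <- preprocessField(fx$field)
  org <- organelleMask(getChannel(pp$corrected, "organelle"))
  ibs <- groundTruthInclusions(fx$truth)
  expect_gt(sum(org), 0)
  # a signal-free channel yields an (almost) empty mask
  noise <- withr::with_seed(3L, matrix(rnorm(256^2, 100, 20), 256, 256))
  expect_lt(mean(organelleMask(noise)), 1e-4)
})

test_that("the surrounded fraction recovers the planted shell probability", {
  rec <- NULL; plantedShell <- 0; plantedTot <- 0
  for (s in 1:2) {
    fx <- generateField(smallSpec(nCells = 15L, seed = s,
                                  shellProbability = 0.8))
    r <- analyzeField(fx$field, fieldId = paste0("f", s))
    rec <- rbind(rec, r$association)
    ib <- groundTruthInclusions(fx$truth)
    plantedShell <- plantedShell + sum(ib$shell)
    plantedTot <- plantedTot + nrow(ib)
  }
  sa <- summarizeAssociation(rec)
  pHat <- plantedShell / plantedTot
  se <- sqrt(pHat * (1 - pHat) / sa$n)
  expect_lt(abs(sa$overall - pHat), 3 * se + 0.03)
  # the surrounded flag is non-increasing in the threshold
  fr <- vapply(c(0.25, 0.5, 0.75, 1),
               function(th) mean(rec$encirclement >= th), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(summarizeAssociation(rec[0, ]), "no association")
})

test_that("class-independent shells give non-significant class differences", {
  rec <- NULL
  for (s in 1:4) {
    fx <- generateField(smallSpec(nCells = 15L, seed = 100L + s,
                                  shellProbability = 0.8))
    r <- analyzeField(fx$field, fieldId = paste0("f", s))
    rec <- rbind(rec, r$association)
  }
  sa <- summarizeAssociation(rec)
  expect_gt(sa$globalP, 0.05)
  expect_identical(nrow(sa$comparisons), 3L)
})
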