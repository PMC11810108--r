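# Pooled t-test and dual-criterion hit calling.

test_that("the pooled t-test matches its closed form and stats::t.test", {
  r <- studentTTest(c(1, 2, 3), c(4, 5, 6))
  # closed form: sp = 1, se = sqrt(2/3), t = -3/se
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_identical(r$df, 4)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4))
  expect_lt(abs(r$p - 0.021), 5e-4)
  # independent route: R's own pooled t-test
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  # random cases, both routes agree
  withr::with_seed(1L, for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), 50, 5); b <- rnorm(sample(2:6, 1), 55, 5)
    mine <- studentTTest(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value)
  })
})

test_that("t-test degenerate limits and antisymmetry hold", {
  expect_identical(studentTTest(c(5, 5, 5), c(5, 5, 5)),
                   list(t = 0, df = 4, p = 1))
  expect_warning(r <- studentTTest(c(5, 5), c(7, 7)), "zero pooled variance")
  expect_identical(r$p, 0)
  expect_error(studentTTest(1, c(2, 3)), "at least 2")
  a <- c(40, 45, 50); b <- c(60, 62, 58)
  expect_equal(studentTTest(a, b)$t, -studentTTest(b, a)$t)
  expect_equal(studentTTest(a, b)$p, studentTTest(b, a)$p)
})

test_that("the dual criterion gates mutants exactly as published", {
  wt <- c(50, 50, 50)
  crit <- hitCriteria()
  # +25 points, significant -> hit
  expect_true(evaluateMutant(c(75, 74, 76), wt, crit)$is_hit)
  # large delta but noisy replicates (p > 0.05) -> no hit
  noisy <- evaluateMutant(c(95, 50, 80), wt, crit)
  expect_false(noisy$is_hit)
  expect_false(noisy$passes_significance)
  expect_true(noisy$passes_effect)
  # highly significant but +15 points (< 20) -> no hit
  small <- evaluateMutant(c(65, 65.2, 64.8), wt, crit)
  expect_false(small$is_hit)
  expect_true(small$passes_significance)
  expect_false(small$passes_effect)
  # direction gate: a strong decrease is not a hit under "increase"
  dec <- evaluateMutant(c(25, 24, 26), wt, crit)
  expect_false(dec$is_hit)
  expect_true(evaluateMutant(c(25, 24, 26), wt,
                             hitCriteria(direction = "both"))$is_hit)
  # replicate order does not matter
  expect_equal(evaluateMutant(c(76, 74, 75), wt, crit)$t_statistic,
               evaluateMutant(c(74, 75, 76), wt, crit)$t_statistic)
})

test_that("vectorized hit calling agrees with per-mutant evaluation", {
  scr <- generateScreenDataset(screenSpec(nMutants = 40L, nHitsPlanted = 5L,
                                          seed = 9L))
  calls <- callHits(scr$measurements, scr$wildtype)
  for (id in sample(unique(scr$measurements$mutant_id), 6)) {
    v <- scr$measurements$class3_percent[scr$measurements$mutant_id == id]
    one <- evaluateMutant(v, scr$wildtype, mutantId = id)
    row <- calls$hits[calls$hits$mutant_id == id, ]
    expect_equal(row$t_statistic, one$t_statistic)
    expect_equal(row$p_two_sided, one$p_two_sided)
    expect_identical(row$is_hit, one$is_hit)
  }
})

test_that("planted screen hits are recovered exactly with no false positives", {
  scr <- generateScreenDataset(screenSpec(nMutants = 100L,
                                          nHitsPlanted = 10L, hitShift = 30,
                                          replicateSD = 5, seed = 1L))
  calls <- callHits(scr$measurements, scr$wildtype)
  called <- calls$hits$mutant_id[calls$hits$is_hit]
  expect_setequal(called, scr$plantedHits)
  expect_identical(calls$summary$n_hits, 10L)
  # all mutants identical to WT -> no hits
  null <- generateScreenDataset(screenSpec(nMutants = 50L,
                                           nHitsPlanted = 0L, seed = 2L))
  expect_identical(callHits(null$measurements, null$wildtype)$summary$n_hits,
                   0L)
  # vacuous criteria: every mutant is a hit
  lax <- callHits(null$measurements, null$wildtype,
                  hitCriteria(alpha = 0.999, minAbsDeltaPoints = 0,
                              direction = "both"))
  expect_identical(lax$summary$n_hits, 50L)
})

test_that("hit counts are monotone in both criteria", {
  scr <- generateScreenDataset(screenSpec(nMutants = 200L,
                                          nHitsPlanted = 30L, hitShift = 25,
                                          replicateSD = 8, seed = 4L))
  nHits <- function(alpha, delta)
    callHits(scr$measurements, scr$wildtype,
             hitCriteria(alpha = alpha, minAbsDeltaPoints = delta))$summary$n_hits
  expect_true(all(diff(sapply(c(30, 20, 10, 0), nHits, alpha = 0.05)) >= 0))
  expect_true(all(diff(sapply(c(0.001, 0.01, 0.05, 0.5), nHits,
                              delta = 20)) >= 0))
})

test_that("a pure-null screen at small replicate noise yields no false hits", {
  # the 20-point effect gate dominates when replicate SD << 20
  for (s in 1:3) {
    null <- generateScreenDataset(screenSpec(nMutants = 1000L,
                                             nHitsPlanted = 0L,
                                             replicateSD = 5, seed = s))
    expect_identical(callHits(null$measurements, null$wildtype)$summary$n_hits,
                     0L)
  }
})

test_that("screen input tables are schema-checked", {
  expect_error(callHits(data.frame(mutant_id = "a", replicate = 1),
                        c(50, 50)), "class3_percent")
  expect_error(callHits(data.frame(mutant_id = character(0),
                                   replicate = integer(0),
                                   class3_percent = numeric(0)),
                        c(50, 50)), "empty")
  expect_error(hitCriteria(alpha = 0), "alpha")
  expect_error(hitCriteria(minAbsDeltaPoints = -5), "non-negative")
})
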