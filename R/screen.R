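## Replicate-level statistics and dual-criterion hit calling for the
## genome-wide screen.

#' Pooled-variance two-sample Student's t-test
#'
#' The screen's significance test: pooled-variance Student's t with
#' `df = n_a + n_b - 2` and a two-sided p-value from the t distribution.
#' Degenerate samples are given their defined limits: zero pooled variance
#' with equal means yields `t = 0, p = 1`; zero pooled variance with
#' unequal means yields `p = 0` with a warning.
#'
#' @param a,b numeric samples, each with at least 2 finite values.
#' @return list with `t`, `df`, `p`.
#' @examples
#' studentTTest(c(1, 2, 3), c(4, 5, 6))   # t = -3.674, df = 4, p = 0.021
#' @export
studentTTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b))))
    stop("each sample needs at least 2 finite values")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; p = 0")
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Hit-calling criteria
#'
#' The screen's dual criterion: a mutant is a hit when (1) its Class-3
#' percentage differs significantly from wild type (Student's t-test,
#' `p <= alpha`, inclusive) and (2) the absolute difference is at least
#' `minAbsDeltaPoints` percentage points, in the configured direction.
#' Defaults are the screen's published gates: `alpha = 0.05`, 20 points,
#' direction `increase` (the confirmed list comprises mutants with more
#' Class-3 inclusions).
#'
#' @param alpha significance level in (0, 1).
#' @param minAbsDeltaPoints effect-size gate in percentage points (>= 0).
#' @param direction `"increase"`, `"decrease"` or `"both"`.
#' @return a validated criteria list.
#' @export
hitCriteria <- function(alpha = 0.05, minAbsDeltaPoints = 20,
                        direction = c("increase", "decrease", "both")) {
  direction <- match.arg(direction)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(minAbsDeltaPoints) || minAbsDeltaPoints < 0)
    stop("minAbsDeltaPoints must be non-negative")
  list(alpha = alpha, minAbsDeltaPoints = minAbsDeltaPoints,
       direction = direction)
}

.directionOK <- function(delta, direction) {
  switch(direction,
         increase = delta > 0,
         decrease = delta < 0,
         both = delta != 0 | delta == 0)   # always TRUE for "both"
}

#' Evaluate one mutant against wild type
#'
#' Computes the replicate-mean difference (mutant minus wild type, in
#' percentage points), the pooled t statistic and two-sided p-value, and
#' applies both hit gates. Invariant to replicate ordering.
#'
#' @param values mutant replicate Class-3 percentages (>= 2 finite values).
#' @param wildtype wild-type replicate percentages.
#' @param criteria see [hitCriteria()].
#' @param mutantId identifier recorded in the result row.
#' @return one-row data.frame: `mutant_id`, `delta_points`, `t_statistic`,
#'   `p_two_sided`, `passes_significance`, `passes_effect`, `is_hit`,
#'   `direction_label`.
#' @export
evaluateMutant <- function(values, wildtype, criteria = hitCriteria(),
                           mutantId = "mutant") {
  tt <- studentTTest(values, wildtype)
  delta <- mean(values) - mean(wildtype)
  sig <- tt$p <= criteria$alpha
  eff <- abs(delta) >= criteria$minAbsDeltaPoints &&
    .directionOK(delta, criteria$direction)
  data.frame(mutant_id = mutantId, delta_points = delta,
             t_statistic = tt$t, p_two_sided = tt$p,
             passes_significance = sig, passes_effect = eff,
             is_hit = sig && eff,
             direction_label = if (delta > 0) "increase"
                               else if (delta < 0) "decrease" else "none")
}

#' Call hits over a whole screen
#'
#' Applies [evaluateMutant()]'s dual criterion to every mutant against the
#' shared wild-type replicates (vectorized), with no multiple-testing
#' correction: the screen uses raw p-values gated by the percentage-point
#' effect size. Deterministic given its inputs.
#'
#' @param measurements long data.frame with columns `mutant_id`,
#'   `replicate`, `class3_percent` (as produced by
#'   [generateScreenDataset()] or read via [readScreenTable()]).
#' @param wildtype numeric vector of wild-type replicate percentages.
#' @param criteria see [hitCriteria()].
#' @return list with `hits` (one row per mutant, the [evaluateMutant()]
#'   columns) and `summary` (list: `n_mutants`, `n_hits`, `n_increase`,
#'   `n_decrease`).
#' @export
callHits <- function(measurements, wildtype, criteria = hitCriteria()) {
  req <- c("mutant_id", "replicate", "class3_percent")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurements table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(measurements) == 0L) stop("empty measurements table")
  if (length(wildtype) < 2L || any(!is.finite(wildtype)))
    stop("wildtype needs at least 2 finite replicate values")
  ids <- factor(measurements$mutant_id,
                levels = unique(measurements$mutant_id))
  v <- measurements$class3_percent
  if (any(!is.finite(v))) stop("non-finite class3_percent values")
  n <- tabulate(ids)
  if (any(n < 2L)) stop("every mutant needs at least 2 replicates")
  m <- as.numeric(rowsum(v, ids)) / n
  ss <- pmax(as.numeric(rowsum(v^2, ids)) - n * m^2, 0)
  nw <- length(wildtype)
  mw <- mean(wildtype)
  ssw <- sum((wildtype - mw)^2)
  df <- n + nw - 2
  sp2 <- (ss + ssw) / df
  delta <- m - mw
  se <- sqrt(sp2 * (1 / n + 1 / nw))
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), 0)
  p[se == 0 & delta == 0] <- 1
  sig <- p <= criteria$alpha
  eff <- abs(delta) >= criteria$minAbsDeltaPoints &
    .directionOK(delta, criteria$direction)
  hits <- data.frame(
    mutant_id = levels(ids), delta_points = delta, t_statistic = t,
    p_two_sided = p, passes_significance = sig, passes_effect = eff,
    is_hit = sig & eff,
    direction_label = ifelse(delta > 0, "increase",
                             ifelse(delta < 0, "decrease", "none")))
  list(hits = hits,
       summary = list(n_mutants = nlevels(ids),
                      n_hits = sum(hits$is_hit),
                      n_increase = sum(hits$is_hit &
                                         hits$direction_label == "increase"),
                      n_decrease = sum(hits$is_hit &
                                         hits$direction_label == "decrease")))
}
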