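#' Pointwise paired t tests with a run-length significance criterion
#'
#' Computes a two-tailed paired t test at every sample of the epoch time
#' axis (participants as pairs) and reports the maximal runs of consecutive
#' samples with `p < alpha` that span at least `k` samples. At the 500-Hz
#' analysis rate the default `k = 10` corresponds to 20 ms, a criterion
#' that controls false positives arising from dense temporal testing.
#' Samples whose paired differences are all zero yield `t = 0, p = 1`.
#'
#' @param condA,condB participant x time matrices of equal shape (e.g. MMN
#'   waveform values for two sessions); at least 3 participants.
#' @param timesMs sample times, ms, within \[0, 300\].
#' @param alpha pointwise significance level.
#' @param k minimum run length, samples.
#' @return a [WindowTestResult-class].
#' @examples
#' t <- seq(0, 300, by = 2)
#' a <- matrix(rnorm(15 * length(t)), 15)
#' res <- sequentialPairedTests(a, a * 0, t)
#' @export
sequentialPairedTests <- function(condA, condB, timesMs, alpha = 0.05, k = 10) {
  condA <- as.matrix(condA)
  condB <- as.matrix(condB)
  if (!all(dim(condA) == dim(condB)))
    stopf("condition matrices must have identical shape")
  if (ncol(condA) != length(timesMs))
    stopf("number of columns must match the time axis")
  n <- nrow(condA)
  if (n < 3) stopf("at least 3 participants required (got %d)", n)
  if (any(timesMs < 0) || any(timesMs > 300))
    stopf("time axis must lie within [0, 300] ms")
  d <- condA - condB
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  tval <- numeric(ncol(d))
  pval <- numeric(ncol(d))
  zero <- s == 0
  tval[!zero] <- m[!zero] / (s[!zero] / sqrt(n))
  pval[!zero] <- 2 * stats::pt(-abs(tval[!zero]), df = n - 1)
  # degenerate columns: all-zero differences are defined as no effect;
  # equal nonzero differences are a perfect separation
  tval[zero & m == 0] <- 0
  pval[zero & m == 0] <- 1
  tval[zero & m != 0] <- sign(m[zero & m != 0]) * Inf
  pval[zero & m != 0] <- 0
  runs <- significantRunTable(pval < alpha, timesMs, k)
  new("WindowTestResult", times = timesMs, statistic = tval, p = pval,
      runs = runs, alpha = alpha, k = k, n = n)
}

# Maximal runs of TRUE of length >= k, as (start_ms, end_ms, n_samples,
# length_ms). length_ms counts each sample as one sampling step, so a
# 10-sample run at 500 Hz spans 20 ms.
significantRunTable <- function(sig, timesMs, k) {
  dt <- if (length(timesMs) > 1) stats::median(diff(timesMs)) else NA_real_
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= k
  data.frame(start_ms = timesMs[starts[keep]],
             end_ms = timesMs[ends[keep]],
             n_samples = r$lengths[keep],
             length_ms = r$lengths[keep] * dt)
}

ttestResult <- function(t, df, p, d, n, kind) {
  structure(list(t = t, df = df, p = p, d = d, n = n, kind = kind),
            class = "TTestResult")
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("%s t test: t(%g) = %.4g, p = %.4g", x$kind, x$df, x$t, x$p))
  if (!is.na(x$d)) cat(sprintf(", d = %.3g", x$d))
  cat("\n")
  invisible(x)
}

#' One-sample t test against a reference value
#'
#' Tests whether the mean of `values` differs from `mu0` (two-tailed),
#' e.g. whether MMN peak amplitudes differ from zero (no change). The
#' degenerate case of all values equal to `mu0` is defined as
#' `t = 0, p = 1`; zero variance with mean away from `mu0` leaves t
#' undefined and is an error.
#'
#' @param values numeric vector, length >= 2.
#' @param mu0 reference value (default 0).
#' @return a `TTestResult` list: `t`, `df`, `p`, effect size `d`
#'   (`mean/sd`), `n`, `kind`.
#' @export
oneSampleT <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2) stopf("at least 2 values required")
  if (stats::sd(values) == 0) {
    if (mean(values) == mu0) return(ttestResult(0, n - 1, 1, 0, n, "one_sample"))
    stopf("t is undefined: zero variance with mean != mu0")
  }
  tt <- stats::t.test(values, mu = mu0)
  ttestResult(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              (mean(values) - mu0) / stats::sd(values), n, "one_sample")
}

#' Paired t test with Cohen's d
#'
#' Two-tailed paired t test on the element-wise differences `a - b`, with
#' Cohen's d for paired data: the mean difference divided by the standard
#' deviation of the differences, which equals `t / sqrt(n)`.
#'
#' @param a,b paired numeric vectors of equal length, n >= 2.
#' @return a `TTestResult` with `kind = "paired"`.
#' @export
pairedTWithD <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  out <- oneSampleT(a - b, 0)
  out$kind <- "paired"
  out$d <- out$t / sqrt(out$n)
  out
}

#' Two-sample t test
#'
#' Independent-samples t test between two groups (pooled variance by
#' default; Welch available). Zero variance in both groups with unequal
#' means leaves t undefined and is an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pooled logical; `TRUE` (default) for the pooled-variance test,
#'   `FALSE` for Welch.
#' @return a `TTestResult` with `kind = "two_sample"`; `d` is the
#'   pooled-SD standardized mean difference (NA for Welch).
#' @export
twoSampleT <- function(a, b, pooled = TRUE) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(ttestResult(0, length(a) + length(b) - 2, 1, 0,
                         length(a) + length(b), "two_sample"))
    stopf("t is undefined: zero pooled variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  d <- if (pooled) {
    sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
               (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  } else NA_real_
  ttestResult(unname(tt$statistic), unname(tt$parameter), tt$p.value, d,
              length(a) + length(b), "two_sample")
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the proportion of effect-plus-
#' error variance attributable to the effect.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared in \[0, 1).
#' @export
partialEtaSq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Cohen's d from a paired t statistic
#'
#' For paired designs `d = t / sqrt(n)` where `n` is the number of pairs.
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Cohen's d.
#' @export
cohensDFromT <- function(t, n) t / sqrt(n)

#' 2 x 2 mixed-design ANOVA with partial eta squared
#'
#' Repeated-measures ANOVA with one within-subjects factor at two levels
#' (session: no-TMS vs post-TMS) and one between-subjects factor at two
#' levels (group). Implemented through the classical decomposition for the
#' 2 x 2 mixed design: the between-groups effect is tested on
#' participant means across sessions against the between-participant error;
#' the within effect and the interaction are tested on the within-
#' participant session differences against the session x participant error.
#' With unbalanced groups the main effect of session uses unweighted
#' marginal means (Type III-style) and a warning is emitted. All F tests
#' have `df1 = 1` and `df2 = n1 + n2 - 2`.
#'
#' @param amplitudes numeric matrix or data.frame, participants x 2
#'   sessions (column 1 = first/within level, column 2 = second); no
#'   missing values (a missing session is an error).
#' @param group factor/character of length `nrow(amplitudes)` with exactly
#'   two levels.
#' @param effectNames names used for the three effects in the output.
#' @return data.frame with one row per effect (`within`, `between`,
#'   `interaction` by default): `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @examples
#' amp <- cbind(no_tms = rnorm(8), post_tms = rnorm(8))
#' mixedAnova2x2(amp, rep(c("a", "b"), each = 4))
#' @export
mixedAnova2x2 <- function(amplitudes, group,
                          effectNames = c("tms", "group", "tms_x_group")) {
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != 2)
    stopf("amplitudes must have exactly 2 session columns")
  if (anyNA(amplitudes))
    stopf("missing session measurement for at least one participant")
  group <- factor(group)
  if (nlevels(group) != 2) stopf("exactly two groups required")
  if (length(group) != nrow(amplitudes))
    stopf("one group label per participant required")
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 participants")
  if (n1 != n2)
    warning("unbalanced groups: session main effect uses unweighted ",
            "(Type III-style) marginal means", call. = FALSE)
  dfe <- n1 + n2 - 2
  subjMean <- rowMeans(amplitudes)          # between-subject part
  diffs <- amplitudes[, 2] - amplitudes[, 1]  # within-subject part
  g1 <- group == levels(group)[1]
  pooledVar <- function(x) {
    (sum((x[g1] - mean(x[g1]))^2) + sum((x[!g1] - mean(x[!g1]))^2)) / dfe
  }
  safeT <- function(num, se) if (num == 0) 0 else num / se  # 0 effect -> F = 0
  # group: two-sample pooled t on subject means, squared
  vM <- pooledVar(subjMean)
  tGroup <- safeT(mean(subjMean[g1]) - mean(subjMean[!g1]),
                  sqrt(vM * (1 / n1 + 1 / n2)))
  # session (within): unweighted mean of the group mean differences
  vD <- pooledVar(diffs)
  dbar <- (mean(diffs[g1]) + mean(diffs[!g1])) / 2
  tTms <- safeT(dbar, sqrt(vD * (1 / n1 + 1 / n2) / 4))
  # interaction: group difference in the session effect
  tInt <- safeT(mean(diffs[g1]) - mean(diffs[!g1]),
                sqrt(vD * (1 / n1 + 1 / n2)))
  Fs <- c(tTms, tGroup, tInt)^2
  data.frame(effect = effectNames, F = Fs, df1 = 1, df2 = dfe,
             p = stats::pf(Fs, 1, dfe, lower.tail = FALSE),
             partial_eta_sq = partialEtaSq(Fs, 1, dfe),
             stringsAsFactors = FALSE)
}

#' Family-wise error of the run-length criterion under the null
#'
#' Monte Carlo characterization of the consecutive-timepoint criterion:
#' simulates pairs of null condition matrices (no true difference), applies
#' the pointwise paired t tests, and reports the fraction of simulations
#' that produce at least one significant run of `k` or more samples.
#' The per-replication maximal run lengths are returned so the family-wise
#' error rate (FWER) can be re-evaluated at any `k` with shared
#' simulations, which makes the monotone decrease of FWER in `k` directly
#' inspectable.
#'
#' @param nParticipants participants per simulated experiment.
#' @param nSamples samples on the 0-300 ms axis (151 at 500 Hz).
#' @param alpha pointwise level.
#' @param k run-length criterion, samples.
#' @param noise `"white"` for i.i.d. Gaussian samples or `"ar1"` for an
#'   AR(1) process with coefficient `rho` (temporally autocorrelated, as
#'   filtered EEG is).
#' @param rho AR(1) coefficient.
#' @param nReps number of null simulations (>= 100).
#' @param seed integer seed.
#' @param fsHz nominal analysis rate used to build the time axis.
#' @return list with `fwer`, 95% Clopper-Pearson `ci`, `maxRunLengths`
#'   (per replication), and the simulation parameters.
#' @export
runlengthFwerSimulation <- function(nParticipants = 15, nSamples = 151,
                                    alpha = 0.05, k = 10,
                                    noise = c("white", "ar1"), rho = 0.5,
                                    nReps = 1000, seed = 1, fsHz = 500) {
  noise <- match.arg(noise)
  if (nReps < 100) stopf("nReps must be >= 100")
  times <- (seq_len(nSamples) - 1) * 1000 / fsHz
  times <- times * (300 / max(times))  # map onto 0-300 ms regardless of n
  drawMatrix <- function() {
    m <- matrix(stats::rnorm(nParticipants * nSamples), nParticipants)
    if (noise == "ar1") {
      m <- t(apply(m, 1, function(e)
        as.numeric(stats::filter(e, rho, method = "recursive"))))
    }
    m
  }
  maxRun <- withSeed(seed, {
    vapply(seq_len(nReps), function(rep) {
      d <- drawMatrix() - drawMatrix()
      mu <- colMeans(d)
      s <- apply(d, 2, stats::sd)
      tv <- mu / (s / sqrt(nParticipants))
      p <- 2 * stats::pt(-abs(tv), df = nParticipants - 1)
      r <- rle(p < alpha)
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    }, numeric(1))
  })
  hits <- sum(maxRun >= k)
  ci <- as.numeric(stats::binom.test(hits, nReps)$conf.int)
  list(fwer = hits / nReps, ci = ci, maxRunLengths = maxRun,
       nReps = nReps, k = k, alpha = alpha, noise = noise,
       nParticipants = nParticipants, nSamples = nSamples)
}
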