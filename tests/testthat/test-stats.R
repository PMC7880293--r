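grid151 <- function() seq(0, 300, by = 2)

test_that("identical conditions yield t = 0, p = 1 and no runs", {
  t151 <- grid151()
  a <- matrix(rnorm(15 * length(t151)), 15)
  res <- sequentialPairedTests(a, a, t151)
  expect_true(all(res@statistic == 0))
  expect_true(all(res@p == 1))
  expect_equal(nrow(significantRuns(res)), 0)
})

test_that("pointwise t and p match stats::t.test at every sample", {
  t151 <- grid151()
  set.seed(11)
  a <- matrix(rnorm(12 * length(t151), sd = 2), 12)
  b <- matrix(rnorm(12 * length(t151), sd = 2), 12)
  res <- sequentialPairedTests(a, b, t151)
  for (j in seq(1, length(t151), by = 10)) {
    tt <- t.test(a[, j], b[, j], paired = TRUE)
    expect_equal(res@statistic[j], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res@p[j], tt$p.value, tolerance = 1e-8)
  }
})

test_that("nine consecutive significant samples report no run; ten report one", {
  t151 <- grid151()
  n <- 15
  makeShift <- function(nSig) {
    # identical conditions (p = 1) everywhere except a constant separation
    # over exactly nSig samples starting at 158 ms (p = 0 there)
    a <- matrix(rnorm(n * length(t151), sd = 0.1), n)
    b <- a
    sel <- which(t151 >= 158)[seq_len(nSig)]
    b[, sel] <- b[, sel] + 10
    list(a = a, b = b)
  }
  set.seed(21)
  nine <- makeShift(9)
  res9 <- sequentialPairedTests(nine$a, nine$b, t151)
  # verify the construction: exactly 9 consecutive points are significant
  expect_equal(sum(res9@p < 0.05), 9)
  expect_equal(nrow(significantRuns(res9)), 0)
  ten <- makeShift(10)
  res10 <- sequentialPairedTests(ten$a, ten$b, t151)
  runs <- significantRuns(res10)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_samples, 10)
  expect_equal(runs$length_ms, 20)  # 10 samples at 500 Hz span 20 ms
})

test_that("a constructed separation window is recovered with matching bounds", {
  t151 <- grid151()
  n <- 15
  sel <- t151 >= 158 & t151 <= 230
  set.seed(31)
  a <- matrix(rnorm(n * length(t151), sd = 0.5), n)
  b <- a
  b[, sel] <- b[, sel] + 8 + rnorm(n * sum(sel), sd = 0.5)  # shift >> SE inside the window only
  res <- sequentialPairedTests(a, b, t151)
  runs <- significantRuns(res)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start_ms, 158)
  expect_equal(runs$end_ms, 230)
  # cross-check the pointwise p against direct t CDF evaluation
  d <- a - b
  j <- which(t151 == 200)
  tj <- mean(d[, j]) / (sd(d[, j]) / sqrt(n))
  expect_equal(res@p[j], 2 * pt(-abs(tj), n - 1), tolerance = 1e-12)
})

test_that("the pointwise tests are invariant to participant order", {
  t151 <- grid151()
  set.seed(41)
  a <- matrix(rnorm(10 * length(t151)), 10)
  b <- matrix(rnorm(10 * length(t151)), 10)
  perm <- sample(10)
  r1 <- sequentialPairedTests(a, b, t151)
  r2 <- sequentialPairedTests(a[perm, ], b[perm, ], t151)
  expect_equal(r1@statistic, r2@statistic, tolerance = 1e-12)
  expect_equal(significantRuns(r1), significantRuns(r2))
})

test_that("degenerate and invalid inputs are handled as documented", {
  t151 <- grid151()
  z <- matrix(0, 5, length(t151))
  res <- sequentialPairedTests(z, z, t151)
  expect_true(all(res@statistic == 0) && all(res@p == 1))
  expect_error(sequentialPairedTests(z[1:2, ], z[1:2, ], t151), "at least 3")
  expect_error(sequentialPairedTests(z, z[, 1:10], t151), "shape")
  expect_error(sequentialPairedTests(z, z, t151 + 200), "0, 300")
})

test_that("one-sample t follows the closed form", {
  res <- oneSampleT(c(-1, -2, -3))
  expect_equal(res$t, -2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t, -3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  # all values at mu0: defined as t = 0, p = 1
  flat <- oneSampleT(rep(2, 5), mu0 = 2)
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_error(oneSampleT(rep(2, 5), mu0 = 0), "undefined")
  expect_error(oneSampleT(3), "at least 2")
})

test_that("one-sample t matches the mean/SEM ratio for moment-matched data", {
  # synthetic amplitudes with mean -2.25 and SEM 0.49 (n = 15)
  n <- 15
  x <- scale(rnorm(n))[, 1] * 0.49 * sqrt(n) - 2.25
  expect_equal(mean(x), -2.25, tolerance = 1e-12)
  res <- oneSampleT(x)
  expect_equal(res$t, -2.25 / 0.49, tolerance = 1e-10)
  expect_equal(abs(res$t), 4.59, tolerance = 0.01)
})

test_that("paired t carries Cohen's d = t / sqrt(n)", {
  a <- c(2, 4, 6)
  b <- c(1, 2, 3)  # diffs 1, 2, 3
  res <- pairedTWithD(a, b)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$d, 2.0, tolerance = 1e-10)
  expect_equal(res$d, res$t / sqrt(3), tolerance = 1e-12)
  same <- pairedTWithD(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)
  expect_error(pairedTWithD(1:3, 1:4), "equal length")
})

test_that("two-sample t handles pooled, Welch and degenerate inputs", {
  a <- c(1, 2, 3, 4)
  expect_equal(twoSampleT(a, a)$t, 0)
  expect_error(twoSampleT(rep(0, 4), rep(1, 4)), "undefined")
  expect_equal(twoSampleT(rep(3, 4), rep(3, 4))$t, 0)
  set.seed(5)
  x <- rnorm(8); y <- rnorm(10, 1)
  res <- twoSampleT(x, y)
  sp <- sqrt((7 * var(x) + 9 * var(y)) / 16)
  expect_equal(res$t, (mean(x) - mean(y)) / (sp * sqrt(1 / 8 + 1 / 10)),
               tolerance = 1e-10)
  expect_equal(res$df, 16)
  welch <- twoSampleT(x, y, pooled = FALSE)
  expect_equal(welch$t, unname(t.test(x, y)$statistic), tolerance = 1e-12)
})

test_that("partial eta squared reproduces every printed F pair at 2 dp", {
  pairs <- rbind(c(8.57, 0.23), c(8.32, 0.22), c(15.56, 0.35),
                 c(13.80, 0.32), c(4.04, 0.12))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(round(partialEtaSq(pairs[i, 1], 1, 29), 2), pairs[i, 2])
  }
  expect_equal(round(cohensDFromT(3.41, 15), 2), 0.88)
})

test_that("the mixed ANOVA matches a brute-force SS decomposition (balanced)", {
  set.seed(8)
  y <- cbind(rnorm(12, -5), rnorm(12, -4))
  group <- rep(c("g1", "g2"), each = 6)
  fit <- mixedAnova2x2(y, group)
  oracle <- anovaOracle(y, group)
  expect_equal(fit$F, unname(oracle), tolerance = 1e-8)
  expect_equal(fit$df1, rep(1, 3))
  expect_equal(fit$df2, rep(10, 3))
  expect_equal(fit$partial_eta_sq,
               fit$F * 1 / (fit$F * 1 + fit$df2), tolerance = 1e-12)
})

test_that("the mixed ANOVA matches aov with an Error stratum (balanced)", {
  set.seed(9)
  y <- cbind(rnorm(10, -5), rnorm(10, -4))
  group <- rep(c("g1", "g2"), each = 5)
  fit <- mixedAnova2x2(y, group)
  df <- data.frame(amp = c(y), session = rep(c("s1", "s2"), each = 10),
                   group = rep(group, 2), id = factor(rep(1:10, 2)))
  av <- summary(aov(amp ~ group * session + Error(id), data = df))
  fGroup <- av[["Error: id"]][[1]]["group", "F value"]
  fSes <- av[["Error: Within"]][[1]]["session", "F value"]
  fInt <- av[["Error: Within"]][[1]]["group:session", "F value"]
  expect_equal(fit$F[fit$effect == "group"], fGroup, tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "tms"], fSes, tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "tms_x_group"], fInt, tolerance = 1e-8)
})

test_that("degenerate and malformed ANOVA inputs behave as documented", {
  y <- cbind(rep(1, 6), rep(1, 6))
  fit <- mixedAnova2x2(y, rep(c("a", "b"), each = 3))
  expect_true(all(fit$F == 0))  # all cells equal: zero effect SS
  y2 <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_warning(mixedAnova2x2(rbind(y2, c(0, 1)),
                               c("a", "a", "a", "b", "b")), "unbalanced")
  y2[2, 2] <- NA
  expect_error(mixedAnova2x2(y2, c("a", "a", "b", "b")), "missing session")
  expect_error(mixedAnova2x2(cbind(1:4, 2:5), rep("a", 4)), "two groups")
})

test_that("F(1,29) = 8.57 style results give partial eta squared 0.23", {
  # constructed unbalanced 15 + 16 dataset; identity checked on its output
  set.seed(10)
  y <- rbind(cbind(rnorm(15, -5.4, 1.5), rnorm(15, -4.0, 1.6)),
             cbind(rnorm(16, -6.9, 2.5), rnorm(16, -7.2, 3.4)))
  fit <- suppressWarnings(mixedAnova2x2(y, rep(c("nt", "t"), c(15, 16))))
  expect_equal(fit$df2, rep(29, 3))
  expect_equal(fit$partial_eta_sq, partialEtaSq(fit$F, 1, 29), tolerance = 1e-12)
})

test_that("uncontrolled pointwise testing has high familywise error; runs control it", {
  sim <- runlengthFwerSimulation(nParticipants = 15, nSamples = 151,
                                 k = 1, nReps = 300, seed = 3)
  expect_gt(sim$fwer, 0.5)  # k = 1: multiple comparisons uncontrolled
  # same simulations re-thresholded: FWER monotone non-increasing in k
  fwerAtK <- vapply(c(1, 5, 10, 20),
                    function(k) mean(sim$maxRunLengths >= k), numeric(1))
  expect_true(all(diff(fwerAtK) <= 0))
  expect_lt(fwerAtK[4], fwerAtK[1])
  # AR(1) noise produces longer null runs than white noise at equal seeds
  ar <- runlengthFwerSimulation(nParticipants = 15, nSamples = 151, k = 10,
                                noise = "ar1", rho = 0.9, nReps = 200, seed = 4)
  wh <- runlengthFwerSimulation(nParticipants = 15, nSamples = 151, k = 10,
                                noise = "white", nReps = 200, seed = 4)
  expect_gte(ar$fwer, wh$fwer)
  expect_error(runlengthFwerSimulation(nReps = 10), ">= 100")
})
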