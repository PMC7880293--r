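waveFromValues <- function(values, fsHz = 500, channel = "FCz",
                           label = "da4", method = "average",
                           session = NA_character_, kind = "oddball") {
  dt <- 1000 / fsHz
  times <- seq(-100, by = dt, length.out = length(values))
  new("Waveform", values = values, times = times, fsHz = fsHz,
      channel = channel, label = label, sequenceKind = kind,
      session = session, method = method, nEpochs = 1)
}

noiselessEpochs <- function(nTotal = 30, seed = 1, templates = NULL,
                            fsHz = 1000) {
  d <- tinyDesign(nTotal = nTotal, seed = seed)
  ev <- generateOddballSequence(d)
  if (is.null(templates)) templates <- defaultErpTemplates(channels = montage3())
  cfg <- simulationConfig(noiseSdUv = 0, trialJitterSd = 0, seed = seed,
                          channels = montage3())
  rec <- simulateRecording(ev, templates, cfg)
  flagDesignExclusions(
    epochRecording(rec, preprocessConfig(targetFsHz = fsHz)), 0)
}

test_that("averaging uses kept epochs only and records the count", {
  ep <- epochSetFromRoles(rep("standard", 4))
  ep@data[1, 1, ] <- 1
  ep@data[2, 1, ] <- -1
  avg <- averageErp(ep, "da1", "oddball", "FCz")
  expect_true(all(voltages(avg) == 0))
  expect_equal(avg@nEpochs, 4)
  # identical epochs average to themselves
  ep2 <- epochSetFromRoles(rep("standard", 2))
  ep2@data[, 1, ] <- 5
  expect_true(all(voltages(averageErp(ep2, "da1", "oddball", "FCz")) == 5))
  # rejected epochs never enter
  ep@info$status[1] <- "artifact_rejected"
  avg2 <- averageErp(ep, "da1", "oddball", "FCz")
  expect_equal(avg2@nEpochs, 3)
  expect_equal(voltages(avg2)[1], -1 / 3)
  # empty selections error with the selector in the message
  expect_error(averageErp(ep, "zz", "oddball", "FCz"), "zz")
})

test_that("noiseless deviant averages reproduce the rendered deviant ERP", {
  tpl <- defaultErpTemplates(channels = montage3())
  ep <- noiselessEpochs(templates = tpl)
  avg <- averageErp(ep, "da4", "oddball", "FCz")
  ren <- renderErp(tpl$da4, asDeviant = TRUE, fsHz = 1000,
                   channels = montage3(), tRangeMs = c(0, 300))
  sel <- sampleTimes(avg) >= 0
  expect_equal(voltages(avg)[sel], unname(ren["FCz", ]), tolerance = 1e-10)
})

test_that("traditional MMN is the pointwise deviant minus standard difference", {
  std <- waveFromValues(rep(-1, 200))
  dev <- waveFromValues(rep(-1, 200))
  expect_true(all(voltages(traditionalMmn(dev, std)) == 0))
  ctx <- renderErp(erpTemplate("x", list(), erpComponent(185, 25, -6)),
                   asDeviant = TRUE, fsHz = 500, channels = "FCz",
                   tRangeMs = c(-100, 300))
  dev2 <- waveFromValues(rep(-1, 200) + as.numeric(ctx))
  mmn <- traditionalMmn(dev2, std)
  expect_equal(voltages(mmn), as.numeric(ctx))
  expect_equal(mmn@method, "traditional")
  # grid mismatch errors
  shorter <- waveFromValues(rep(0, 100))
  expect_error(traditionalMmn(dev, shorter), "grid")
})

test_that("identity MMN requires the same stimulus in both contexts", {
  odd <- waveFromValues(rnorm(200), label = "ba1")
  ctrlSame <- waveFromValues(rnorm(200), label = "ba1", kind = "control")
  ctrlOther <- waveFromValues(rnorm(200), label = "da4", kind = "control")
  expect_error(identityMmn(odd, ctrlOther), "SAME stimulus")
  out <- identityMmn(odd, ctrlSame)
  expect_equal(voltages(out), voltages(odd) - voltages(ctrlSame))
  expect_equal(out@method, "identity")
  expect_true(all(voltages(identityMmn(odd, odd)) == 0))
})

test_that("identity MMN recovers the injected context component exactly (noiseless)", {
  tpl <- defaultErpTemplates(channels = montage3())
  d <- tinyDesign(nTotal = 30, seed = 4)
  cfg <- simulationConfig(noiseSdUv = 0, trialJitterSd = 0, seed = 4,
                          channels = montage3())
  ep <- noiselessEpochs(nTotal = 30, seed = 4, templates = tpl)
  dev <- averageErp(ep, "da4", "oddball", "FCz")
  ctrlEv <- generateControlSequence("da4", 10, d)
  ctrlRec <- simulateRecording(ctrlEv, tpl, cfg)
  ctrlEp <- flagDesignExclusions(
    epochRecording(ctrlRec, preprocessConfig(targetFsHz = 1000)), 0)
  ctrl <- averageErp(ctrlEp, "da4", "control", "FCz")
  id <- identityMmn(dev, ctrl)
  ren <- renderErp(erpTemplate("x", list(), tpl$da4@contextMmn),
                   asDeviant = TRUE, fsHz = 1000, channels = "FCz",
                   tRangeMs = c(0, 300))
  sel <- sampleTimes(id) >= 0
  expect_equal(voltages(id)[sel], unname(ren[1, ]), tolerance = 1e-10)
})

test_that("label-specific exogenous responses bias traditional but not identity MMN", {
  # the deviant has a larger exogenous N1 than the standard: the
  # traditional subtraction absorbs that difference, the same-stimulus
  # subtraction does not
  ch <- montage3()
  w <- stats::setNames(c(1, -0.2, -0.2), ch)
  exoStd <- list(erpComponent(100, 20, -3, w))
  exoDev <- list(erpComponent(100, 20, -4.5, w))
  ctx <- erpComponent(185, 25, -6, w)
  tpl <- list(da1 = erpTemplate("da1", exoStd),
              ba1 = erpTemplate("ba1", exoStd),
              da4 = erpTemplate("da4", exoDev, contextMmn = ctx))
  d <- tinyDesign(nTotal = 30, seed = 5)
  cfg <- simulationConfig(noiseSdUv = 0, trialJitterSd = 0, seed = 5,
                          channels = ch)
  ep <- noiselessEpochs(nTotal = 30, seed = 5, templates = tpl)
  std <- averageErp(ep, "da1", "oddball", "FCz")
  dev <- averageErp(ep, "da4", "oddball", "FCz")
  ctrlRec <- simulateRecording(generateControlSequence("da4", 10, d), tpl, cfg)
  ctrl <- averageErp(flagDesignExclusions(
    epochRecording(ctrlRec, preprocessConfig(targetFsHz = 1000)), 0),
    "da4", "control", "FCz")
  trad <- traditionalMmn(dev, std)
  iden <- identityMmn(dev, ctrl)
  ctxRen <- renderErp(erpTemplate("x", list(), ctx), asDeviant = TRUE,
                      fsHz = 1000, channels = "FCz", tRangeMs = c(0, 300))
  exoDiff <- renderErp(erpTemplate("x", list(erpComponent(100, 20, -1.5, w))),
                       fsHz = 1000, channels = "FCz", tRangeMs = c(0, 300))
  sel <- sampleTimes(trad) >= 0
  expect_equal(voltages(iden)[sel], unname(ctxRen[1, ]), tolerance = 1e-10)
  expect_equal(voltages(trad)[sel] - voltages(iden)[sel],
               unname(exoDiff[1, ]), tolerance = 1e-10)
})

test_that("identity and traditional MMN agree when exogenous responses are shared", {
  tpl <- defaultErpTemplates(channels = montage3())
  d <- tinyDesign(nTotal = 30, seed = 6)
  cfg <- simulationConfig(noiseSdUv = 0, trialJitterSd = 0, seed = 6,
                          channels = montage3())
  ep <- noiselessEpochs(nTotal = 30, seed = 6, templates = tpl)
  std <- averageErp(ep, "da1", "oddball", "FCz")
  dev <- averageErp(ep, "ba1", "oddball", "FCz")
  ctrlRec <- simulateRecording(generateControlSequence("ba1", 10, d), tpl, cfg)
  ctrl <- averageErp(flagDesignExclusions(
    epochRecording(ctrlRec, preprocessConfig(targetFsHz = 1000)), 0),
    "ba1", "control", "FCz")
  expect_equal(voltages(traditionalMmn(dev, std)),
               voltages(identityMmn(dev, ctrl)), tolerance = 1e-10)
})

test_that("peak finding returns the earliest most-negative sample with edge flags", {
  ctx <- renderErp(erpTemplate("x", list(), erpComponent(180, 20, -6)),
                   asDeviant = TRUE, fsHz = 500, channels = "FCz",
                   tRangeMs = c(-100, 300))
  pk <- findPeak(waveFromValues(as.numeric(ctx)), c(100, 250))
  expect_equal(pk$latency_ms, 180)
  expect_equal(pk$value_uv, -6)
  expect_false(pk$edge_peak)
  # monotone ramp: minimum at the window edge, flagged
  ramp <- waveFromValues(seq(0, -10, length.out = 200))
  pk2 <- findPeak(ramp, c(100, 250))
  expect_equal(pk2$latency_ms, 250)
  expect_true(pk2$edge_peak)
  # two equal minima: earliest wins
  v <- rep(0, 200)
  times <- seq(-100, by = 2, length.out = 200)
  v[times == 160] <- -5
  v[times == 200] <- -5
  pk3 <- findPeak(waveFromValues(v), c(100, 250))
  expect_equal(pk3$latency_ms, 160)
  expect_error(findPeak(ramp, c(100, 400)), "outside the epoch")
})

test_that("peak-window amplitude is the closed-interval mean on the grid", {
  const <- waveFromValues(rep(-5, 200))
  amp <- peakWindowAmplitude(const, 180)
  expect_equal(as.numeric(amp), -5)
  expect_equal(attr(amp, "n_samples"), 21)  # 40 ms closed window at 500 Hz
  # triangular trough, peak -6 at 180 ms, reaching zero +-40 ms away;
  # oracle: mean over samples t in {160,162,...,200} of -6*(1-|t-180|/40)
  times <- seq(-100, by = 2, length.out = 200)
  tri <- -6 * pmax(0, 1 - abs(times - 180) / 40)
  oracle <- -6 * (1 - mean(abs(seq(-20, 20, by = 2))) / 40)
  expect_equal(oracle, -6 * (1 - (220 / 21) / 40))
  amp2 <- peakWindowAmplitude(waveFromValues(tri), 180)
  expect_equal(as.numeric(amp2), oracle)
  # window running past the epoch end errors
  expect_error(peakWindowAmplitude(const, 295), "outside the epoch")
})

test_that("the window mean is never more extreme than the peak itself", {
  set.seed(42)
  for (i in 1:20) {
    v <- cumsum(rnorm(200))
    w <- waveFromValues(v)
    pk <- findPeak(w, c(100, 250))
    if (pk$latency_ms - 20 < -100 || pk$latency_ms + 20 > 298) next
    amp <- as.numeric(peakWindowAmplitude(w, pk$latency_ms))
    expect_gte(amp, pk$value_uv)
  }
  const <- waveFromValues(rep(-3, 200))
  pk <- findPeak(const, c(100, 250))
  expect_equal(as.numeric(peakWindowAmplitude(const, pk$latency_ms)),
               pk$value_uv)
})

test_that("averaging then differencing equals differencing then averaging", {
  ep <- epochSetFromRoles(c(rep("standard", 3), rep("deviant", 3)))
  set.seed(7)
  ep@data[, 1, ] <- rnorm(6 * dim(ep@data)[3])
  std <- averageErp(ep, "da1", "oddball", "FCz")
  dev <- averageErp(ep, "da4", "oddball", "FCz")
  mmn <- traditionalMmn(dev, std)
  perEpochDiff <- colMeans(ep@data[4:6, 1, ]) - colMeans(ep@data[1:3, 1, ])
  expect_equal(voltages(mmn), perEpochDiff, tolerance = 1e-12)
})

test_that("measureMmn assembles a tidy one-row result", {
  ctx <- renderErp(erpTemplate("x", list(), erpComponent(180, 20, -6)),
                   asDeviant = TRUE, fsHz = 500, channels = "FCz",
                   tRangeMs = c(-100, 300))
  row <- measureMmn(waveFromValues(as.numeric(ctx), method = "traditional",
                                   session = "no_tms"),
                    contrast = "tone")
  expect_equal(row$peak_latency_ms, 180)
  expect_lt(row$peak_amplitude_uv, -5)
  expect_equal(row$contrast, "tone")
  expect_equal(row$session, "no_tms")
})
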