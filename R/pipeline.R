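#' Default end-to-end run configuration
#'
#' Nested list mirroring the experiment: the oddball design block, the
#' same-stimulus control block, the EEG simulation block, the groups
#' (each with its own context MMN suppression factor for post-TMS
#' sessions), the preprocessing, MMN-measurement and statistics blocks.
#' All values can be overridden from a YAML file via [readRunConfig()].
#'
#' @return a named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    design = list(
      n_total = 1800,
      probabilities = list(da1 = 0.8, ba1 = 0.1, da4 = 0.1),
      standard = "da1",
      stimulus_duration_ms = 150,
      isi_ms = 400,
      min_standards_between_deviants = 1
    ),
    control = list(n_repetitions = 400, labels = c("ba1", "da4")),
    simulation = list(
      fs_hz = 1000,
      channels = eegMontage(),
      noise_sd_uv = 10,
      noise_exponent = 1,
      trial_jitter_sd = 0.1,
      mmn_amplitudes = list(ba1 = -2.5, da4 = -6),
      mmn_latency_ms = 185,
      mmn_width_ms = 25
    ),
    groups = list(
      list(name = "non_tonal", n_participants = 15, tms_suppression = 0.7),
      list(name = "tonal", n_participants = 16, tms_suppression = 1.0)
    ),
    preprocess = list(
      target_fs_hz = 500, highpass_hz = 1, lowpass_hz = 30,
      epoch_start_ms = -100, epoch_end_ms = 300,
      reject_threshold_uv = 70, n_initial_excluded = 10,
      reref_channels = mastoidChannels()
    ),
    mmn = list(channel = "FCz", search_window_ms = c(100, 250), window_ms = 40),
    stats = list(alpha = 0.05, k = 10),
    output = list(write_edf = FALSE)
  )
}

mergeConfig <- function(defaults, overrides) {
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !is.null(names(overrides[[k]]))) {
      defaults[[k]] <- mergeConfig(defaults[[k]], overrides[[k]])
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified fields from
#' [defaultRunConfig()], and validates the result before any computation;
#' violations are reported with their field paths.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  config <- defaultRunConfig()
  if (!is.null(path)) config <- mergeConfig(config, yaml::read_yaml(path))
  validateRunConfig(config)
  config
}

#' @rdname readRunConfig
#' @param config configuration list to validate.
#' @export
validateRunConfig <- function(config) {
  fail <- function(path, msg) stopf("config %s: %s", path, msg)
  p <- unlist(config$design$probabilities)
  if (abs(sum(p) - 1) > 1e-12) fail("design.probabilities", "must sum to 1")
  if (!(config$design$standard %in% names(p)))
    fail("design.standard", "must name one of the labels")
  chans <- unlist(config$simulation$channels)
  missing <- setdiff(unlist(config$preprocess$reref_channels), chans)
  if (length(missing) > 0)
    fail("preprocess.reref_channels",
         sprintf("channel(s) %s not in simulation.channels",
                 paste(missing, collapse = ", ")))
  if (!(config$mmn$channel %in% chans))
    fail("mmn.channel", "not in simulation.channels")
  bad <- setdiff(unlist(config$control$labels), names(p))
  if (length(bad) > 0)
    fail("control.labels", sprintf("unknown label(s) %s", paste(bad, collapse = ", ")))
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    if (is.null(g$name)) fail(sprintf("groups[%d].name", i), "missing")
    s <- g$tms_suppression
    if (is.null(s) || s < 0 || s > 1)
      fail(sprintf("groups[%d].tms_suppression", i), "must lie in [0, 1]")
  }
  invisible(config)
}

configObjects <- function(config, seed = config$seed) {
  p <- unlist(config$design$probabilities)
  design <- oddballDesign(
    nTotal = config$design$n_total, probabilities = p,
    standard = config$design$standard,
    stimulusDurationMs = config$design$stimulus_duration_ms,
    isiMs = config$design$isi_ms,
    minStandardsBetweenDeviants = config$design$min_standards_between_deviants,
    seed = seed)
  templates <- defaultErpTemplates(
    mmnAmplitudes = unlist(config$simulation$mmn_amplitudes),
    mmnLatencyMs = config$simulation$mmn_latency_ms,
    mmnWidthMs = config$simulation$mmn_width_ms,
    channels = unlist(config$simulation$channels))
  simCfg <- simulationConfig(
    fsHz = config$simulation$fs_hz,
    channels = unlist(config$simulation$channels),
    noiseSdUv = config$simulation$noise_sd_uv,
    noiseExponent = config$simulation$noise_exponent,
    trialJitterSd = config$simulation$trial_jitter_sd,
    seed = seed)
  preCfg <- preprocessConfig(
    targetFsHz = config$preprocess$target_fs_hz,
    rerefChannels = unlist(config$preprocess$reref_channels),
    highpassHz = config$preprocess$highpass_hz,
    lowpassHz = config$preprocess$lowpass_hz,
    epochStartMs = config$preprocess$epoch_start_ms,
    epochEndMs = config$preprocess$epoch_end_ms,
    rejectThresholdUv = config$preprocess$reject_threshold_uv,
    nInitialExcluded = config$preprocess$n_initial_excluded)
  list(design = design, templates = templates, simCfg = simCfg, preCfg = preCfg)
}

#' Simulate and analyse one virtual participant
#'
#' End-to-end unit of the pipeline: generates this participant's oddball
#' sequence, simulates the requested sessions (and same-stimulus control
#' sequences in the no-TMS session), preprocesses each recording, and
#' returns MMN difference waves and peak measures. Per-stage seeds are
#' derived deterministically from `seed` (keep it below 2^27).
#'
#' @param seed participant-level integer seed.
#' @param design a [SequenceDesign-class] (its seed is replaced).
#' @param templates named list of [ErpTemplate-class].
#' @param simConfig a [SimulationConfig-class]; `tmsSuppression` applies in
#'   the post-TMS session.
#' @param preConfig a [PreprocessConfig-class].
#' @param sessions sessions to simulate.
#' @param controlLabels labels given same-stimulus control sequences in the
#'   no-TMS session (empty = traditional method only).
#' @param controlReps control sequence length.
#' @param channel analysis channel.
#' @param searchWindowMs,windowMs peak search window and amplitude window.
#' @param contrasts named map label -> contrast name.
#' @return list with `measures` (data.frame, one row per contrast x method
#'   x session) and `waves` (named list of difference [Waveform-class]s,
#'   names `<method>.<label>.<session>`).
#' @export
simulateParticipant <- function(seed, design = oddballDesign(),
                                templates = defaultErpTemplates(),
                                simConfig = simulationConfig(),
                                preConfig = preprocessConfig(),
                                sessions = c("no_tms", "post_tms"),
                                controlLabels = character(0),
                                controlReps = 400,
                                channel = "FCz",
                                searchWindowMs = c(100, 250), windowMs = 40,
                                contrasts = c(ba1 = "phoneme", da4 = "tone")) {
  design@seed <- seed * 16 + 1
  oddEvents <- generateOddballSequence(design)
  std <- design@standard
  devLabels <- setdiff(names(design@probabilities), std)
  measures <- list()
  waves <- list()
  devWavesNoTms <- list()
  for (si in seq_along(sessions)) {
    ses <- sessions[si]
    simConfig@seed <- seed * 16 + 1 + si
    rec <- simulateRecording(oddEvents, templates, simConfig, session = ses)
    epochs <- preprocessRecording(rec, preConfig)
    stdWave <- averageErp(epochs, std, "oddball", channel, session = ses)
    for (lab in devLabels) {
      devWave <- averageErp(epochs, lab, "oddball", channel, session = ses)
      mmn <- traditionalMmn(devWave, stdWave)
      key <- sprintf("traditional.%s.%s", lab, ses)
      waves[[key]] <- mmn
      measures[[key]] <- measureMmn(mmn, searchWindowMs, windowMs,
                                    contrast = unname(contrasts[lab]))
      if (ses == "no_tms") devWavesNoTms[[lab]] <- devWave
    }
  }
  if (length(controlLabels) > 0 && "no_tms" %in% sessions) {
    for (ci in seq_along(controlLabels)) {
      lab <- controlLabels[ci]
      ctrlEvents <- generateControlSequence(lab, controlReps, design)
      simConfig@seed <- seed * 16 + 8 + ci
      rec <- simulateRecording(ctrlEvents, templates, simConfig,
                               session = "no_tms")
      epochs <- preprocessRecording(rec, preConfig)
      ctrlWave <- averageErp(epochs, lab, "control", channel,
                             session = "no_tms")
      mmn <- identityMmn(devWavesNoTms[[lab]], ctrlWave)
      key <- sprintf("identity.%s.no_tms", lab)
      waves[[key]] <- mmn
      measures[[key]] <- measureMmn(mmn, searchWindowMs, windowMs,
                                    contrast = unname(contrasts[lab]))
    }
  }
  list(measures = do.call(rbind, measures), waves = waves,
       events = oddEvents)
}

writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mmnerp %s config_sha1=%s",
                     as.character(utils::packageVersion("mmnerp")), hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full oddball MMN pipeline
#'
#' Simulates every group and participant of the configuration across the
#' no-TMS and post-TMS sessions, preprocesses the recordings, measures
#' traditional (both sessions) and identity (no-TMS) MMN responses, and
#' runs the statistical layer: pointwise paired t tests with the
#' run-length criterion (no-TMS vs post-TMS, per group and contrast),
#' one-sample t tests of the peak amplitudes against zero, paired t tests
#' with Cohen's d for the TMS effect, and (with two groups) the 2 x 2
#' mixed ANOVA with partial eta squared per contrast. All outputs are CSV
#' files stamped with the SHA-1 hash of the configuration; re-running with
#' the same configuration and seed reproduces them bit for bit.
#'
#' @param config configuration list (see [defaultRunConfig()] /
#'   [readRunConfig()]).
#' @param outDir output directory, created if needed.
#' @param verbose emit stage-boundary messages with epoch accounting.
#' @return invisibly, a list with `measures`, `ttests`, `anova`, `runs`
#'   data.frames and the config `hash`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir, verbose = TRUE) {
  validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- digest::digest(config, algo = "sha1")
  say <- function(...) if (verbose) message(sprintf(...))
  obj <- configObjects(config)
  contrasts <- c(ba1 = "phoneme", da4 = "tone")
  labs <- setdiff(names(unlist(config$design$probabilities)),
                  config$design$standard)
  contrasts <- contrasts[intersect(names(contrasts), labs)]

  allMeasures <- list()
  allWaves <- list()
  pCounter <- 0
  for (g in config$groups) {
    simCfg <- obj$simCfg
    simCfg@tmsSuppression <- g$tms_suppression
    for (pi in seq_len(g$n_participants)) {
      pCounter <- pCounter + 1
      res <- simulateParticipant(
        seed = config$seed * 1000 + pCounter,
        design = obj$design, templates = obj$templates,
        simConfig = simCfg, preConfig = obj$preCfg,
        controlLabels = unlist(config$control$labels),
        controlReps = config$control$n_repetitions,
        channel = config$mmn$channel,
        searchWindowMs = config$mmn$search_window_ms,
        windowMs = config$mmn$window_ms, contrasts = contrasts)
      m <- res$measures
      m$group <- g$name
      m$participant <- pi
      allMeasures[[pCounter]] <- m
      allWaves[[sprintf("%s.%d", g$name, pi)]] <- res$waves
      if (pi == 1) {
        writeEventTable(res$events,
                        file.path(outDir, sprintf("events_%s_p1.csv", g$name)))
      }
      say("group %s participant %d/%d done", g$name, pi, g$n_participants)
    }
  }
  measures <- do.call(rbind, allMeasures)
  rownames(measures) <- NULL
  writeStamped(measures, file.path(outDir, "mmn_results.csv"), hash)

  ttests <- list()
  runsTab <- list()
  anovas <- list()
  groupNames <- vapply(config$groups, `[[`, "", "name")
  for (lab in names(contrasts)) {
    ampsByGroup <- list()
    for (g in groupNames) {
      sel <- function(method, session) {
        measures$peak_amplitude_uv[measures$group == g &
          measures$label == lab & measures$method == method &
          measures$session == session]
      }
      noTms <- sel("traditional", "no_tms")
      postTms <- sel("traditional", "post_tms")
      ampsByGroup[[g]] <- cbind(no_tms = noTms, post_tms = postTms)
      for (session in c("no_tms", "post_tms")) {
        ot <- oneSampleT(sel("traditional", session))
        ttests[[length(ttests) + 1]] <- data.frame(
          group = g, contrast = contrasts[[lab]], test = "one_sample_vs_zero",
          method = "traditional", session = session,
          t = ot$t, df = ot$df, p = ot$p, d = ot$d)
      }
      idAmp <- measures$peak_amplitude_uv[measures$group == g &
        measures$label == lab & measures$method == "identity"]
      if (length(idAmp) >= 2) {
        ot <- oneSampleT(idAmp)
        ttests[[length(ttests) + 1]] <- data.frame(
          group = g, contrast = contrasts[[lab]], test = "one_sample_vs_zero",
          method = "identity", session = "no_tms",
          t = ot$t, df = ot$df, p = ot$p, d = ot$d)
      }
      pt <- pairedTWithD(noTms, postTms)
      ttests[[length(ttests) + 1]] <- data.frame(
        group = g, contrast = contrasts[[lab]], test = "paired_no_vs_post",
        method = "traditional", session = "both",
        t = pt$t, df = pt$df, p = pt$p, d = pt$d)
      # pointwise session comparison under the run-length criterion
      gWaves <- allWaves[grep(sprintf("^%s\\.", g), names(allWaves))]
      getMat <- function(session) {
        do.call(rbind, lapply(gWaves, function(w) {
          wv <- w[[sprintf("traditional.%s.%s", lab, session)]]
          wv@values[wv@times >= 0]
        }))
      }
      wv1 <- gWaves[[1]][[sprintf("traditional.%s.no_tms", lab)]]
      times <- wv1@times[wv1@times >= 0]
      if (length(gWaves) >= 3) {
        wt <- sequentialPairedTests(getMat("no_tms"), getMat("post_tms"),
                                    times, config$stats$alpha,
                                    config$stats$k)
        if (nrow(wt@runs) > 0) {
          rt <- wt@runs
          rt$group <- g
          rt$contrast <- contrasts[[lab]]
          runsTab[[length(runsTab) + 1]] <- rt
        }
      }
    }
    if (length(groupNames) == 2) {
      amp <- rbind(ampsByGroup[[1]], ampsByGroup[[2]])
      grp <- rep(groupNames, times = c(nrow(ampsByGroup[[1]]),
                                       nrow(ampsByGroup[[2]])))
      an <- suppressWarnings(mixedAnova2x2(amp, grp))
      an$contrast <- contrasts[[lab]]
      anovas[[length(anovas) + 1]] <- an
    }
  }
  ttests <- do.call(rbind, ttests)
  writeStamped(ttests, file.path(outDir, "ttests.csv"), hash)
  runs <- if (length(runsTab) > 0) do.call(rbind, runsTab) else
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               n_samples = integer(0), length_ms = numeric(0),
               group = character(0), contrast = character(0))
  writeStamped(runs, file.path(outDir, "sequential_runs.csv"), hash)
  anova <- if (length(anovas) > 0) do.call(rbind, anovas) else NULL
  if (!is.null(anova))
    writeStamped(anova, file.path(outDir, "anova.csv"), hash)

  writeLines(c(
    sprintf("mmnerp %s", as.character(utils::packageVersion("mmnerp"))),
    sprintf("config_sha1: %s", hash),
    "config:",
    strsplit(yaml::as.yaml(config), "\n")[[1]]
  ), file.path(outDir, "provenance.txt"))
  say("pipeline complete: %d participants, outputs in %s", pCounter, outDir)
  invisible(list(measures = measures, ttests = ttests, anova = anova,
                 runs = runs, hash = hash))
}
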