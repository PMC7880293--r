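# Shared fixtures: everything is generated in code at test time.

# Reduced montage for expensive loops: the FCz analysis channel plus the
# two mastoids needed for re-referencing.
montage3 <- function() c("FCz", "M1", "M2")

tinyDesign <- function(nTotal = 10, seed = 1, minGap = 1) {
  oddballDesign(nTotal = nTotal, seed = seed,
                minStandardsBetweenDeviants = minGap)
}

# Build an EpochSet directly from a role sequence (e.g. c("standard",
# "deviant", ...)) with all-zero data, for exercising the design-exclusion
# rules in isolation.
epochSetFromRoles <- function(roles, fsHz = 500) {
  dt <- 1000 / fsHz
  times <- seq(-100, 300 - dt, by = dt)
  n <- length(roles)
  info <- data.frame(
    index = seq_len(n) - 1,
    label = ifelse(roles == "standard", "da1", "da4"),
    role = roles,
    sequence_kind = "oddball",
    status = "kept",
    reason = "",
    stringsAsFactors = FALSE)
  new("EpochSet", data = array(0, dim = c(n, 1, length(times))),
      times = times, fsHz = fsHz, channelNames = "FCz", info = info,
      provenance = list())
}

# Brute-force sums-of-squares oracle for the balanced 2 x 2 mixed design:
# every SS term is computed from cell/subject/session means from scratch,
# independently of the closed-form implementation it checks.
anovaOracle <- function(y, group) {
  n <- nrow(y)
  grand <- mean(y)
  subjMean <- rowMeans(y)
  gLevels <- unique(group)
  ssGroup <- 2 * sum(vapply(gLevels, function(g)
    sum(group == g) * (mean(subjMean[group == g]) - grand)^2, numeric(1)))
  ssSubj <- 2 * sum((subjMean - grand)^2) - ssGroup
  sesMean <- colMeans(y)
  ssSes <- n * sum((sesMean - grand)^2)
  ssInt <- 0
  for (g in gLevels) for (j in 1:2) {
    cell <- mean(y[group == g, j])
    ssInt <- ssInt + sum(group == g) *
      (cell - mean(subjMean[group == g]) - sesMean[j] + grand)^2
  }
  ssTot <- sum((y - grand)^2)
  ssErr <- ssTot - ssGroup - ssSubj - ssSes - ssInt
  dfe <- n - length(gLevels)
  c(tms = (ssSes / 1) / (ssErr / dfe),
    group = (ssGroup / 1) / (ssSubj / dfe),
    interaction = (ssInt / 1) / (ssErr / dfe))
}

# One simulated participant on the reduced montage; used by the recovery
# properties. Returns the traditional MMN waves and measures.
recoveryParticipant <- function(seed, nEvents = 200, noiseSdUv = 10,
                                trialJitterSd = 0.1, tmsSuppression = 0.7,
                                sessions = c("no_tms", "post_tms")) {
  simulateParticipant(
    seed,
    design = oddballDesign(nTotal = nEvents, seed = seed),
    templates = defaultErpTemplates(channels = montage3()),
    simConfig = simulationConfig(channels = montage3(),
                                 noiseSdUv = noiseSdUv,
                                 trialJitterSd = trialJitterSd,
                                 tmsSuppression = tmsSuppression),
    preConfig = preprocessConfig(),
    sessions = sessions)
}
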