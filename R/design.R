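#' Construct an oddball sequence design
#'
#' Defines a passive auditory oddball sequence with exact per-label counts:
#' `nTotal * p` events of each syllable are presented, so the nominal
#' probabilities are realised exactly rather than in expectation. Defaults
#' follow the standard three-syllable design: 1800 stimuli of which 80% are
#' the frequent standard `da1` and 10% each the phoneme deviant `ba1` and
#' the tone deviant `da4`, presented for 150 ms with a 400-ms
#' inter-stimulus interval (550-ms stimulus-onset asynchrony).
#'
#' @param nTotal total number of stimuli.
#' @param probabilities named numeric vector of presentation probabilities;
#'   must sum to 1 and give whole per-label counts.
#' @param standard name of the frequent (standard) label.
#' @param stimulusDurationMs stimulus duration, ms.
#' @param isiMs offset-to-onset inter-stimulus interval, ms.
#' @param minStandardsBetweenDeviants minimum number of standards required
#'   between two successive deviants (0 disables the constraint).
#' @param seed integer seed for the pseudorandomization.
#' @return a [SequenceDesign-class] object.
#' @examples
#' d <- oddballDesign(seed = 1)
#' tab <- generateOddballSequence(d)
#' table(events(tab)$label)
#' @export
oddballDesign <- function(nTotal = 1800,
                          probabilities = c(da1 = 0.8, ba1 = 0.1, da4 = 0.1),
                          standard = "da1",
                          stimulusDurationMs = 150,
                          isiMs = 400,
                          minStandardsBetweenDeviants = 1,
                          seed = 1) {
  new("SequenceDesign",
      nTotal = nTotal, probabilities = probabilities, standard = standard,
      stimulusDurationMs = stimulusDurationMs, isiMs = isiMs,
      minStandardsBetweenDeviants = minStandardsBetweenDeviants,
      seed = seed)
}

makeEventTable <- function(labels, design, sequenceKind) {
  soa <- design@stimulusDurationMs + design@isiMs
  roles <- stats::setNames(
    ifelse(names(design@probabilities) == design@standard, "standard", "deviant"),
    names(design@probabilities))
  n <- length(labels)
  ev <- data.frame(
    onset_ms = (seq_len(n) - 1) * soa,
    label = labels,
    sequence_kind = rep(sequenceKind, n),
    index = seq_len(n) - 1,
    stringsAsFactors = FALSE)
  new("EventTable", events = ev,
      stimulusDurationMs = design@stimulusDurationMs,
      isiMs = design@isiMs, labelRoles = roles)
}

#' Generate a pseudorandomized oddball sequence
#'
#' Lays out the exact per-label counts of the design in pseudorandom order,
#' subject to the spacing constraint that any two successive deviants (of
#' any label) are separated by at least `minStandardsBetweenDeviants`
#' standards. Deviant positions are drawn by randomly distributing the
#' non-mandatory standards over the gaps around the deviants, and deviant
#' identities are randomly permuted. Identical seeds give byte-identical
#' tables.
#'
#' @param design a [SequenceDesign-class].
#' @return an [EventTable-class] with `sequence_kind = "oddball"`, first
#'   onset at 0 ms and onsets on the SOA grid.
#' @examples
#' tab <- generateOddballSequence(oddballDesign(seed = 7))
#' nEvents(tab)
#' @export
generateOddballSequence <- function(design) {
  validObject(design)
  counts <- round(design@nTotal * design@probabilities)
  std <- design@standard
  nStd <- counts[[std]]
  devLabels <- setdiff(names(counts), std)
  devCounts <- counts[devLabels]
  nDev <- sum(devCounts)
  m <- design@minStandardsBetweenDeviants
  if (nDev > 1 && nStd < (nDev - 1) * m) {
    stopf(paste0("infeasible spacing constraint: %d deviants need at least ",
                 "%d standards to keep >= %d standards between successive ",
                 "deviants, but only %d are available"),
          nDev, (nDev - 1) * m, m, nStd)
  }
  labels <- withSeed(design@seed, {
    if (nDev == 0) {
      rep(std, nStd)
    } else {
      # gaps: standards before deviant 1, between deviants, after the last.
      nGaps <- nDev + 1
      mandatory <- c(0, rep(m, max(nDev - 1, 0)), 0)
      extra <- nStd - sum(mandatory)
      alloc <- tabulate(sample.int(nGaps, extra, replace = TRUE), nbins = nGaps)
      gaps <- mandatory + alloc
      ids <- sample(rep(devLabels, devCounts))
      out <- character(0)
      for (i in seq_len(nDev)) {
        out <- c(out, rep(std, gaps[i]), ids[i])
      }
      c(out, rep(std, gaps[nGaps]))
    }
  })
  makeEventTable(labels, design, "oddball")
}

#' Generate a same-stimulus control sequence
#'
#' Builds the control sequence of the same-stimulus (identity) MMN method:
#' `nRepetitions` identical presentations of one syllable at the oddball
#' design's stimulus-onset asynchrony, so that the physically identical
#' sound is recorded as a frequent stimulus in its own sequence.
#'
#' @param label the syllable to repeat; must be one of the design's labels.
#' @param nRepetitions number of presentations (default 400).
#' @param design the [SequenceDesign-class] supplying timing and label
#'   roles.
#' @return an [EventTable-class] with `sequence_kind = "control"`.
#' @examples
#' ctrl <- generateControlSequence("ba1", 400, oddballDesign())
#' sequenceDuration(ctrl)  # 3.667 min
#' @export
generateControlSequence <- function(label, nRepetitions = 400, design = oddballDesign()) {
  validObject(design)
  if (!(label %in% names(design@probabilities)))
    stopf("unknown label '%s'; design labels are %s", label,
          paste(names(design@probabilities), collapse = ", "))
  if (nRepetitions <= 0) stopf("nRepetitions must be > 0")
  makeEventTable(rep(label, nRepetitions), design, "control")
}

#' Total duration of a stimulus sequence
#'
#' Each stimulus occupies one stimulus-onset asynchrony (duration + ISI), so
#' the sequence lasts `nEvents * SOA`; the value is returned in minutes. The
#' default 1800-stimulus oddball sequence at 550-ms SOA lasts 16.5 min.
#'
#' @param table an [EventTable-class]; must be nonempty.
#' @return duration in minutes.
#' @export
sequenceDuration <- function(table) {
  stopifnot(is(table, "EventTable"))
  n <- nrow(table@events)
  if (n == 0) stopf("cannot compute the duration of an empty event table")
  n * (table@stimulusDurationMs + table@isiMs) / 60000
}

#' Read and write event tables as CSV
#'
#' Event tables are serialized as CSV with columns
#' `onset_ms,label,sequence_kind,index`, preceded by `#`-prefixed header
#' lines carrying the stimulus duration, ISI and label roles so the table
#' round-trips exactly.
#'
#' @param table an [EventTable-class].
#' @param path file path.
#' @return `writeEventTable` returns `path` invisibly; `readEventTable`
#'   returns an [EventTable-class].
#' @export
writeEventTable <- function(table, path) {
  stopifnot(is(table, "EventTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# stimulus_duration_ms=%g", table@stimulusDurationMs),
    sprintf("# isi_ms=%g", table@isiMs),
    sprintf("# roles=%s", paste(sprintf("%s:%s", names(table@labelRoles),
                                        table@labelRoles), collapse = ","))
  ), con)
  utils::write.csv(table@events, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(hit) != 1) stopf("malformed event CSV: missing '%s' header", key)
    sub(sprintf("^# %s=", key), "", hit)
  }
  dur <- as.numeric(getMeta("stimulus_duration_ms"))
  isi <- as.numeric(getMeta("isi_ms"))
  rolePairs <- strsplit(strsplit(getMeta("roles"), ",")[[1]], ":")
  roles <- stats::setNames(vapply(rolePairs, `[`, "", 2),
                           vapply(rolePairs, `[`, "", 1))
  ev <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  if (nrow(ev) == 0) stopf("event CSV '%s' contains no events", path)
  new("EventTable", events = ev, stimulusDurationMs = dur, isiMs = isi,
      labelRoles = roles)
}
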