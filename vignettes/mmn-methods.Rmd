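---
title: "Models and methods behind mmnerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmnerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnerp)
```

# The paradigm and the measurement

In a passive auditory oddball paradigm a frequent *standard* syllable is
interleaved with rare *deviants* while the listener ignores the sounds.
Deviants elicit the mismatch negativity (MMN), a fronto-central negative
deflection peaking roughly 150-250 ms after stimulus onset that indexes
automatic auditory change detection. `mmnerp` implements the complete
desk-side analysis for such experiments — sequence design, preprocessing,
MMN extraction, and the statistical layer — together with a synthetic EEG
generator so that every stage can be validated against known ground truth.

The default experiment is a three-syllable design: 1800 stimuli of which
80% are the standard `da1`, 10% the phoneme deviant `ba1` and 10% the tone
deviant `da4`, each 150 ms long with a 400-ms inter-stimulus interval
(stimulus-onset asynchrony, SOA, 550 ms; 16.5 min total). Same-stimulus
*control* sequences present 400 repetitions of one deviant syllable alone.
Two MMN definitions are supported:

* **traditional**: oddball deviant ERP minus oddball standard ERP. Simple,
  but the two ERPs come from acoustically different stimuli, so exogenous
  response differences contaminate the subtraction.
* **identity (same-stimulus)**: oddball deviant ERP minus the ERP of the
  *same* syllable presented frequently in its own control sequence. The
  acoustic confound cancels; only the context effect remains. The label
  match is enforced — `identityMmn()` refuses waveforms for different
  syllables.

# Sequence design

`generateOddballSequence()` uses an *exact-count* pseudorandomization:
`nTotal * p` events of each label are laid out, so probabilities are
realised as exact proportions (0.1 x 1800 = 180) and every downstream
count is deterministic. Design choices that the classical description of
the paradigm leaves open were fixed once:

* at least one standard between successive deviants by default
  (`minStandardsBetweenDeviants = 1`, configurable down to 0). The
  post-deviant exclusion rule below presupposes that standards typically
  follow deviants; the constraint is implemented by randomly distributing
  the non-mandatory standards over the gaps around the deviants, which
  errors out explicitly when the requested spacing is infeasible;
* onsets are acoustic onsets on the SOA grid, first event at t = 0 ms;
* the ISI is read as offset-to-onset, so SOA = duration + ISI = 550 ms.

# The synthetic EEG generator

The generator is first-class, tested code: its defaults *are* the study
conditions, and all recovery tests run against it.

**ERP model.** Each syllable has a template of Gaussian-envelope
components `a * exp(-(t - mu)^2 / (2 * sigma^2))`, scaled per channel by a
topography vector (FCz weight 1 by convention). No waveform model is
canonical for ERPs; Gaussians were chosen because they are smooth and
fully described by peak latency, width and amplitude. All syllables share
an exogenous N1-like (-3 uV, 100 ms, sigma 20 ms) and P2-like (+2 uV,
200 ms, sigma 30 ms) response by default, so identity and traditional MMN
coincide; label-specific exogenous components can be configured to study
the traditional method's bias. A `contextMmn` component is added *only*
when the syllable occurs as a deviant in an oddball sequence: -6 uV for
the tone contrast and -2.5 uV for the phoneme contrast (the tone MMN about
twice the phoneme MMN, matching the relative magnitudes typical of these
contrasts), peaking at 185 ms (inside the typical 175-200 ms range) with
sigma 25 ms.

**Topography.** The default weights fall off from FCz toward parietal
sites and invert at the mastoids (-0.2), as auditory generators do.
Consequently mastoid re-referencing *increases* the fronto-central MMN by
a factor 1.2 — the reason that reference is used in the first place.

**Noise and variability.** Background noise is 1/f^alpha Gaussian noise
(alpha = 1 by default, 0 = white), independent across channels, with
10 uV SD — a realistic broadband EEG scale. Trials are jittered by a
multiplicative amplitude factor `1 + N(0, 0.1)` truncated at zero. No
published single-trial variability figure exists for this paradigm; these
are package choices reported with every simulation.

**TMS suppression.** An inhibitory rTMS session is modelled *only* as a
multiplicative factor (default 0.7) on the context MMN amplitude in
`post_tms` sessions. The exogenous components are untouched, which matches
the observation that suppression effects concentrate on the
deviance-related portion of the response.

**What the generator does not emulate** — and therefore what passing
recovery tests do and do not show: there are no eye blinks or EMG bursts
(artifacts are idealised square transients for testing the amplitude
rule), no spatially correlated noise across channels, no slow drifts
beyond the 1/f tail, no latency variability between participants, and no
genuine between-subject amplitude differences beyond the trial jitter.
Recovery results validate the *pipeline arithmetic*, not the physiology.

# Preprocessing

`preprocessRecording()` fixes the stage order as resample ->
re-reference -> band-pass -> epoch + baseline -> design exclusions ->
artifact rejection, and echoes it into the epoch set's provenance.
Published descriptions of this chain are usually ambiguous about order;
this one is conventional and recorded rather than inferred.

Numerical choices:

* **Resampling** (1000 -> 500 Hz by default) is an anti-aliased polyphase
  decimator built on a zero-phase (forward-backward) Butterworth
  anti-alias filter with exact sample picking, so the new grid is exactly
  aligned with the old time axis. Group delay here would translate
  directly into spurious MMN latency shifts, which is why the filter is
  applied zero-phase.
* **Band-pass** 1-30 Hz, zero-phase Butterworth (order 4 per direction,
  giving an 8th-order magnitude response): DC is removed entirely, the
  passband is flat to within a few percent at 10 Hz, and 60 Hz is
  attenuated by more than 20 dB (both measured in the test suite).
* **Epochs** span the half-open window [-100, 300) ms on the analysis
  grid — exactly 200 samples at 500 Hz, with no double-counted boundary
  sample — baseline-corrected by the mean of [-100, 0) ms per channel and
  epoch. Onsets are mapped to the nearest sample with ties rounding
  toward negative infinity. Events without full epoch support are flagged
  (`boundary`), never silently dropped.
* **Artifact rejection** removes epochs whose absolute amplitude
  *strictly* exceeds 70 uV on any channel at any sample — a literal
  reading of "exceeding +-70 uV": an epoch peaking at exactly 70 uV is
  retained.
* **Design exclusions** remove the first 10 epochs of each sequence and
  every standard whose immediate predecessor is a deviant (its response
  carries residual deviance-related activity). Design exclusions take
  precedence over artifact rejection so that rejection rates refer to
  analyzable epochs; every input event ends up with exactly one status.

# MMN measurement

Averaging uses kept epochs only. Peaks are found as the most negative
sample within a configurable search window, 100-250 ms by default — wide
enough to bracket typical individual latencies (roughly 174-210 ms for
these contrasts) without capturing the later discriminatory negativity;
ties break toward the earliest latency and window-edge minima are flagged
`edge_peak`. The amplitude measure is the mean voltage across a 40-ms
window centered at the peak, closed on both ends on the sample grid (21
samples at 500 Hz); a window that would cross the epoch boundary is an
error, not a silent truncation. One rule is applied to traditional and
identity MMN alike.

Peak latency is determined independently per participant, contrast and
session — the convention of the empirical literature. Note a statistical
consequence, documented because the recovery tests depend on it: picking
each participant's own minimum on a noisy difference wave is *negatively
biased* (the expected measured amplitude is more negative than the true
one, and more so the weaker the signal). The package's parameter-recovery
harness therefore measures amplitudes in a window fixed at the
grand-average peak latency, which is unbiased; the per-participant rule
remains the default in `measureMmn()` for fidelity to standard practice.

# The statistical layer

* `sequentialPairedTests()` computes a two-tailed paired t test at every
  sample and reports maximal runs of consecutive samples with `p < alpha`
  of length at least `k` (default 10 samples = 20 ms at 500 Hz). The
  0-300 ms test grid is inclusive at both ends (151 samples at 500 Hz)
  when built directly; waveforms cut from the half-open epoch contribute
  150 samples (0-298 ms), which shifts run bounds by at most one sample.
  All-zero difference columns are defined as t = 0, p = 1 so degenerate
  synthetic inputs cannot crash property tests; constant nonzero
  differences are a perfect separation (p = 0).
* `runlengthFwerSimulation()` characterises the criterion under the null:
  with `k = 1` dense pointwise testing is uncontrolled (family-wise error
  far above alpha), and the family-wise error is monotone non-increasing
  in `k`; the returned per-replication maximal run lengths make the
  monotonicity directly inspectable with shared simulations. An AR(1)
  noise option exercises the criterion's behaviour under temporal
  autocorrelation, which is the realistic regime for band-passed EEG.
* `mixedAnova2x2()` implements the classical decomposition of the
  2 (session, within) x 2 (group, between) mixed design in closed form:
  the group effect tested on participant means, the session effect and
  interaction on within-participant differences, all with
  `df = (1, n1 + n2 - 2)`. With unbalanced groups the session main effect
  uses unweighted (Type III-style) marginal means and a warning is
  emitted; with balanced groups all sums-of-squares types coincide (the
  test suite checks the implementation against both `stats::aov` and a
  brute-force sums-of-squares oracle). Partial eta squared follows
  `F * df1 / (F * df1 + df2)`; paired Cohen's d is `t / sqrt(n)`. A zero
  effect sum of squares is reported as F = 0 even when the error variance
  is also zero. Following the analysis convention this package mirrors,
  the two contrasts are analysed in separate ANOVAs with no cross-test
  correction.

# Problem sizes used in validation

The full study conditions (1800-event oddball, 400-repetition controls,
11 channels, 1000 Hz) remain the generator defaults. Loops that simulate
a hundred or more virtual participants use reduced sizes, chosen once:
200-event sequences on the FCz + mastoid montage for the 100-seed
recovery property (across-seed 2 SE around 0.37 uV, comfortably below the
recovered amplitudes), and 600-event sequences for the simulated
two-group TMS study in `scripts/acceptance.R`, at which point the
per-participant standard error of the session difference (~0.4 uV) sits
well below the ~1.8 uV suppression effect. The noiseless configuration is
used wherever a property holds exactly (identity recovery to machine
precision, the post/no-TMS ratio converging to the configured
suppression factor).

# Known limitations

* EDF I/O is a minimal 16-bit implementation sufficient for round-tripping
  the package's own recordings (one sampling rate across signals,
  microvolt units); it is not a general EDF+ reader.
* No ICA or regression-based artifact correction, no bad-channel
  interpolation: artifact handling is the amplitude threshold only.
* The epoch ends at 300 ms by design, so the late discriminatory
  negativity beyond 300 ms is out of reach.
* The two-sample t test defaults to pooled variance (Welch available);
  the mixed ANOVA covers exactly the 2 x 2 design.
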