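# mmnerp

Mismatch negativity (MMN) analysis for passive auditory oddball EEG, with
a synthetic-data generator that makes the whole pipeline testable against
known ground truth.

## The problem this package addresses

The MMN is a fronto-central negative event-related potential (ERP)
component elicited ~150–250 ms after a rare (deviant) stimulus embedded in
a sequence of frequent (standard) stimuli, and indexes automatic auditory
change detection. Analysing it requires a chain of standard but
error-prone steps — sequence design, preprocessing, epoch bookkeeping,
difference-wave extraction, peak measurement, and a statistical layer with
a temporal multiple-comparisons criterion — each with conventions that are
rarely written down precisely. `mmnerp` implements that chain end to end
for researchers in auditory cognitive neurophysiology, and pairs it with a
parametric EEG simulator so every stage can be validated by parameter
recovery rather than by eye.

The experimental design at the core is a three-syllable oddball sequence:
1800 stimuli (standard `da1`, p = 0.8; phoneme deviant `ba1`, p = 0.1;
tone deviant `da4`, p = 0.1), 150-ms syllables with 400-ms ISI (550-ms
SOA, 16.5 min), plus 400-repetition same-stimulus control sequences. Two
MMN definitions are computed at the FCz electrode:

* traditional: `MMN(t) = ERP_deviant(t) − ERP_standard(t)` within the
  oddball sequence;
* identity (same-stimulus): `MMN(t) = ERP_oddball-deviant(t) −
  ERP_control(t)` for the physically identical syllable, removing the
  exogenous acoustic confound.

Amplitude is the mean voltage over a 40-ms window centered at the
individually determined peak (most negative deflection in 100–250 ms).
Session (no-TMS vs post-TMS) comparisons use pointwise paired t tests with
a run-length criterion — an effect counts only when p < 0.05 holds for at
least 10 consecutive samples (= 20 ms at 500 Hz) — plus one-sample and
paired t tests (paired Cohen's d = t/√n), and a 2 × 2 mixed ANOVA
(session × group) with partial η² = F·df1/(F·df1 + df2). A Monte Carlo
harness characterises the family-wise error of the run-length rule. An
inhibitory-rTMS session is modelled as a multiplicative suppression of the
deviance-related (context) component.

## Worked example

Simulate one virtual participant through the full chain — oddball and
control sequences, both sessions, preprocessing (500 Hz, mastoid
re-reference, 1–30 Hz zero-phase band-pass, [−100, 300) ms epochs, ±70 µV
rejection, design exclusions), MMN extraction and peak measurement:

```r
library(mmnerp)

design <- oddballDesign(seed = 2026)
oddball <- generateOddballSequence(design)
oddball
#> EventTable: 1800 events (ba1=180, da1=1440, da4=180), kind: oddball
#>   SOA: 550 ms
sequenceDuration(oddball)
#> [1] 16.5

res <- simulateParticipant(
  seed = 42,
  design = oddballDesign(nTotal = 300, seed = 42),
  templates = defaultErpTemplates(),          # tone MMN -6 uV, phoneme -2.5 uV
  simConfig = simulationConfig(noiseSdUv = 10, tmsSuppression = 0.7),
  controlLabels = c("ba1", "da4"), controlReps = 100)
res$measures[, c("contrast", "method", "session", "peak_latency_ms",
                 "peak_amplitude_uv", "n_epochs")]
#>  contrast      method  session peak_latency_ms peak_amplitude_uv n_epochs
#>   phoneme traditional   no_tms             198         -1.405644       29
#>      tone traditional   no_tms             186         -6.371054       29
#>   phoneme traditional post_tms             200         -0.117304       29
#>      tone traditional post_tms             196         -4.385395       29
#>   phoneme    identity   no_tms             180         -2.974138       29
#>      tone    identity   no_tms             182         -6.600304       29
```

The tone MMN peaks near the injected 185-ms latency at about −6.4 µV (the
−6 µV ground truth times the 1.2 mastoid re-reference gain, less window
and filter losses, plus epoch noise), and the post-TMS tone response is
suppressed by close to the configured factor: −4.39/−6.37 ≈ 0.69. The
identity MMN agrees with the traditional one because the default
templates give all syllables identical exogenous responses.

`runPipeline(readRunConfig("config.yaml"), "out/")` runs a whole
multi-participant, two-group study from one YAML configuration and writes
event tables, MMN measures, t tests, ANOVA and significant-run CSVs, every
file stamped with the SHA-1 of the configuration; identical configuration
and seed reproduce the outputs byte for byte.

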