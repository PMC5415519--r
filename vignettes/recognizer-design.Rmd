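---
title: "Designing and validating automated call recognizers with frogrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating automated call recognizers with frogrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogrec)
```

## The problem

Automated recording devices (ARDs) turn a low per-survey detection
probability into a near-certain cumulative one — with `p = 0.2` per
five-minute recording, 25 recordings give
`1 - (1 - 0.2)^25 = ` `r round(cumulative_detection(0.2, 25), 3)` — but
they bury the signal in audio that must still be searched. Call
recognizers (parameterized models of a target vocalization that scan
recordings and emit scored candidate matches) do that search, and their
error rates depend heavily on two things the analyst controls: the
training data used to build the model, and the settings of the build
variables. `frogrec` implements a complete design-and-validation
workflow for such recognizers around a wood-frog-like study system:
calls of 1–4 nearly identical syllables, hierarchical variation among
sites, among recordings within a site, and among calls within a
recording, and evaluation datasets that differ from the training data in
site, year, or region.

Because the original field recordings behind this workflow are not
publicly deposited, the package pairs the evaluation machinery with a
synthetic chorus generator, so that every claim the package makes is
testable end to end against known ground truth.

## The synthetic chorus generator

`scene_config()` + `synth_scene()` simulate mono recordings at
8 kHz containing:

* **Calls**: trains of 1–4 raised-cosine-enveloped tone pulses
  (40 ms syllables, 30 ms gaps). The dominant frequency of each call is
  `1200 Hz + site effect + recording effect + call effect`, Gaussian
  with standard deviations 60 / 25 / 15 Hz. The site level dominates, as
  assumed for territorial anurans whose call frequency tracks body size;
  the exact spectral numbers are plausible ranid-like placeholders, not
  species measurements — nothing in the framework depends on them.
* **Background noise**: white Gaussian by default, optional 1/f
  ("pink") mode.
* **Interferers**: non-target sounds at `interferer_rate_per_min`
  (default 2/min; tests and the acceptance analyses use denser values).
  70% are call-like pulse trains (1–3 pulses, 50–90 ms, wrong rhythm) at
  frequencies 100–450 Hz off the target call — close enough to the
  target band to be detected and scored mid-range, which is what creates
  realistic false-positive opportunities. The rest are chirps well above
  the detection band. Interferer amplitude rides on the same gain as the
  calls (0.5–0.9×), i.e. other species calling at comparable loudness.
* **Calibrated SNR**: the signal gain is solved per recording (by
  `uniroot` on the realized per-segment energies) so that the
  segment-based SNR estimator — mean dB over call-containing one-second
  segments minus mean dB over call-free segments, `estimate_snr()` —
  recovers the configured `snr_db` in expectation. The default, 13.3 dB,
  is a high-quality training condition; transfer experiments use values
  down to 3 dB.

Defaults describe the study conditions the package assumes throughout:
five-minute recordings, eight recordings per dataset group of which five
contain calls and three do not, and a Poisson mean of 70 calls per
call-containing recording. Tests and examples scale duration and call
counts down (typically 15–60 s recordings) purely to keep run times
short; the generator itself is size-agnostic.

What the generator deliberately does **not** emulate: reverberation and
distance-dependent propagation, weather noise regimes, recorder-specific
transfer functions, diel/seasonal call-rate dynamics, and species
mixtures. Passing tests therefore demonstrate that the *framework* —
metrics, penalty, threshold transfer, sensitivity ranking — behaves
correctly, not that any particular recognizer will reach a particular
error rate on field audio.

`build_dataset_groups()` assembles the five evaluation groups used for
transferability: `train`, `A` (same sites, new year), `B` (new sites,
same year), `C` (new sites and year), and `D` (disjoint region). Region
identity has no acoustic definition, so `D` is emulated by drawing its
site effects from a shifted, wider distribution (mean `+2` site-sd,
sd `1.5×`), optionally with a different SNR.

## The surrogate recognizer

The commercial detector that motivated this workflow is a proprietary
HMM whose internals are undocumented; the framework only requires a
detector with tunable build variables and 0–100 match scores. `frogrec`
therefore substitutes a transparent spectrogram template matcher:

1. Hann-window STFT (`fft_size`, `fft_overlap`), dB scale, restricted to
   the fixed detection band (600–2000 Hz by default).
2. Per-row running-mean background subtraction over
   `background_filter_s` seconds (window clamped to ≥ 3 frames), then a
   dynamic-range clamp at `dynamic_range_db` below the per-recording
   maximum.
3. Band energy per frame; frames above an adaptive threshold (median
   + 6 dB — a fixed, documented constant, so the tunable set stays at
   exactly nine variables) become candidate frames.
4. Candidate frames merge into syllables, bridging silent gaps up to
   `max_syllable_gap_ms`; each merged syllable remembers how many bursts
   it absorbed. Syllables longer than `max_syllable_ms` are discarded.
5. Syllables assemble into candidate songs (gap ≤ `max_syllable_gap_ms`,
   span ≤ `max_song_ms`, burst count ≥ `min_syllables`).
6. Each candidate's feature summary — the processed band spectrogram
   resampled to `feature_vector_length` frequency rows × 16 time
   columns, by block means when downsampling (point-sampling would alias
   narrow spectral lines) — is scored as
   `100 × max(0, cor(candidate, template))` against the template, the
   mean feature summary of the annotated training calls
   (`train_recognizer()`). Zero-scoring candidates are dropped.

Training features are trimmed to the above-threshold frames inside each
annotated interval, so a recording that contains an exact copy of its
single training call scores exactly 100 on it. Because burst bridging
and song assembly share `max_syllable_gap_ms`, a sub-gap setting
fragments a 4-syllable call into up to four scoring candidates — the
mechanism behind conditional sensitivity above one — while a super-gap
setting merges it into one candidate (or discards it entirely if the
merged syllable exceeds `max_syllable_ms`). This interaction is real in
the surrogate just as it was in the detector it stands in for, and it is
exactly what the variable sensitivity analysis is designed to expose.

## Metrics

`label_matches()` automates match verification against ground truth: any
positive temporal overlap with an annotated call makes a match a true
positive. The default per-match mode lets several hits claim one call
(reproducing sensitivity > 1); per-call mode assigns greedily by score,
one-to-one, and guarantees `tp + fn = n_calls` at every threshold.

* **Precision** `= tp / (tp + fp)`; `1 - precision` is the Type I
  (false-discovery) error rate.
* **Sensitivity** `= tp / n_calls`, with *all* true calls in the
  denominator, detected or not; `1 - sensitivity` is the Type II rate.
* **ROC / Youden**: positives and negatives are the verified TP and FP
  *matches*; at each observed score `t`, `tpr = |TP ≥ t|/|TP|` and
  `tnr = |FP < t|/|FP|`. The operating threshold maximizes
  `J = tpr + tnr − 1`, ties broken toward the highest threshold
  (favouring precision; configurable). Metrics reported at this
  threshold are called *conditional*.

True negatives deserve a note: "sounds that are neither calls nor
matches" are uncountable in open audio, so the TN cell is
operationalized as verified-FP matches scoring *below* the threshold.
The ROC is thus a discrimination curve over scored candidates — standard
practice for score-thresholded detectors — while conditional sensitivity
keeps the true-call denominator. These two denominators are deliberately
different.

**The subsampling penalty** (`subsample_penalty()`): when a recognizer
hits several syllables of one call, sensitivity exceeds one and would
reward syllable-chasing settings. Per repetition, if there are more TP
matches than true calls (`N`), a uniform without-replacement sample of
`N` TPs is retained (all FPs kept), the Youden threshold is *recomputed
on the reduced set*, and conditional metrics recalculated; the reported
penalized metrics are means over (by default) 1000 repetitions, and each
per-repetition sensitivity is ≤ 1 by construction. Recomputing the
threshold inside each repetition is the literal reading of the
procedure; a fixed-threshold variant sits behind
`recompute_threshold = FALSE`. When a repetition has no FPs the ROC is
undefined and a threshold of 0 (retain everything) is used.

## Variable sensitivity analysis and selection

`evaluate_grid()` varies one of the nine tunables across a grid while
holding the others at base values, rebuilding and re-running the
recognizer for each value — local, one-variable-at-a-time optimization;
a joint search over nine variables is out of scope by design. Matches
are pooled across evaluation recordings before thresholding by default
(`summary_mode = "per-recording"` averages instead; whether to pool is
genuinely ambiguous, and both are provided). `metric_cv()` summarizes
each grid as `CV = sd/mean` of the per-value conditional precision and
sensitivity; CV ≥ 0.1 flags a variable as one the metrics are sensitive
to. Penalized metrics feed the CV by default (`use_penalized = FALSE`
switches, since either reading of the procedure is defensible).

`weighted_error()` converts a (precision, sensitivity) pair into
`(w1 (1−prec) + w2 (1−sens)) / (w1 + w2)`. Normalizing by `w1 + w2`
makes schemes comparable; sensitivity is clipped at 1 so surplus hits
can never produce a negative Type II error. The standard schemes are
1:1, 5:1 and 1:5 (`default_weight_schemes()`). `select_settings()` picks
each variable's minimizer (ties → closest to base value), and
`finalize_recognizer()` rebuilds the template, computes the Youden
threshold on the training group, and freezes it.

## Training-data scaling

`build_training_subsets()` builds nested subsets of a call library along
one of the three variability axes (calls within recording, recordings
within site, sites) with the other two held fixed, via one seeded random
ordering — so level `k`'s calls are always a subset of level `k+1`'s,
and shortfalls against the targets are recorded as achieved counts with
a warning. Recognizer metrics across subsets are then modelled with
`fit_beta_regression()`: a logit-link beta regression
(`y ~ Beta(μφ, (1−μ)φ)`, constant `φ`) fitted by direct ML (`optim`,
BFGS), with boundary responses shrunk by `(y(n−1)+0.5)/n`. The canonical
CRAN implementation of this model is not among the package's
dependencies, so the likelihood is maximized in-package; an independent
ML implementation (`glmmTMB`) verifies the estimates in the test suite.
Pseudo-R² is the squared correlation between the linear predictor and
`logit(y)` — a convention, flagged as such. `aicc()` and `rank_models()`
provide small-sample AIC, Akaike weights, and evidence ratios (weights
divided).

## Transferability

`evaluate_transfer()` applies finalized recognizers to dataset groups
with their training thresholds frozen — re-thresholding on test data is
refused by a provenance check, because threshold transfer is precisely
what is being evaluated. Per group it reports conditional precision and
sensitivity plus BCa bootstrap CIs (`bootstrap_ci()`, built on the
`boot` package, 2000 replicates, percentile fallback for degenerate
samples) over recording-level metrics; the recording is the resampling
unit (eight per group). Call-free recordings contribute only to
precision (they have no sensitivity denominator); recordings with no
matches contribute only to sensitivity.

## Numerical and design choices

* Times are seconds, 0-based, half-open `[start, end)`; scores live in
  `[0, 100]`.
* All randomness flows from explicit seeds; `run_pipeline()` derives
  per-stage seeds from a single root seed, and identical configs give
  byte-identical outputs.
* Undefined metrics (zero denominators) are `NA` with a `defined` flag,
  never silent zeros; degenerate single-class training outcomes fall
  back to a threshold of 0 with the AUROC marked undefined.
* The Youden tie-break is "highest threshold among maximizers".
* WAV I/O is 16-bit PCM mono; annotation and match tables are TSV (no
  quoting ambiguity), configs YAML or JSON.

## Problem sizes used by tests and the acceptance analyses

The test suite and `scripts/acceptance.R` run the workflow on scenes of
15–120 s with 6–45 calls per recording and 2–6 sites per group — the
package's chosen desk-scale problem sizes. The acceptance analyses
report, among others: the analytic cumulative detection value; AUROC and
penalized conditional metrics of the base recognizer on a simulated
training group; the balanced recognizer's conditional metrics and its
transfer means over groups A–D; a Monte-Carlo vs exact-enumeration check
of the subsampling penalty (`|TP| = 6`, `N = 4`, 100,000 repetitions);
an SNR synthesis round-trip at the 13.3 dB training condition; and BCa
coverage for a normal mean.

## Known limitations

* The surrogate scorer is a template correlator, not an HMM; absolute
  scores and optimal settings are not comparable to any commercial
  detector, only the design procedure is.
* Overlapping calls can merge into one candidate; the per-match/per-call
  labelling modes bracket, but do not resolve, that ambiguity.
* With `feature_vector_length = 4`, calls differing only by fine
  spectral structure are indistinguishable — intentional for a simple
  1–4-syllable call, limiting for complex vocalizations.
* Beta-regression dispersion is constant; dispersion covariates are not
  modelled.
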