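# frogrec

Design and validation of automated call recognizers for bioacoustic
monitoring.

Automated recording devices make detecting a calling species nearly
certain — 25 five-minute recordings at a per-survey detection
probability of *p* = 0.2 give a cumulative detection probability of
1 − (1 − *p*)^*N* = 0.996 — but someone still has to find the calls in
the audio. Recognizers (models of a target vocalization that scan
recordings and emit matches scored 0–100) automate that search, and
their Type I (false discovery) and Type II (missed call) error rates
depend strongly on how they are built. `frogrec` implements, for a
wood-frog-like study system with 1–4-syllable calls, the full
design-and-validation loop:

* **Synthetic choruses** with ground truth: hierarchical call-frequency
  variation (site / recording / call), calibrated segment-based SNR,
  call-free recordings, and non-target interferers that create false
  positives (`scene_config()`, `synth_scene()`,
  `build_dataset_groups()`).
* **A surrogate recognizer** with nine tunable build variables (FFT
  size, overlap, background filter, dynamic range, syllable/gap/song
  limits, minimum syllables, feature vector length) over a fixed
  frequency band, scoring candidates by template cross-correlation
  (`recognizer_settings()`, `train_recognizer()`, `detect()`).
* **Threshold-conditioned evaluation**: precision = tp/(tp+fp),
  sensitivity = tp / (all true calls) — which can exceed 1 when several
  syllable hits land on one call — at the threshold maximizing Youden's
  *J* = sensitivity + true-negative rate − 1 on the match-level ROC
  (`label_matches()`, `roc_and_threshold()`, `conditional_metrics()`),
  plus the subsampling penalty that bounds sensitivity at 1 by retaining
  at most *N* = (number of true calls) TP matches per randomization
  (`subsample_penalty()`).
* **Variable sensitivity analysis**: one-variable-at-a-time grids,
  ranked by CV = sd/mean of the conditional metrics, and selection of
  final settings by weighted Type-I/II error cost (1:1, 5:1, 1:5)
  (`evaluate_grid()`, `metric_cv()`, `select_settings()`).
* **Training-data scaling**: nested subsets along the three variability
  axes, logit-link beta regressions of the metrics, and AICc model
  selection with Akaike weights and evidence ratios
  (`build_training_subsets()`, `fit_beta_regression()`, `rank_models()`).
* **Transferability**: selected recognizers applied to dataset groups
  differing in sites, year, or region, with training thresholds frozen
  and BCa bootstrap CIs (`evaluate_transfer()`, `bootstrap_ci()`,
  `cumulative_detection()`).

`run_pipeline()` chains all stages from one YAML/JSON config with full
seed control; `inst/scripts/frogrec-cli.R` exposes the stages as shell
subcommands. See the vignette (`vignettes/recognizer-design.Rmd`) for
the model details and design choices.

## Worked example

```r
library(frogrec)
cfg <- pipeline_config(list(
  scene = list(n_sites = 4, duration_s = 30, calls_per_recording = 10,
               interferer_rate_per_min = 12, seed = 7),
  grids = list(max_syllable_gap_ms = c(15, 50, 120),
               dynamic_range_db = c(30, 50, 70)),
  penalty_reps = 50, bootstrap_reps = 200, seed = 7))
res <- run_pipeline(cfg, out_dir = file.path(tempdir(), "demo"))

res$ranking[, 1:3]
#>              variable cv_precision cv_sensitivity
#> 1    dynamic_range_db   0.07550755    0.065360408
#> 2 max_syllable_gap_ms   0.05528332    0.006765823

res$selected$balanced
#> Selected recognizer (weights 1:1): mean weighted error 0.080
#>   frozen threshold 31.68 (source: train)
#>             variable value weighted_error
#>  max_syllable_gap_ms    50     0.08040936
#>     dynamic_range_db    50     0.08040936

subset(res$transfer, recognizer == "balanced",
       select = c(group, precision, sensitivity, threshold))
#>   group precision sensitivity threshold
#> 1 train 0.9444444   0.8947368  31.68068
#> 2     A 0.9032258   0.9333333  31.68068
#> 3     B 0.9166667   0.9565217  31.68068
#> 4     C 0.8518519   0.9200000  31.68068
#> 5     D 0.4642857   0.6190476  31.68068
```

Reading this: on the simulated training group the balanced (1:1
error-cost) recognizer operates at score threshold 31.68 with
conditional precision 0.94 and conditional sensitivity 0.89 — i.e.
Type I error 0.06, Type II error 0.11. With the threshold frozen, it
transfers with little loss to groups sharing the training region (A–C)
but degrades sharply in the acoustically disjoint region D (precision
0.46), the pattern that motivates holding out genuinely out-of-sample
recordings when validating a recognizer. The CV table ranks how strongly
each build variable moved the conditional metrics across its grid.

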