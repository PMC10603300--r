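# coupledraw

When people draw a vertical line with one hand and a circle with the other,
the movements interfere: lines bulge outward, circles flatten. The strength
of this *interlimb coupling* varies trial by trial, and `coupledraw` asks
which representation of simultaneously recorded motor-cortical EEG predicts
it:

* **univariate** — event-related desynchronization (ERD): one value per
  channel and band (9 channels × alpha/beta = 18 candidate correlates);
* **distributed univariate** — magnitude-squared coherence between motor
  channel pairs, averaged over frontal-central, central and
  central-parietal groups (3 groups × 2 bands = 6 candidates);
* **multivariate** — a shallow 3600–100–1 feedforward regressor over the
  band-resolved time-frequency pattern of all nine channels, trained with
  variable-learning-rate backpropagation and early stopping over repeated
  random 85/5/10 trial splits, each trial's prediction averaged over the
  iterations in which it was held out.

Behaviour is summarised per trial by the coupling index

    CI = 1 / max(|C_left - C_right|, floor),   C_hand = |max(x) - min(x)|,

the reciprocal difference of the two hands' horizontal drawing extents in
pixels: the more similar the drawn shapes, the larger CI.

No public recording of this task exists, so the package includes a fully
seeded synthetic session generator (pen trajectories *and* 256 Hz EEG for
240 trials, 60 per condition) with a known ground-truth coupling drive and
configurable encodings — including a distributed *nonlinear* code that is
provably invisible to every single-channel and coherence readout yet
recoverable by the network. That turns the central claim — multivariate
beats univariate — into a falsifiable property checked by the test suite.

The package is intended for methodologists studying motor EEG analysis
pipelines: every stage (filtering, epoching, Morlet log-ratio maps, ERD,
coherence, the network, the correlation reports) is an exported, tested
function.

## Worked example

```r
library(coupledraw)

cfg <- session_config(encoding_mode = "distributed_nonlinear", snr = 1, seed = 2)
session <- generate_session(cfg)

summarise_conditions(session$behaviour)
#>       condition  n c_left_mean c_left_sd c_right_mean c_right_sd  ci_mean   ci_sd
#> 4     line-line 60       107.6      23.2        111.6       18.1 0.086951 0.08188
#> 1 circle-circle 60       367.4      19.4        389.1       24.0 0.079782 0.09650
#> 3   line-circle 60       156.2      23.9        318.2       27.1 0.006873 0.00279
#> 2   circle-line 60       306.5      25.0        164.3       20.4 0.007694 0.00260
```

Lines drawn against a circle are ~50 px wider than lines drawn against
another line, circles against a line ~60 px narrower than pure circles —
the interference signature — and the coupling index is an order of
magnitude higher in congruent (~0.08) than incongruent (~0.007)
conditions.

```r
sp  <- spectral_features(session$eeg)    # 18 ERD values + 3600-long pattern per trial
coh <- coherence_table(session$eeg)      # 6 coherence values per trial
ann <- iterate_splits(sp$features, session$behaviour$ci, n_iter = 50, seed = 3)

ci_tab <- data.frame(trial_id = session$behaviour$trial_id, ci = session$behaviour$ci)
compare_approaches(list(correlate_erd(sp$erd, ci_tab),
                        correlate_coherence(coh$coherence, ci_tab),
                        evaluate_ann(ann$predictions, ci_tab)))
#>    approach n_features max_abs_r n_significant ann_beats_this
#> 1       erd         18    0.1285             0           TRUE
#> 2 coherence          6    0.0702             0           TRUE
#> 3       ann          1    0.7803             1             NA
```

None of the 18 ERD or 6 coherence correlations is significant (the
largest, |r| = 0.13, sits below the permutation-null familywise 95% bound
of 0.197), while the network's averaged held-out predictions correlate
with the actual coupling index at r = 0.78 across the 240 trials (mean
per-iteration test r = 0.50 over 136 iterations — 50 requested plus the
automatic extension that guarantees every trial at least 5 test
appearances). Switch `encoding_mode` to `"univariate"` and the same ERD
report flags C3-alpha at r ≈ 0.77 — the pipeline finds single-channel
structure when it is there.

## Analysis workflow

`analysis/` contains the numbered end-to-end workflow, each a thin driver
over the package functions, writing its tables under `results/`:

    01_simulate_session.R      simulate the nonlinear + univariate sessions
    02_behavioural_coupling.R  curvature, CI, condition summaries
    03_spectral_features.R     ERD table + 3600-feature matrix per session
    04_coherence.R             6 group x band coherence values per trial
    05_ann_prediction.R        iterated-split network predictions
    06_compare_approaches.R    correlation reports, permutation bound, figure

Run them in order with `Rscript analysis/01_simulate_session.R` etc., or
run everything in memory with `run_pipeline(pipeline_config(), "results/run")`.

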