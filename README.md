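# actbind

Analysis toolkit for **action binding** experiments: when a voluntary
keypress produces a delayed effect (a tone 250 ms later), the reported
time of the keypress shifts *toward* the tone. `actbind` implements the
complete analysis path for Libet-clock studies of this effect in which
keypress force is recorded with a force sensing resistor (FSR), together
with a generative model of the task so that every stage can be exercised
and validated on synthetic data with known ground truth.

## The model at the core

The reported keypress time is treated as a weighted combination of two
time cues:

- a **somatosensory cue** `S(F)`, tied to the force profile of the press
  (`S = s_base + s_latency_gain * peak_latency(F)`; stronger presses
  peak later, so their somatosensory cue is later), and
- an **auditory cue** `A`, the action-effect delay (250 ms).

In the action-only condition (AO, no tone) the report tracks `S` alone
(`B1 = 1`). In the action-sound condition (AS) the report is

```
report = B1(F) * S(F) + B2(F) * A,   B1 + B2 = 1,
B1(F) = 1 - weight_scale * exp(-weight_slope * F)
```

with the somatosensory weight `B1` increasing in peak force `F`. The
model predicts the full observed pattern: a positive within-participant
correlation between peak force and reported time in AO, a negative one
in AS, and a *smaller* binding effect (AS − AO) for stronger presses.

Around that model the package provides:

- `fit_calibration()` / `raw_to_newton()` — monotone polynomial
  conversion of raw FSR units (0–1023) to Newtons;
- `generate_dataset()` — synthetic cohorts with digitized force traces,
  Libet-clock reports (1800 ms period, 10 ms resolution) and
  per-participant heterogeneity;
- `compute_trial_features()`, `reject_trials()`,
  `exclude_participants()` — peak force / peak latency extraction in the
  800 ms post-press window and the standard rejection cascade
  (450 ms median rule, 3 SD rules, force-validity rule; 30-trial and
  −100 ms participant exclusions);
- `skipped_pearson()` — robust correlation with projection-based
  bivariate outlier detection and a percentile-bootstrap CI;
- `binding_per_participant()`, `group_binding_test()`, `rm_anova_2x2()`,
  `precision_analysis()` — binding quantification (per-participant
  two-sample *t*), one-tailed group tests with Cohen's *dz*, 2×2
  within-subject ANOVA with partial eta squared, and report-precision
  (SD) analysis;
- `power_resample()` / `min_n_for_power()` — participant-resampling
  bootstrap power curves over sample sizes;
- `run_pipeline()` — the whole chain under one seeded YAML-configurable
  entry point.

## Worked example

```r
library(actbind)

trials <- generate_dataset(42, 60, design = "study1", master_seed = 2020)
pp     <- preprocess(trials)
res    <- analyze_study1(pp$trials, n_boot = 1000, seed = 2020)

res$corr_tests
#> # A tibble: 2 × 8
#>   condition    mean    sd     n     t    df      p     dz
#>   <chr>       <dbl> <dbl> <int> <dbl> <dbl>  <dbl>  <dbl>
#> 1 AO         0.0361 0.176    42  1.32    41 0.193   0.204
#> 2 AS        -0.0746 0.189    42 -2.56    41 0.0142 -0.395

res$binding
#> # A tibble: 1 × 7
#>   mean_as mean_ao mean_diff     t    df        p    dz
#>     <dbl>   <dbl>     <dbl> <dbl> <dbl>    <dbl> <dbl>
#> 1    61.9    32.1      29.8  3.99    41 0.000134 0.616

res$binding_vs_as_r
#> <skipped_corr> r = -0.266 on 41 points (1 outlier removed)
#>   bootstrap 95% CI [-0.680, 0.194] (1000 resamples)
```

Reading the output: the mean within-participant correlation between
peak force and reported time is positive in AO and negative in AS —
the signature of force-weighted cue integration. The group binding test
shows reports in AS shifted ~30 ms toward the tone (one-tailed paired
*t*(41) = 3.99, *dz* = 0.62), and participants with a more negative AS
coupling (stronger auditory integration) tend to show larger binding
(skipped Pearson r = −0.27).

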