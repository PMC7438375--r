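---
title: "Methods: force-weighted cue integration and the action-binding pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-weighted cue integration and the action-binding pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actbind)
```

## The scientific problem

In a Libet-clock experiment, a participant presses a key at a
self-chosen moment while watching a clock hand that revolves every
1800 ms, and afterwards reports the hand position at the time of the
press. When the press triggers a tone 250 ms later (the action-sound
condition, AS), the reported press time shifts toward the tone relative
to a no-tone baseline (action-only, AO). This forward shift is the
*action binding* effect.

`actbind` treats the reported press time as the output of a
multisensory cue-integration process. A keypress has no physical time
*point* — key contact lasts on the order of 150 ms — so the reported
time must be constructed from cues. Two are available: the
somatosensory sensation of the press, and (in AS) the tone. The model
is a reliability-weighted average:

$$\mathrm{report} = B_1(F)\,S(F) + B_2(F)\,A,\qquad B_1 + B_2 = 1 .$$

Here $S(F)$ is the time carried by the somatosensory cue, $A$ the
auditory cue (the 250 ms delay), and $B_1$ the somatosensory weight. In
AO, $B_1 \equiv 1$. Two mechanisms tie the model to keypress force $F$:

1. **The somatosensory cue arrives later for stronger presses.**
   Force-profile landmarks (peak force among them) occur later when
   more force is produced. We model the peak-force latency as linear
   in peak force and tie the cue to it:
   $S = s_\mathrm{base} + g_S \cdot \mathrm{latency}(F)$.
   In AO this predicts a *positive* within-participant correlation
   between peak force and reported time.
2. **Stronger presses weight the somatosensory cue more.** We use
   $B_1(F) = 1 - w\,e^{-kF}$, clipped to $[0,1]$: smooth,
   non-decreasing in $F$, equal to $1-w$ at zero force. Since the
   auditory cue is much later than the somatosensory one, a larger
   $B_1$ pulls the AS report *earlier* — a *negative* force-report
   correlation in AS, and less binding for strong presses.

Any smooth non-decreasing map would express mechanism 2; the
exponential form was chosen because it has interpretable endpoints
(`weight_scale` $= 1 - B_1(0)$ is the maximal auditory influence,
`weight_slope` sets how quickly force squeezes it out) and two
parameters only. The weights are not fitted to data anywhere in the
package: the task never identifies them trial by trial, so the
generator's weights are calibration targets, not estimates.

### A note on the two opposing mechanisms

Mechanism 1 moves the AS report later with force; mechanism 2 moves it
earlier. The model's predicted negative AS correlation therefore holds
only while the integration term dominates, i.e. while
$k\,(1-B_1)\,(A-S) > B_1\,S'(F)$. With the default parameters that is
the case below roughly 2.2 N — which covers free pressing
(mean ~1.4–1.7 N) and the light-press regime where the prediction is
scientifically at stake. Above that force the somatosensory weight has
saturated near 1 and the AS condition behaves like AO. The
monotonicity test in the suite asserts the decreasing AS pattern on
0.2–2.0 N for exactly this reason; asserting it globally would demand
something the weighted-average model itself cannot promise.

## The synthetic-data generator

`generate_dataset()` simulates whole cohorts under two designs:
`study1` (AO/AS under free pressing) and `study2` (AO/AS crossed with
enforced light and strong force windows). Defaults express the study
conditions:

| parameter | default | why |
|---|---|---|
| `sound_delay` | 250 ms | the action-effect delay of the paradigm |
| `clock_resolution` | 10 ms | 2° hand steps on an 1800 ms clock |
| `s_base`, `s_latency_gain` | 0, 0.6 | mean AO report ≈ 30–35 ms after the press for latencies near 56 ms |
| `weight_scale`, `weight_slope` | 0.35, 1.0 | mean free-press binding ≈ 25–30 ms; negative AS coupling of about −0.05 to −0.10 |
| `report_noise_sd` | 80 / 80 / 72 ms (free/light/strong) | trial-level report SD near 80 ms; stronger presses yield more precise reports |
| `peak_force_mean` | 1.72 / 1.44 N (free AO/AS), 1.18, 3.10 N | free AS presses are lighter than AO; light/strong means sit inside the enforced windows |
| light / strong windows | 1.06–1.31 N, 2.57–4.01 N | the experimentally accepted raw ranges 350–450 and 700–800 |
| `latency_intercept`, `latency_gain`, `latency_noise_sd` | 32 ms, 14 ms/N, 30 ms | mean peak latency ≈ 56 ms at free forces; within-participant force–latency correlation ≈ 0.23 |
| `sampling_rate` | 518 Hz | the force sensor's rate |
| `press_duration_mean` | 149 ms | registered key-contact duration |

Between-participant heterogeneity (all SDs): stable report bias 45 ms,
per-condition block bias 35 ms (conditions run in separate blocks),
free-press mean force 0.35 N, integration strength (`weight_scale`)
0.15, latency intercept 8 ms. The block-bias term is what keeps the
group binding effect size near $d_z \approx 0.6$ rather than the
implausibly large value a pure trial-noise model would give.

Force traces are emitted as the sensor would see them: a unimodal
gamma-like pulse $F(t) = P\,(t/t_p)^3 e^{3(1-t/t_p)}$, digitized to
integer raw units in [0, 1023] through the inverse calibration, with
1 raw unit of sensor noise. The sample nearest the nominal peak is
pinned to the digitized peak value, so feature extraction recovers the
generated peak force to within one quantization step and the latency to
within one sample — that round trip is what makes the generator usable
as ground truth.

**What the generator does not emulate:** eye movements and other
visual-report biases, motor-intention timing, EMG onset, sequential
(trial-order) effects, non-Gaussian report errors, and any trial-to-
trial coupling between report noise and force beyond the
condition-level SDs. Passing tests on synthetic data therefore
demonstrate that the pipeline's estimators recover the generative
pattern they target — not that real data satisfy the model.

## Preprocessing conventions

- Reported time = signed angular distance from the press-time hand
  position to the reported position, wrapped to the nearest offset
  (±900 ms), at 5 ms/degree. The wrap choice is safe because the
  rejection cascade removes anything beyond 450 ms from the condition
  median anyway.
- Peak force = maximum calibrated sample in the 800 ms window from the
  press; ties go to the earliest sample; traces ending early are
  scanned over their available portion and flagged.
- "No reliable force" = no calibrated sample at or above 0.1 N in the
  window (the task itself provides no threshold; 0.1 N is far below
  any accepted press and above sensor noise).
- The rejection cascade is sequential, per participant × condition
  (× force condition): (1) |report − median| > 450 ms; (2) among
  survivors, |report − mean| > 3 SD; (3) invalid force; (4) among
  survivors, |peak force − mean| > 3 SD. SDs are sample SDs of the
  survivors at the stage where the rule runs; zero or undefined SDs
  remove nothing. Only rule 1 is idempotent by construction —
  re-running the cascade can in principle remove more under rules 2/4,
  which is inherent to any sequential mean/SD rule.
- Participants are excluded when any condition retains fewer than 30
  trials, or when any condition-*mean* report is below −100 ms. The
  mean (not median) is used as the summary, and the inequality is
  strict: a participant at exactly −100 ms survives.

## Robust and inferential statistics

- **Skipped Pearson correlation.** Axes are robust-standardized
  (ideal-fourths IQR; SD fallback when over half the values tie), the
  coordinatewise median serves as center, and every point defines an
  outward projection direction; a boxplot rule with ideal-fourths
  fences at 1.5 IQR flags extreme projections, and the union of flags
  is removed before Pearson's r. Standardizing first is what makes the
  flags — and hence r — invariant under positive affine transforms of
  either axis. The 95% CI is a percentile bootstrap of the *entire*
  procedure (outlier re-screening inside every resample): bootstrapping
  only the retained pairs measurably under-covers, while the
  full-procedure bootstrap is slightly conservative, which we prefer.
- **Group-level tests on correlations** compare the raw mean
  coefficient to zero with a one-sample t (no Fisher z), because the
  quantity of scientific interest is the average coefficient itself.
- **Binding size** per participant is the pooled-variance two-sample t
  between AS and AO trial-level reports (pooled rather than Welch: the
  two blocks share the measurement apparatus and noise model), and the
  group test is a one-tailed paired t with the direction (AS > AO)
  fixed a priori. One-tailed directions are never chosen post hoc: the
  binding direction and the negative binding-integration correlation
  are the model's predictions.
- **2×2 within-subject ANOVA** uses `aov` with an
  `Error(id/(A*B))` stratification; each effect is tested against its
  own participant-by-effect error term, partial eta squared is
  $SS_e/(SS_e+SS_{err})$, and with two-level factors no sphericity
  correction exists to apply. The identity $F(1, n-1) = t^2$ of the
  contrast paired-t is used as an independent oracle in the tests. A
  literally flat dataset yields 0/0; we define F = 0, p = 1 there (no
  evidence of an effect), and likewise t = 0, p = 0.5 for a paired
  test whose differences are all exactly zero.
- **Normality checks** use the Lilliefors statistic (with either the
  Dallal–Wilkinson approximation via `nortest` or a seeded Monte-Carlo
  null) and the Jarque–Bera statistic with a χ²(2) reference and a
  Monte-Carlo option for small n.

## Bootstrap power analysis

`power_resample()` estimates detection probability by drawing
participant subsets *without replacement* from the cohort and running
the detection test per draw — the post hoc, cohort-bounded notion of
power appropriate when no population model is assumed. Detectors:
the one-sample t on per-participant correlations, and the paired t on
per-participant 2 N slope changes (the regression of report on peak
force scaled to a 2 N increase) between AS and AO — the latter is our
choice of statistic for the force × binding interaction, which the
procedure's definition leaves open. Near the full cohort size the
number of distinct subsets collapses (exactly one subset at full size),
so the function warns that very high power estimates there deserve
caution. Seeds: one master seed spawns an independent derived seed per
(size, repetition) cell, so curves are reproducible and effect-scaling
comparisons can share draws.

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 42 participants
× 60 trials per condition (the analysed cohort size of the free-press
design) for the sign-pattern checks, and 1000-repetition power curves
over sizes 20–42; unit tests use smaller cohorts where the property
under test does not depend on size. All randomness flows from explicit
master seeds; identical seeds give byte-identical trial tables,
analyses and power curves.

## Known limitations

- The generator's weights are calibrated to summary statistics, not
  estimated from data; the package deliberately contains no fitting
  routine for $B_1$.
- The skipped-correlation outlier rule is one member of a family
  (boxplot-rule variants differ in fence constant and center); the
  implementation fixes ideal-fourths fences at k = 1.5 and records
  that choice in the result object's provenance rather than offering
  an estimator zoo.
- Without-replacement power curves cannot exceed the information in
  the cohort at hand; they are interpretable as guidance, not as
  population power.
- The precision analysis uses the per-cell SD of reports; it does not
  model the quantization floor (10 ms) separately, which slightly
  inflates SDs for very precise participants.
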