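---
title: "Single-item ERP preference discrimination: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-item ERP preference discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sierp)
```

This vignette documents the scientific choices behind `sierp`: what the
procedure assumes, how the synthetic generator is built, which parameters
matter, and the numerical conventions that make the results exactly
reproducible. It states no empirical figure that the test suite or the
`analysis/` scripts do not themselves compute.

## The discrimination procedure

The question is whether the ERP evoked by a single product is informative
about its behavioural preference rank. The procedure turns that into a
family of paired contrasts. For each participant, item-level waveforms are
averaged from artifact-free trials, reduced to an anterior ROI trace
(F3/Fz/F4) for the N200 and a posterior ROI trace (P3/Pz/P4) for the late
positivities, and scored per window. The single-item score is compared to
the scores of the HP and LP *group* waveforms; the group average always
excludes the item under test, so an item never contributes to its own
reference. Across 12 items, two references and six windows that is a
family of 144 two-tailed paired t-tests, corrected with Benjamini–Hochberg
FDR, after which each item × window cell is judged by one of two logical
criteria (rank 1–6: significantly above LP and not significantly below HP;
rank 7–12: the mirror image).

Assumptions worth making explicit:

- The contrasts are paired t-tests across participants. The design is
  repeated-measures, and the published degrees of freedom are consistent
  with that choice, but normality of the paired differences is assumed,
  not tested. A rank-based alternative would need its own calibration.
- "x ≥ HP" is operationalised as *not significantly lower than HP*, which
  deliberately admits "significantly higher"; symmetrically "y ≤ LP"
  admits "significantly lower". An HP item that beats its own group is
  treated as more, not less, consistent with its rank.
- The direction of a contrast is the sign of the across-participant mean
  difference, not a per-participant majority vote.

### FDR family

The contrast family defaults to the single family of all 144 tests
(`apply_fdr(..., family = "all")`), which is how the correction is
described in the source analysis; a per-window family of 24 tests is
available. Re-running the step-up on the *printed, rounded* p-values of
the packaged summary table reproduces 143/144 of the printed significance
flags under the single family and 142/144 per window
(`analysis/01_reproduce_published_table.R` prints both). Neither choice
reproduces the flags perfectly from rounded inputs, which is expected —
three-decimal p-values straddle the step-up thresholds — so the printed
flags themselves are treated as authoritative when reproducing the
published verdict grid, and the recomputation is reported as a diagnostic
only.

### Degenerate contrasts

Zero-variance differences cannot be t-tested. Two cases are separated:
identical score vectors report t = 0, p = 1 and no direction (the cell can
then never pass a criterion, which is the conservative reading), while a
constant non-zero difference is reported with p = 0, the sign as its
direction, and an explicit `degenerate` flag plus a warning. The same
convention is used for the behavioural HP-vs-LP paired test.

## The synthetic generator

The generator emulates the study design it is meant to exercise: 36
participants, 12 products shown 30 times each (360 viewing epochs), epochs
from −200 to 3000 ms at 512 Hz, a pairwise-choice task of 66 pairs × 7
blocks (462 choices, any item choosable at most 77 times), and a BDM
willingness-to-pay auction from a budget of 50 currency units.

Each epoch is a sum of four component templates, scaled by topography and
a preference-dependent amplitude, plus noise:

- **P200**: Gaussian, centre 180 ms, SD 30 ms, base +6 µV, anterior
  topography; slope 0 by default (carrier for the peak-to-peak measure).
- **N200**: Gaussian, centre 300 ms, SD 50 ms, base −8 µV, anterior;
  default slope +0.2 µV per utility unit, so preferred items have a
  *less deep* N200, matching the polarity of the group-level effects.
- **LPP**: Gaussian, centre 600 ms, SD 120 ms, base +3 µV, posterior;
  slope +0.35.
- **PSW**: smoothed boxcar spanning 800–3000 ms (logistic edges, 50 ms),
  base +1.5 µV, posterior; slope +0.3.

With item utilities at their default `seq(12, 1)` these slopes produce
HP-minus-LP group differences of roughly 1.5–2 µV, the order of magnitude
of the published group means. Amplitudes receive a per-participant
additive offset (SD 1.5 µV) and a multiplicative lognormal trial jitter
(σ = 0.3, mean 1), so that 16–30-trial averages have realistic
signal-to-noise behaviour. Trial noise is a mixture of white and 1/f
(pink) noise at total SD 12 µV, half of the variance pink. A configurable
fraction of trials (default 5%) receives a single-sample 200 µV spike,
which trips both rejection rules; these trials are flagged as generator
ground truth so the rejection stage can be validated against them.

Randomness is organised as one master seed with fixed per-participant
substream offsets (1009 for epochs, 2003 for choices, 3001 for bids), so
identical truths give bit-identical data and the behavioural and EEG
streams can be regenerated independently.

### Behavioural model

Choices follow a Bradley–Terry/logistic rule on per-participant utilities
`u_p = u + N(0, utility_subject_sd)`. The two noise parameters are not
identified by any published statistic, only constrained by two magnitudes:
the mean inter-subject correlation of choice counts (≈ 0.45) and the
fraction of pairs with more than two choice switches across blocks
(≈ 9%). `choice_temperature = 1` and `utility_subject_sd = 3.75` were
chosen once to land near both (the packaged simulation study prints
r_mean ≈ 0.5 and a switch fraction ≈ 0.12 at its reduced size) and are not
revisited. Bids are `clip(3.5 · u_p + N(0, 5), 0, 50)`; the hidden BDM
price is uniform on the budget.

### What the generator does not emulate

There is no head model and no volume conduction — topographies are direct
per-channel weights; no ocular or muscle artifacts beyond the
threshold-tripping spikes; no reaction times; no habituation across the 30
presentations; no re-referencing stage (epochs are generated as already
referenced, since re-referencing is linear and would cancel in every
contrast). Passing tests on this generator therefore validate the
*statistical machinery* — averaging, rejection rules, leave-one-out
references, FDR, criteria logic, ANOVA — not the neurophysiological
realism of any particular dataset.

## ERP quantification conventions

- **Baseline**: mean over [−200, 0] ms subtracted per epoch and channel;
  idempotent by construction.
- **Rejection**: an epoch is rejected when any channel exceeds a 120 µV
  max-minus-min range or a 75 µV step between adjacent samples, evaluated
  after baseline correction. Participants keeping fewer than 16
  artifact-free trials for any item are excluded ("at least 16" keeps a
  participant at exactly 16).
- **Windows**: mean-amplitude windows are half-open `[start, end)` so the
  consecutive late windows partition time without sharing samples; peak
  search windows are closed on both ends so boundary extrema count. The
  N200 peak-to-peak score is (minimum over 200–400 ms) − (maximum over
  130–230 ms); because the windows overlap at 200–230 ms the score is
  never positive, and it is invariant to constant offsets. Ties between
  equal extrema resolve to the earliest sample.
- **Group averages** weight items equally rather than by trial count,
  which makes the leave-one-out identity
  `loo_i = (k·mean − w_i)/(k − 1)` exact and is tested to 1e−10.
- **Filtering**: a zero-phase 4th-order Butterworth 0.01–30 Hz band-pass
  is available but off by default — the generator is already band-limited,
  and the original filter design is not specified precisely enough to
  reproduce.
- The supplementary mean-amplitude N200 variants (200–400 ms and
  228–344 ms) are scored over the same anterior ROI as the peak-to-peak
  measure; their original ROI is not documented, so this assumption is
  recorded here.

One known bias is worth stating: extremum-based measures are not linear,
so a single-item average (fewer trials, noisier) has a slightly more
extreme expected peak than a group average. Under the slope-free null this
inflates raw p-values mildly in the N200 window; with BH correction over
the full family the realized significant-contrast rate in the packaged
null study remains around 0.002, far below α, so the calibration
properties hold regardless.

## Group-level replication analysis

Per-electrode scores over the nine-electrode grid are collapsed into the
2 × 3 × 3 Preference × AP × LAT design; a cell is the mean score of the
six group items at that electrode (the mean-of-scores convention; for the
nonlinear peak-to-peak measure this is an approximation to re-scoring a
pooled group waveform, exact for all window means). The ANOVA computes
each within-subject effect from orthonormal Helmert contrast scores, with
the Greenhouse–Geisser epsilon estimated per effect from its own contrast
covariance — epsilon is exactly 1 for single-df effects, reproducing the
F(1, n−1) pattern for the 2-level Preference factor — and is applied to
every multi-level effect, with uncorrected values also reported (the
"when necessary" policy of the source is not recoverable). The
implementation is verified against `stats::aov` error strata to 1e−8 on
random balanced data, and effects whose sums of squares are pure
floating-point dust (relative magnitude below 1e−12 of the total
within-subject SS) are reported as exactly null rather than as a 0/0
ratio. Simple effects of Preference use the per-level paired contrast
(robust to sphericity violations), and the five late-window Preference
tests are Bonferroni-corrected by the fixed family size 5.

The behavioural one-sample t-test on inter-subject correlations uses raw
r (its degrees of freedom match the published n_pairs − 1 = 629 phrasing);
a Fisher-z variant was considered and rejected as it would change the
stated df.

## Problem sizes of the packaged studies

The simulation studies in the tests and `analysis/` scripts run at
reduced sizes chosen as the package's own working points: 12 participants,
12 trials per item and 32 Hz sampling for the replicated null-calibration
and recovery studies (200 and 100 replicates respectively in the test
suite), and 18 participants, 16 trials at 64 Hz for the single worked
experiment. The behavioural design is never scaled — all 66 pairs × 7
blocks are always simulated, since the design arithmetic (462, 77, 630) is
part of what is being checked. The generator's defaults remain the
full-size study (36 participants, 30 trials, 512 Hz).

## Known limitations

- The published verdict grid is reproduced from printed means and
  significance flags; raw-data contrasts cannot be re-derived because the
  underlying EEG is not public, and whether the original contrasts were
  t-tests is not stated.
- Group F statistics, t(35) = 19.79, r_mean = 0.450 and the choice–WTP
  Spearman 0.73 depend on that unavailable raw data; the package checks
  the corresponding *properties* (directions, calibrations, df patterns)
  rather than those numbers.
- The discrimination criteria are asymmetric in power: a cell can only
  pass via a significant contrast, so accuracy estimates depend on n and
  SNR, and chance level is not 50% but the null rejection rate of the
  FDR-corrected family (near zero). The 0.5 "chance" benchmark used for
  the late-window recovery study is therefore conservative.
- Eye-movement correction by source analysis is out of scope; the
  generator injects only threshold-detectable spikes.
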