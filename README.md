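# sierp: single-item event-related potentials and consumer preference

`sierp` is an R implementation of an analysis pipeline asking whether the
EEG response to a *single* consumer product — rather than to a pooled set of
products — carries enough signal to predict whether that product will be
behaviourally preferred. It targets three stimulus-locked ERP components
with known sensitivity to consumer preference: the fronto-central **N200**
(quantified peak-to-peak against the preceding P200), the centro-parietal
**late positive potential** (LPP, 400–800 ms mean amplitude) and the
**positive slow wave** (PSW, four windows spanning 800–3000 ms).

The package is written for methodologists in EEG/consumer-neuroscience who
want a fully testable version of this procedure: every stage runs on
synthetic data with known ground truth, and the package re-evaluates a
published single-item summary table to reproduce its printed accuracy
figures.

## The method

Products are ranked 1–12 by pairwise-choice counts (66 pairs × 7 blocks per
participant) and median-split into highly preferred (HP, ranks 1–6) and
less preferred (LP, ranks 7–12) groups. For each item, window and
participant, the single-item (SI) score is compared against the HP and LP
group waveform scores, where the group average always *leaves out* the item
under test. The 12 items × 2 references × 6 windows = 144 paired t-tests
are corrected with the Benjamini–Hochberg FDR procedure, and each item ×
window cell is judged by two logical criteria (inequalities meaning
FDR-significant differences at p < 0.05):

- **Criterion 1** (HP-ranked item with SI score *x*): `x ≥ HP AND x > LP`
- **Criterion 2** (LP-ranked item with SI score *y*): `y ≤ LP AND y < HP`

Discrimination accuracy is the fraction of cells whose criterion holds.
The package also includes the group-level replication analysis: 2
(Preference) × 3 (Anterior–Posterior) × 3 (Laterality) repeated-measures
ANOVAs with per-effect Greenhouse–Geisser correction, partial η², simple
effects per site, and Bonferroni correction across the five late windows.

A synthetic-data module generates the whole study — EEG epochs built from
Gaussian/boxcar component templates whose amplitudes follow latent item
utilities, plus a Bradley–Terry pairwise-choice task and a BDM
willingness-to-pay auction — so that every downstream stage is testable
with full ground truth.

## Worked example

Re-evaluate the packaged published summary table (12 items × 6 windows of
SI/LP/HP mean amplitudes with FDR significance flags):

```r
library(sierp)
ev <- evaluate_published_table()
ev$accuracy$n_true                 # 51   (of 72 cells)
round(100 * ev$accuracy$overall, 1)  # 70.8
ev$accuracy$by_window_true
#>  n200   400-800  800-1200 1200-1600 1600-2000 2000-3000
#>     6         8         8        10        10         9
round(100 * ev$accuracy$psw_800_3000, 1)  # 77.1  (pooled 800-3000 ms)
ev$accuracy$excluding_true         # 43   (of 60, dropping boundary ranks 6-7)
```

So 51 of 72 single-item amplitude values conform to their criterion
(70.8%); the N200 discriminates at chance (6/12) while the late windows
reach 8–10 of 12, and dropping the two median-split boundary items barely
moves the overall rate (71.7%) — the pattern the table was published to
demonstrate.

A full simulated experiment, end to end:

```r
truth <- simulation_truth(n_participants = 18, trials_per_item = 16,
                          sampling_rate = 64, seed = 101L)
res <- run_pipeline(truth, min_trials = 8)
res$summary$behavior
#> r_mean 0.545, switch fraction 0.122, HP-LP t(17) = 14.66, WTP rho 0.93
round(res$discrimination$accuracy$by_window, 2)
#>  n200   400-800  800-1200 1200-1600 1600-2000 2000-3000
#>  0.50      0.75      0.75      0.75      0.75      0.67
```

With the default preference-dependent amplitude slopes the late windows
discriminate well above chance while the weakly-sloped N200 sits at 0.5,
and the behavioural summaries (inter-subject consistency, choice-switch
rate, HP-vs-LP paired t, choice–WTP correlation) fall in realistic ranges.

The numbered scripts under `analysis/` run these studies as a workflow and
write their tables under `results/`: `01` re-evaluates the published table,
`02` runs one full simulated experiment (including the ANOVAs above), `03`
checks null calibration (slope-free generator ⇒ significant-contrast rate
≈ 0.002, far below α = 0.05), `04` shows late windows beating the N200 in
100% of seeded runs when LPP/PSW slopes dominate.

## Package layout

- `R/simulate.R` — ground truth, epoch/choice/WTP generators
- `R/behavior.R` — choice counting, ranks, consistency statistics
- `R/erp.R` — baseline correction, artifact rejection, averaging, ROI and
  component measures
- `R/discrimination.R` — contrasts, FDR, criteria, accuracy, published
  table re-evaluation
- `R/anova.R` — repeated-measures ANOVA with Greenhouse–Geisser correction
- `R/pipeline.R` — end-to-end orchestration and artifact writing
- `vignettes/single-item-erp-discrimination.Rmd` — methods notes: model
  assumptions, parameter choices, numerical conventions, limitations
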