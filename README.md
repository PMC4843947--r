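# fcentropy

Structure-constrained analysis of resting-state functional connectivity
for region-parcellated brain networks, built around **functional
connectivity entropy (FCE)** stratified by **structural path order**.

The package is aimed at connectomics researchers who have, per subject, a
tractography-derived streamline-count matrix and preprocessed regional
BOLD time series, and who want to ask: *is the spatial variability of
functional connectivity different between groups, and is the difference
specific to links with or without a direct anatomical substrate?*

## The method

For an *N*-region parcellation, every unordered region pair is classified
by its shortest path length in the binarized structural graph (an edge is
a streamline count at or above a configurable minimum, default 1):

| class | shortest path | meaning |
|---|---|---|
| primary | 1 | direct white-matter tract |
| secondary | 2 | one intermediary region |
| tertiary | 3 | two intermediary regions |
| higher / disconnected | ≥ 4 / ∞ | kept distinct, policy-controlled |

Functional connectivity is the Pearson correlation *r* of each pair's
time series.  Within each stratum (and whole-brain), the FC values are
binned into *B* equal-width bins over a fixed range and summarized by
their Shannon entropy

&nbsp;&nbsp;&nbsp;&nbsp;*H* = −Σ<sub>k</sub> *p*<sub>k</sub> log₂ *p*<sub>k</sub>  (bits),
0 ≤ *H* ≤ log₂ *B*,

the **FCE** of that stratum: 0 when all links share one strength, maximal
when strengths are uniformly unpredictable.  Group inference residualizes
per-subject FCE against age, sex and antipsychotic dose (OLS, pooled
design), compares patient strata (early / late illness, 5-year cutoff)
to controls with Student's *t* and Cohen's *d*, correlates FCE with
symptom burden (total SSPI), and sweeps the streamline threshold 1–3 as a
sensitivity analysis.

A synthetic-cohort generator produces complete cohorts — shared anatomical
template, per-subject structural networks, class-structured correlations
with designed group/severity effects, covariates and ground truth — so the
entire pipeline is testable without any imaging data.

## Worked example

```r
library(fcentropy)

cohort <- simulate_cohort(sim_config(), seed = 42)
cohort
#> <fce_cohort> 66 subjects (34 patients, 32 controls), 90 regions
#>   ground truth attached

adj <- binarize_streamlines(cohort$streamlines$S001, min_streamlines = 1)
path_class_proportions(classify_paths(adj))
#> # A tibble: 5 × 3
#>   class        n_pairs proportion
#>   <chr>          <int>      <dbl>
#> 1 primary         1141     0.285
#> 2 secondary       2799     0.699
#> 3 tertiary          65     0.0162
#> 4 higher             0     0
#> 5 disconnected       0     0
```

One subject's 4,005 pairs split ≈ 28% / 70% / 2% across primary,
secondary and tertiary paths.  Per-subject stratified entropies:

```r
fce <- compute_fce_cohort(cohort, fce_config())
print(fce, n = 5)
#> # A tibble: 330 × 10
#>   subject_id stratum     entropy_bits n_links undefined n_bins bin_lo bin_hi
#> 1 S001       whole_brain         4.52    4005 FALSE        100     -1      1
#> 2 S001       primary             4.33    1141 FALSE        100     -1      1
#> 3 S001       secondary           4.45    2799 FALSE        100     -1      1
#> 4 S001       tertiary            3.71      65 FALSE        100     -1      1
#> 5 S001       higher             NA          0 TRUE         100     -1      1
```

(the empty `higher` stratum is flagged, not an error).  The
covariate-adjusted group comparison, as a broom-style tidy table:

```r
report <- run_full_comparison(fce, cohort$cohort, fce_config())
tidy(report)   # one row per duration stratum x FCE stratum
#>   duration_stratum stratum     mean_control mean_patient t_stat  p_value cohen_d
#> 1 early            whole_brain         4.45         4.48   2.20  3.26e-2   0.661
#> 2 early            secondary           4.26         4.35   3.60  7.59e-4   1.08
#> 3 early            tertiary            3.88         3.81  -2.06  4.54e-2   0.617
#> 4 late             whole_brain         4.43         4.40  -2.69  9.81e-3   0.808
#> 5 late             secondary           4.21         4.13  -3.50  1.03e-3   1.05
#> 6 late             tertiary            3.89         3.73  -4.59  3.36e-5   1.38
```

This cohort was simulated with its designed effects, and the report
recovers them: early-stage patients show *higher* secondary-path FCE
(*d* = 1.08) and *lower* tertiary FCE, late-stage patients lower FCE
everywhere with tertiary paths most affected (*d* = 1.38).  `direction`
carries the sign of (patient − control); `cohen_d` is reported as a
magnitude.  `glance(report)` summarizes the run (12 tests, threshold 1,
100 bins, raw *r*, plug-in estimator); `autoplot(report)` draws the
signed effect sizes.

A command-line interface wraps the same functions
(`inst/cli/fcentropy simulate | classify | fce | compare | report`); every
run writes a log and an effective-config copy beside its outputs.

## Package layout

- `R/` — implementation: IO and CLI, structural path classification,
  functional connectivity, FCE, group statistics, synthetic cohorts,
  tidiers and plots
- `tests/testthat/` — unit, property and end-to-end statistical tests
  (independent oracles: boolean matrix powers, textbook *t*/*r*
  formulas, brute-force re-tallies)
- `vignettes/fce-methods.Rmd` — the model, its assumptions, parameter
  defaults and rationale, generator design and known limitations
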