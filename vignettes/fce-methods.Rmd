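---
title: "Structure-constrained functional connectivity entropy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-constrained functional connectivity entropy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcentropy)
```

## The scientific question

Resting-state functional connectivity (FC) — the Pearson correlation between
two brain regions' BOLD time series — varies widely across region pairs, and
part of that variation is anchored in anatomy: pairs joined by white-matter
tracts tend to correlate more strongly than pairs whose interaction is
mediated by intermediate regions.  `fcentropy` operationalizes this coupling
in two steps:

1. **Structural stratification.** From a diffusion-tractography
   streamline-count matrix, every unordered region pair is labelled by its
   shortest path length in the binarized structural graph: *primary*
   (direct tract, length 1), *secondary* (one intermediary, length 2),
   *tertiary* (two intermediaries, length 3).  Pairs at length ≥ 4 get a
   distinct *higher* label, and unreachable pairs *disconnected*.
2. **Functional connectivity entropy (FCE).** Within each stratum (and for
   the whole brain) the FC values are binned into an equal-width histogram
   and summarized by their Shannon entropy,
   $H = -\sum_k p_k \log_2 p_k$ (bits).  FCE measures the spatial
   *unpredictability* of connectivity strength over a set of links: 0 when
   every link shares one strength, $\log_2 B$ when strengths spread evenly
   over all $B$ bins.  Unlike variance, it is insensitive to the location
   of the distribution and uses its full shape.

The package then asks the clinical question this design serves: do patient
groups (stratified by illness duration) differ from controls in per-stratum
FCE after removing age, sex and antipsychotic-dose effects, and does FCE
track symptom burden?

## Path classification

The streamline matrix is binarized at a minimum streamline count
(`min_streamlines`, default 1: "one or more streamlines" defines a direct
edge).  Classification uses unweighted breadth-first distances on the
undirected graph; streamline counts play no role beyond thresholding.  The
suite cross-checks this route against an independent boolean matrix-power
oracle (the class of a pair is the smallest $k$ with $(A^k)_{ij} > 0$).

Three choices here were genuinely open and are worth recording:

* **Pairs beyond tertiary.**  Real cohorts contain a handful of pairs
  needing more than two intermediaries.  Rather than silently folding them
  into tertiary, the package labels them `higher` and exposes
  `higher_order_policy` (`"separate"` default, `"merge_into_tertiary"`
  optional); every output records which policy was used.
* **Consensus matrices.**  Group-level class comparisons need one matrix
  per group; `consensus_path_class()` takes the per-pair modal class with
  ties broken toward the *lower* path order — the conservative,
  structurally constrained reading.  The tie-break is deterministic and
  documented in the output rather than left to sort order.
* **Agreement denominators.**  "X% of primary links classified the same
  in both groups" is ambiguous about its denominator.  `class_agreement()`
  therefore reports both variants — the union denominator (pairs carrying
  the class in either classification) and the conditional denominator
  (pairs carrying it in the first classification) — instead of guessing.
  Similarly, group-level class *proportions* can be computed per subject
  and averaged, or from the consensus matrix; both are supported, and the
  bundled acceptance script uses per-subject averages (matching an "on
  average" reading) while using consensus matrices for agreement, and says
  so in its output names.

## The entropy estimator

FCE needs a bin scheme and an estimator; neither is canonical, so both are
explicit configuration with recorded defaults:

* **Bins:** 100 equal-width bins over $[-1, 1]$ (raw correlations).  Bins
  are left-closed/right-open with the last bin closed, so both range ends
  are countable.  Values outside the range are an *error*, never silently
  clamped — with the `fisher_z` transform the user must widen `bin_range`
  deliberately.  100 bins keeps the ceiling $\log_2 100 \approx 6.64$ bits
  interpretable while resolving far more structure than the typical
  per-stratum link count demands.
* **Value scale:** `fc_transform` is `raw_r` by default: raw correlations
  preserve the sign of bidirectional deviations (both hyper- and
  hypo-connectivity), which is exactly the dispersion FCE is meant to
  capture.  `abs_r` and `fisher_z` are available.
* **Estimator:** the plug-in (maximum-likelihood) histogram entropy, with
  an optional Miller–Madow correction (`estimator = "miller_madow"`,
  adding $(K-1)/2N$ nats for $K$ occupied bins and $N$ links).  Tertiary
  strata hold only ~3% of the 4,005 pairs of a 90-region parcellation
  (~120 links), where plug-in bias is visible; the default remains the
  simplest reproducible choice and the correction is recorded in output
  when used.
* **Degenerate strata:** a stratum with fewer than two links gets a
  flagged `NA` instead of a degenerate 0 — a single value has entropy 0
  for the wrong reason and would bias group means.  Flagged rows are
  excluded from group statistics.

Whole-brain FCE uses all off-diagonal pairs, including disconnected ones;
class strata exclude disconnected pairs.

## Group statistics

Covariate removal follows the classical residualization route: ordinary
least squares of the per-subject FCE value on age, sex (0/1) and
chlorpromazine-equivalent dose, pooled across the compared subjects, with
the grand mean added back so group means stay interpretable.  Dose is 0
for controls; in control-only fits that column carries no information and
is dropped rather than made an error (a per-group residualization flag
exists for users who prefer separate fits).  Comparisons use Student's
pooled-variance $t$ (Welch by flag) with two-tailed $p$, and Cohen's
$d = |\bar{y} - \bar{x}| / s_{pooled}$ with $n-1$ pooled variances — the
pooled denominator matches the $t$ convention.  The direction of each
difference is carried separately as the sign of
$\bar{y}_{patient} - \bar{x}_{control}$.  Symptom correlations are Pearson
$r$ on residualized patient FCE versus the total SSPI score, with $p$ from
the $t$ transform of $r$.  No multiple-testing correction is applied; the
report carries the number of tests so users can correct externally.

Patients split into early (< 5 years illness duration) and late (≥ 5
years) strata; the cutoff is configurable.  Comparisons run for the pooled
patient group and for each duration stratum, against all controls by
default or against explicit matched-control subsets via indicator columns
in the cohort table.  Blocks with fewer than two subjects per group — or
too few subjects to support the three-covariate design — are flagged and
skipped rather than aborting the report.

The streamline-threshold sweep (`threshold_sensitivity()`) reruns
classification, FCE and the comparison at thresholds 1–3 and summarizes
per-subject cross-threshold class agreement; thresholding is monotone by
construction (a pair's path order can only rise with the threshold).

## The synthetic-cohort generator

No imaging data ship with the package; a forward model generates complete
cohorts with known ground truth so every stage is testable.

**Structure.**  A cohort shares one anatomical template: 90 regions placed
uniformly in the unit cube and a per-pair edge probability
$p = \exp(-(d/s)^{2.5})$ decaying with Euclidean distance.  The scale $s$
is calibrated by bisection so the expected edge density — the primary-pair
proportion — hits its target (default 27.8%).  The shape exponent controls
how *local* the network is and therefore how the remaining pairs split
between secondary and tertiary; 2.5 puts the split near 69% / 3%, the
regime a 90-region tractography connectome occupies (a pure exponential at
the same density leaves almost no tertiary pairs).  Each subject realizes
edges independently from the shared template — correlated networks, the way
real subjects share an atlas — and the graph is made connected by bridging
nearest components.  Streamline counts on edges are negative-binomial
(mean 25, size 0.8), floored at one.

**Function.**  Per subject, each pair receives a target correlation drawn
from $\mathcal{N}(\mu_c, \sigma_c)$ by path class, truncated to
$(-0.99, 0.99)$, with class means decreasing with path order
($\mu = 0.32, 0.17, 0.06$) — structurally connected pairs correlate more.
The matrix is projected to the nearest symmetric positive-definite
correlation matrix by eigenvalue clipping (floor $10^{-6}$,
re-normalized to unit diagonal), and $T = 240$ Gaussian time points are
drawn with that covariance.  The class spreads $\sigma$ are the *entropy
handle*: widening a class's spread raises its expected FCE, and the suite
verifies this monotonicity empirically over a $\sigma$ grid.

Two numerical trade-offs deserve emphasis:

* The independent-draw construction is only approximately consistent with
  positive-definiteness, and the projection distortion grows with
  $\sigma\sqrt{N}$.  Default spreads ($\sigma = 0.11, 0.095, 0.075$) keep
  the mean absolute off-diagonal change of the projection below 0.05 —
  the price is a somewhat narrower total FC distribution than empirical
  resting-state matrices show.  The pre-projection draws are attached to
  every covariance for inspection.
* The projection mixes classes: changing one class's spread perturbs the
  others slightly.  Under the default early-stage configuration this
  leaks a small *negative* shift into primary-path FCE even though the
  primary spread multiplier is 1.  The designed (checked) effects are the
  configured ones; the leakage is a known artefact of the projection and
  is visible in the generator's ground-truth record.

**Cohort effects.**  Group sizes default to 32 controls and 34 patients
(17 early, 17 late), ages $\mathcal{N}(34, 9)$ truncated to $[18, 65]$,
~70% male, log-normal dose for patients (median ≈ 480 mg/day CPZ) and 0
for controls.  Designed effects act multiplicatively on the class spreads:
early stage raises the secondary spread (×1.35) and lowers tertiary
(×0.60); late stage lowers all three with tertiary most
(×0.70, ×0.70, ×0.45).  Magnitudes were fixed by pilot calibration so the
recovered effect sizes land in the large-$d$ range the stratified
comparisons target, with comfortable sign margins at 17 subjects per
group.  A per-patient latent severity (standard normal) simultaneously
drives the symptom score (SSPI $= 11.8 + 5z + \mathcal{N}(0,3)$, floored
at 0) and modulates spreads (+0.20 on log-spread of secondary in early
stage; −0.22 on primary and secondary in late stage), which makes
FCE–symptom correlations of the configured sign recoverable.  Small linear
age, sex and dose effects on log-spread (0.004/yr, 0.03, $3\times10^{-5}$
per mg/day) give the residualization step real work.  A per-subject
log-spread jitter (SD 0.08) shared across classes sets between-subject
FCE variability.

**What the generator does not emulate.**  Gaussian stationary series — no
hemodynamics, no autocorrelation, no nonstationarity (sliding-window
variability is explicitly out of scope); no spatial smoothness or
physiological noise; no hemispheric or network topography in the template;
streamline counts independent of distance given edge presence.  Passing
recovery tests therefore demonstrates that the *pipeline* measures what it
claims on covariance-faithful data with known truth — not that real BOLD
data satisfy the model.

## Verification problem sizes

The suite checks the dual-route classification oracle on 200 random graphs
(up to 30 nodes, all densities), entropy identities and refinement
monotonicity on randomized histograms, residual orthogonality at $10^{-8}$
on random 30–70-subject designs, type-I error of the stratum comparisons
via 1,000 permuted relabelings of a 66-subject null cohort (nominal 5%,
accepted within [3%, 7%]), and sign recovery of the designed effects over
200 replicate cohorts per stage at 17 subjects per group (≥ 95% required).
These sizes are the package's verification design; they keep the full
suite in the ten-minute range on a single core.

## Known limitations

* The entropy defaults (bin count, base, estimator) are recorded
  conventions, not community standards; comparisons across studies must
  hold them fixed.
* Plug-in entropy is biased downward in small strata; the Miller–Madow
  flag mitigates but does not remove this, and tertiary strata of
  real-size cohorts sit exactly where it matters.
* The SPD projection couples strata (see above), so configured per-class
  spreads are targets, not exact post-projection truths.
* Consensus matrices and agreement fractions depend on cohort size through
  the modal vote; small groups make them noisy.
* The matched-control mechanism takes subsets as given; the package does
  not construct matches.
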