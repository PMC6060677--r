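---
title: "Case-control metabolic profiling of urinary 1H NMR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control metabolic profiling of urinary 1H NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Untargeted ¹H NMR profiling of urine measures thousands of spectral
variables (intensities on a chemical-shift grid) per sample. Comparing a
disease or exposure group against controls on such data faces three
obstacles that this package addresses as a single pipeline:

1. **Urinary dilution.** Urine concentration varies several-fold between
   voids; every peak scales with it. Probabilistic quotient normalization
   (PQN) estimates each sample's dilution as the median point-wise ratio to
   a reference spectrum and divides it out.
2. **Peak-position drift.** Chemical shifts move slightly from sample to
   sample (pH, ionic strength), so a fixed grid column does not track a
   fixed proton. Recursive segment-wise peak alignment (RSPA) shifts
   spectral segments by whole grid points to maximise correlation with a
   reference, recursing into smaller segments.
3. **Many correlated variables, few samples.** Discrimination is modelled
   with PLS-DA — partial least squares against a 0/1 class dummy — and
   O-PLS-DA, which first removes structured variance orthogonal to the
   class (dilution residue, baseline drift, batch effects) so the
   discrimination concentrates in one predictive component. Because such
   models overfit by construction (training R²Y near 1 is typical at these
   n/p ratios), validity rests entirely on stratified 7-fold cross-validated
   Q²Y and on permutation testing: the whole fitting procedure is repeated
   under random relabellings, at the model level (null distribution of Q²Y)
   and per variable (null distribution of each loading correlation |r|).

Assignment of discriminatory peaks to metabolites uses STOCSY: the
correlation of one driver variable against all others across samples, which
lights up resonances belonging to the same molecule. A small univariate
layer (Mann–Whitney, Spearman, t-tests on log concentrations, χ²,
geometric-mean confidence intervals, gender-adjusted logistic regression)
covers the demographic and targeted comparisons that accompany such
studies.

# The synthetic cohort generator

No public spectra accompany the study design this pipeline targets, so the
package ships a generator (`cohort_design()` / `simulate_cohort()`) whose
ground truth makes every stage testable: it records the true dilution
factor, the true per-sample, per-metabolite position jitter, and which
metabolites carry class effects.

Each spectrum is a sum of Lorentzian multiplets from a built-in library of
15 urinary metabolites (microbial co-metabolites, liver-associated species,
one-carbon intermediates, background metabolites), with first-order
binomial multiplet patterns. The defaults describe a morning-urine
collection on a well-shimmed 600 MHz instrument:

| parameter | default | meaning |
|---|---|---|
| `ppm_range`, `n_points` | 0.5–9.5 ppm, 6000 | desk-scale grid (1.5 mppm/point) that still resolves the 3 mppm default linewidth |
| `dilution_sigma` | 0.4 | log-scale SD of the per-sample log-normal dilution factor |
| `biological_cv` | 0.25 | log-normal CV of each metabolite's excretion around its class mean |
| `jitter_sd_ppm` | 0.0015 | per-sample, per-metabolite Gaussian position jitter for buffered samples; pH-sensitive extremes are exercised by raising it to 0.01 in alignment tests |
| `noise_sd`, `baseline_amplitude` | 0.005, 0.005 | additive noise and residual smooth baseline, two orders below unit reference peak height (spectra are baseline-corrected upstream of this pipeline) |
| `water_residual` | TRUE | residual solvent hump at 4.8 ppm (half width 0.04 ppm, log-normal amplitude) |

Class effects enter as fold-change multipliers on the class mean of named
metabolites. A single RNG stream seeded from `design$seed` draws, per
sample and in fixed order: dilution factor, concentrations, jitters, water
amplitude, then baseline and noise — so cohorts are bit-reproducible.

**What the generator does not emulate:** the dense forest of hundreds of
minor metabolites in real urine (between-peak regions here are noise, which
unit-variance scaling amplifies more than in real spectra), J-coupling
physics beyond first-order patterns, correlated metabolite physiology,
batch effects beyond dilution, and matrix differences between human and
mouse urine. Passing tests therefore demonstrate that the algorithms
recover known structure under realistic nuisance processes — not that any
specific biological effect size in real data would be detected.

# Numerical and design choices

**Pipeline order.** Region exclusion (default: the 4.7–4.9 ppm water
window) → PQN → RSPA → per-model unit-variance scaling. The order is
configurable; normalization-before-alignment follows the conventional
processing description. Quotients are computed after exclusion.

**PQN reference and signal floor.** The default reference is the
column-wise median spectrum. Columns where the reference falls below 1% of
its maximum are excluded from the quotient: with a sparse peak library,
baseline- and noise-dominated columns carry no dilution information and
would otherwise bias the median ratio. Quotients are defined only up to the
overall scale of the reference; recovery of simulated dilution is therefore
assessed on median-normalised relative dilution (correlation is unaffected).
The dilution-recovery experiment switches biological variability and jitter
off: with ~15 independent metabolite concentrations at 25% CV the quotient
tracks dilution only to within several percent for mathematical reasons
(the median of ~15 ratios), so the parameter-recovery test isolates the
parameter it recovers.

**RSPA.** Integer-point shifts only (exactly reproducible; a documented
simplification versus interpolating variants). The per-segment search
window is 2% of the segment length with a configurable floor
(`min_window_points`, default 5) and cap; a window smaller than the
expected drift cannot correct it, so jitter studies at 0.01 ppm use a
floor of 12 points. Segments split at the minimum-intensity point of their
middle third; shifted-out points are filled by edge-value padding, so the
point count never changes; ties in the shift search prefer the smallest
|shift| (zero first), making self-alignment exactly the identity.
References: `"median"` (default), `"mean"`, a sample id, or an external
template. A caveat discovered during development and worth knowing: with
sparse peaks and strong jitter the median reference annihilates peaks
(fewer than half the samples overlap any column), and any data-driven
reference converges to the cohort's empirical *mode* of the jitter
distribution, which is biased off the consensus position at realistic n.
Alignment *recovery* is therefore measured against a noiseless library
template, which pins target positions at truth; on real data the
data-driven references remain appropriate because only relative alignment
matters downstream.

**Scaling.** Mean-centring and unit variance with the n−1 denominator;
zero-variance columns are dropped and recorded, making the transform an
exact bijection on kept columns and letting loadings be back-scaled to the
covariance scale (`backscaled_loadings()`, the classical spectrum-like
loadings display coloured by |r|).

**O-PLS-DA.** PLS1 with the closed-form NIPALS solution per component
(single y column needs no inner iteration). Orthogonal components are
extracted iteratively as w_orth = p − (w'p)w before one predictive
component; `n_orth = 0` reduces exactly to one-component PLS-DA. Sign
convention: predictive scores correlate positively with the class dummy.
R²X counts predictive plus orthogonal components. Models on the synthetic
cohorts use 2–3 orthogonal components — the conventional count for
two-class urinary models — which absorb the dilution and baseline residue;
the count is a per-model configuration input, never auto-selected.

**Validation.** Folds are stratified by class with a seeded draw, redrawn
(bounded) if a training split loses a class; samples sharing a subject id
stay in one fold. Scaling is refit inside every training split — the
conservative no-leakage choice. Permutation p-values use the add-one rule
p = (1 + #{null ≥ observed}) / (1 + n_perm), so p is never 0 and the floor
at 1000 permutations is 1/1001 ≈ 0.001. "Significance of a metabolite" is
operationalised as label-permutation of the per-variable loading
correlation |r| (equivalent to permuting the spectral rows under
exchangeability); no multiple-testing correction is applied by default, per
the conventional per-variable α = 0.05 reporting rule (a Benjamini–Hochberg
flag is available).

**Univariate layer.** Mann–Whitney uses midranks, exact enumeration for
pooled sizes ≤ 10 (valid under ties) and a tie-corrected,
continuity-corrected normal approximation otherwise; one-tailed means the
first group tends lower. Spearman is the Pearson correlation of midranks
with the t approximation on n − 2 df. t-tests default to Welch. χ² is
Pearson's without continuity correction by default. The logistic adjustment
op flags non-convergence and (quasi-)separation explicitly.

# Problem sizes used by the test-suite and acceptance script

Simulated experiments run at desk scale, chosen as the package's own
standard study conditions: dilution recovery on 40 spectra (4000 points);
alignment recovery on 12 spectra (6000 points, jitter SD 0.01 ppm); effect
recovery on 20 + 20 cohorts (6000 points, three metabolites at 1.5-fold,
Q² with 3 orthogonal components, 199 model permutations, 499 loading
permutations, 20 replicates for the flagging-power estimate); null
calibration on 100 cohorts of 12 + 12 (800 points, 99 permutations). The
full-scale permutation counts of a publication-grade run (1000 model,
10000 loading) sit behind the `paper_scale` flag of `demo_config()`.

# Known limitations

Two-class PLS1 only (no multiclass, no kernel variants); no automatic
selection of orthogonal components; integer-grid alignment cannot correct
sub-grid drift; PQN accuracy on sparse synthetic spectra is limited by the
number of independent peaks; the logistic op fits one metabolite plus one
covariate, not a general model matrix. Vendor binary formats are out of
scope — spectra enter as CSV with a ppm header row.
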