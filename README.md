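# metabopls

Case-control metabolic profiling of one-dimensional ¹H NMR urine spectra:
preprocessing (water-window exclusion, probabilistic quotient normalization,
recursive segment-wise peak alignment, unit-variance scaling), O-PLS-DA
modelling with cross-validated Q²Y and permutation validation, STOCSY-based
peak assignment, and the univariate statistics that accompany such studies.
A ground-truth-aware synthetic cohort generator makes every stage testable
without access to real spectra.

It is written for analysts running NMR metabonomics case-control
comparisons — toxicology and exposure studies, liver-injury phenotyping,
microbiome co-metabolite work — who need a reproducible, scriptable
pipeline with honest validation statistics.

## The model at the core

For a two-class comparison with class dummy **y** ∈ {0,1}ⁿ and a
UV-scaled spectral matrix **X** (n samples × K variables), O-PLS-DA first
removes `n_orth` orthogonal components: from the PLS weight
**w** ∝ **X**ᵀ**y** and loading **p**, the orthogonal weight is
**w**⊥ = **p** − (**w**ᵀ**p**)**w**, the score **t**⊥ = **Xw**⊥, and
**X** ← **X** − **t**⊥**p**⊥ᵀ. One predictive PLS1 component
(**w**, **t** = **Xw**, c = **y**ᵀ**t**/**t**ᵀ**t**) is then fitted on the
filtered matrix. Validity is assessed by stratified 7-fold cross-validated
Q²Y = 1 − PRESS/TSS and by repeating the entire procedure under `n_perm`
random relabellings, with add-one-corrected p-values
p = (1 + #{Q²null ≥ Q²obs}) / (1 + n_perm) at the model level and the
analogous per-variable rule for the loading correlations |r|. Back-scaled
loadings (loading × column SD, coloured by |r|) recover a spectrum-like
view of what drives the separation.

## Worked example

Simulate a 20 vs 20 cohort in which cases excrete less hippurate and
p-cresol sulphate and more N-methylnicotinamide, then run the full
analysis:

```r
library(metabopls)

design <- cohort_design(
  n_per_class = c(case = 20, village_control = 20),
  effect_map  = list(case = list(hippurate = 0.6, "p-cresol sulphate" = 0.6,
                                 "N-methylnicotinamide" = 1.6)),
  seed = 42
)
cohort <- simulate_cohort(design)

pq <- cohort$spectra |>
  exclude_regions(water_region()) |>
  pqn_normalize()
spectra <- rspa_align(pq$spectra)$spectra

y  <- class_vector(cohort$samples$class_label, positive = "case")
sc <- scale_uv(spectra)
model <- fit_opls_da(sc$X, y, n_orth = 2, scaling_state = sc$state)
glance(model)
#> # A tibble: 1 × 4
#>       n n_orth   R2X   R2Y
#>   <int>  <int> <dbl> <dbl>
#> 1    40      2 0.379 0.843

cv <- cross_validate_q2(spectra, y, n_orth = 2, seed = 42)
glance(cv)
#> # A tibble: 1 × 4
#>     Q2Y PRESS   TSS  seed
#>   <dbl> <dbl> <dbl> <int>
#> 1 0.400  6.00    10    42

permutation_test_model(spectra, y, n_orth = 2, n_perm = 199, seed = 42)
#> <perm_result> observed Q2Y = 0.400, p = 0.005 (199 permutations)
```

Training R²Y (0.843) is optimistic as always at this n/p ratio; the
cross-validated Q²Y of 0.400 with permutation p = 0.005 (the floor at 199
permutations) is what says the separation is real. The per-variable
permutation test then localises it:

```r
sig <- permutation_test_loadings(spectra, y, n_orth = 2,
                                 n_perm = 499, seed = 42)
dplyr::arrange(sig[sig$significant, ], p_value, dplyr::desc(abs(r_obs)))
#> # A tibble: 486 × 5
#>    variable   ppm r_obs p_value significant
#>       <int> <dbl> <dbl>   <dbl> <lgl>
#>  1     3220  4.47 0.819   0.002 TRUE
#>  2     3222  4.47 0.814   0.002 TRUE
#>  3     3223  4.47 0.795   0.002 TRUE
#>  4     3219  4.47 0.788   0.002 TRUE
#>  5     3206  4.49 0.787   0.002 TRUE
#>  6     3207  4.49 0.783   0.002 TRUE
#>  7      140  9.29 0.770   0.002 TRUE
#>  8      387  8.92 0.770   0.002 TRUE
#>  9     3221  4.47 0.766   0.002 TRUE
#> 10     3225  4.46 0.763   0.002 TRUE
#> # ℹ 476 more rows
```

The strongest variables sit at 4.46–4.49 ppm with companions at 9.29 and
8.92 ppm — the N-CH₃ and aromatic resonances of N-methylnicotinamide, one
of the planted effect metabolites. STOCSY from the top variable confirms
the intramolecular correlation structure (r² near 1 across that multiplet),
and positive `r_obs` means higher in cases, matching the planted 1.6-fold
increase:

```r
top <- sig$variable[which.max(abs(sig$r_obs))]
stocsy(spectra, driver_index = top) |> dplyr::arrange(dplyr::desc(r2))
autoplot(model, labels = cohort$samples$class_label)   # Tcv vs TYosc scores
autoplot(backscaled_loadings(model))                   # loadings by |r|
```

`run_pipeline(demo_config())` runs the whole graph — simulate, preprocess,
three class comparisons, validation, STOCSY, univariate battery — and
writes a versioned JSON report; `run_pipeline("config.yaml")` does the same
from a config file.

## File formats

- **Spectra CSV** — header row `sample_id,<ppm values...>` (descending ppm),
  then one row per sample. `read_spectra()` / `write_spectra()`.
- **Sample table CSV** — required columns `id`, `class_label` (vocabulary:
  case, household_control, village_control, pre_dose, post_dose, al_only,
  al_ddt); optional `batch`, `gender`, `age`, `al_level`, `alt`,
  `histopathology_score` (1–5), `duration_months`, `subject`. Empty cells
  stay missing.
- **Reports / ground truth** — versioned JSON via `write_report()` /
  `write_ground_truth()`.

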