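# lymphovac

Quantifying lymphocyte vacuolization as a disease-severity measure for
CLN3 disease (juvenile neuronal ceroid lipofuscinosis) and related
lysosomal storage disorders.

## The problem

CLN3 disease spans a phenotypic spectrum — from classical
childhood-onset neurodegeneration (two truncating *CLN3* alleles) down
to an isolated retinal degeneration (two particularly mild missense
alleles). There is no established metabolic severity marker, which
complicates counseling when novel variants are found. Lymphocyte
vacuolization, a hallmark of the disease visible on a routine blood
smear, tracks genotype severity, and the lysosomal membrane protein
LAMP-1 (CD107a) acts as a flow-cytometric proxy for it: the lysosomal
compartment is globally enlarged in affected lymphocytes.

`lymphovac` implements the full quantification pipeline for clinical
laboratories and method developers:

1. **Smear scoring** — independent observers count the percentage of
   vacuolated lymphocytes among 100 cells and the vacuoles per cell in
   up to 20 vacuolated cells; scores are aggregated along those two
   axes (`score_sample()`, `score_cohort()`, `two_axis_summary()`).
2. **Flow-cytometry gating** — lymphocyte subsets from a seven-marker
   panel (CD3/CD4/CD8/CD20/CD56/LAMP-1/perforin) with 1-D thresholds;
   the **NK population is the internal positive control**: the LAMP-1
   and perforin gates are anchored at a lower quantile of the NK
   distribution, and a cell is *affected* when LAMP-1⁺ **and**
   perforin⁻ (LAMP-1⁺perforin⁺ indicates cytotoxic activation, not
   storage). `gate_sample()` reports the affected percentage per
   subset.
3. **Per-cell image quantification** — for channel-separated 8-bit
   single-cell images (imaging flow cytometry), whole-cell masks are
   segmented from the surface CD4 channel by Otsu's method
   (`otsu_threshold()`, `segment_cell()`); `quantify_cell()` computes
   the mean LAMP-1 per cell and the *sliding-threshold curve*: for
   every intensity level k = 0..255 the percentage of masked cell area
   with LAMP-1 ≥ k. `population_bands()` summarizes curves into
   median/IQR/2.5–97.5% bands; `compare_classes()` tabulates per-class
   deciles of the per-cell means.
4. **Severity modelling** — a longitudinal linear mixed model

   outcomeᵢⱼ = β₀ + β₁·ageᵢⱼ + Σ βc·1[classᵢ = c] + b₀ᵢ (+ b₁ᵢ·ageᵢⱼ) + εᵢⱼ

   with per-patient random intercept b₀ᵢ and, when AIC (under ML)
   prefers it, a random age slope b₁ᵢ; final estimates under REML
   (`fit_severity()`, via nlme). `classify_genotype()` maps allele
   categories to the severity class; `severity_trend_report()` gives
   per-outcome age-stability verdicts.
5. **Synthetic data** — `cohort_config()` + `generate_cohort()` /
   `generate_flow_sample()` / `generate_cell_image()` emulate the
   cohort with known ground truth (per-patient logit-scale random
   effects, binomial observer counts, Gaussian log-fluorescence
   mixtures, rendered vacuole rings), so every stage is testable
   without patient material.

`run_pipeline()` ties the stages together deterministically; a thin
CLI lives at `inst/scripts/lymphovac`
(`simulate | smear-score | gate | image-quant | fit-severity | run-all`).

## Worked example

```r
library(lymphovac)

cfg <- cohort_config(
  n_patients_per_class = c(control = 8, protracted = 4, classical = 8),
  samples_per_patient = c(2L, 3L), seed = 42)
cohort <- generate_cohort(cfg)
scores <- score_cohort(cohort$observations)
two_axis_summary(scores)
#> Two-axis vacuolization summary (% vacuolated / vacuoles per cell)
#>       class n_samples pct_median pct_min pct_max vpc_median vpc_min vpc_max
#>     control        19       2.33    0.00     6.0          2       1       3
#>  protracted         9       7.00    2.67    12.3          8       7       9
#>   classical        22      31.83   14.67    48.7         10       9      11
#> (1 zero-% samples plotted at the 0.5% log floor)
```

Classical-disease samples sit near 30% vacuolated lymphocytes with ~10
vacuoles per affected cell; controls at 1–3% with 1–3 small vacuoles —
the two axes separate the classes cleanly.

```r
fit <- fit_severity(scores)
fit
#> Longitudinal severity model (REML): pct_vacuolated ~ age + class
#>   50 observations, 20 patients; random intercept + random age slope (AIC-preferred)
#>   age slope: 0.1242 (SE 0.111, p = 0.273)
#>   class effect: F(2, 17) = 60, p = 1.98e-08
```

Severity class drives vacuolization (the classical-vs-control contrast
is ≈ 27 percentage points), while age does not (p = 0.27): the marker
reflects genotype severity, not disease progression.

```r
ev <- generate_flow_sample("classical", 5000, cfg, seed = 42)
gate_sample(ev, sample_id = "demo")$report
#>   subset n_events n_affected pct_affected is_control_population
#> 1      B      725         96         13.2                 FALSE
#> 2     T4     1742        473         27.2                 FALSE
#> 3     T8      986        282         28.6                 FALSE
#> 4     NK      756         34          4.5                  TRUE
```

T cells carry the strongest storage signal in classical disease
(~27–29% affected); the NK row is the positive-control population, not
a readout (its ~5% reflects the gate quantile).

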