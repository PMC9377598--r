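# laef — automated left atrial function analysis

`laef` quantifies left atrial (LA) function over the whole cardiac cycle
from time-resolved (CINE MRI) binary segmentations, and runs the clinical
analysis that typically follows in atrial-fibrillation (AF) cohorts. It is
aimed at cardiac-imaging researchers who have per-frame LA masks (e.g. from
an automatic segmentation network) or pre-computed volume-time curves, plus
a clinical table, and want reproducible emptying fractions, AF
classification scores and cohort statistics without manual curve reading.

## What it computes

From a 4D binary mask (x, y, slice, cardiac frame; typically 25 frames per
cycle) the pipeline:

1. **Volumetry** — sums segmented voxels per frame (× voxel volume) into a
   volume-time curve (`build_curve()`).
2. **Fiducial detection** — locates the maximum volume `LAV_max`, minimum
   `LAV_min`, pre-atrial-contraction volume `LAV_preA` and the diastasis
   minimum `LAV_min2` (`detect_fiducials()`). Curves without atrial
   contraction (AF during the scan) are classified `af_no_preA`; curves
   deformed by extrasystoles are rejected. Localisation works on a smoothed
   curve; volumes come from a least-squares fit of a piecewise half-cosine
   waveform model, which is exact on clean biphasic curves and
   noise-averaging otherwise.
3. **Emptying fractions** (`la_function()`), in percent:

   ```
   LAEF_total   = (LAV_max  - LAV_min) / LAV_max  x 100
   LAEF_active  = (LAV_preA - LAV_min) / LAV_preA x 100
   LAEF_passive = (LAV_max  - LAV_preA)/ LAV_max  x 100
   ```

   linked by `(1 - T/100) = (1 - A/100)(1 - P/100)`, plus volumes indexed
   to Mosteller body surface area.
4. **AF classification** — AF Burden score (episode frequency + duration +
   cardioversions, binned minimal/mild/moderate/severe), CHA₂DS₂-VASc and
   its ≥2 stroke-risk dichotomy, EHRA class and AF type pass-through
   (`afbs()`, `cha2ds2vasc()`, `stroke_risk_group()`, `score_cohort()`).
5. **Cohort statistics** — Shapiro-routed group comparisons (pooled
   t-test/ANOVA vs Kruskal-Wallis, Bonferroni post-hocs, Fisher exact for
   categorical variables) and forward-stepwise multivariable linear
   regression with forced covariates age/sex/BMI and entry p < 0.1
   (`compare_groups()`, `fit_ulrm()`, `fit_mlrm_stepwise()`).

A synthetic-data module (`simulate_curve()`, `simulate_af_curve()`,
`corrupt_with_extrasystoles()`, `simulate_mask_series()`,
`simulate_cohort()`) generates curves, masks and cohort tables with known
ground truth, so the whole pipeline is testable end to end.
`run_pipeline()` orchestrates everything and writes per-stage CSVs plus a
JSON results bundle; a thin command-line front end lives at
`inst/cli/laef.R`.

## Worked example

```r
library(laef)

# a noisy synthetic sinus-rhythm curve with known fiducials
sim <- simulate_curve(curve_params(v_max = 104, v_min = 48, v_preA = 82,
                                   v_min2 = 76, noise_sd = 2), seed = 11)
fid <- detect_fiducials(sim$curve)
fid
#> <la_fiducials> patient synthetic: mode sinus_complete; max 104.1@9,
#>   min2 77.1@15, preA 80.7@20, min 47.3@0 (ml@frame)

la_function(fid, bsa = bsa_mosteller(178, 82))
#> <la_function> patient synthetic (sinus_complete)
#>   LAEF total 54.5%, active 41.4%, passive 22.4%
#>   LAVi max 51.7, min 23.5 ml/m2 (BSA 2.01 m2)
```

The detected volumes sit within the noise (SD 2 ml) of the generator values
(104 / 48 / 82 / 76 ml), and the emptying fractions follow from them: a
54.5% total emptying, of which the atrial kick (active fraction 41.4%)
contributes the larger share — the pattern expected in a preserved atrium.

The clinical layer, on one patient with monthly AF episodes lasting hours
and one prior cardioversion, aged 68 with hypertension:

```r
afbs("monthly", "hours", 1)
#>   frequency_points duration_points cardioversion_points total category category_code
#> 1                2               2                    1     5     mild             2

cha2ds2vasc(68, "male", heart_failure = FALSE, hypertension = TRUE,
            diabetes = FALSE, prior_stroke_or_tia = FALSE,
            vascular_disease = FALSE)
#> [1] 2            # age 65-74 (1) + hypertension (1)
stroke_risk_group(2)
#> [1] increased
```

And the statistics stage, on a synthetic 5000-patient cohort generated from
the published active-LAEF coefficient set:

```r
cohort <- simulate_cohort(cohort_config(n_patients = 5000, seed = 7))
fit_mlrm_stepwise(cohort$table, "laef_active",
                  candidates = c("afbs", "heart_failure", "hypertension", "lvef"),
                  forced = c("age", "male_sex", "bmi"))
#> <la_regression> outcome laef_active, adjusted R2 = 0.219
#>               term estimate  ci_low ci_high         p
#>        (Intercept)   63.314  60.462  66.165  0.00e+00
#>                age   -0.328  -0.358  -0.298  7.00e-95
#>           male_sex    2.700   1.974   3.427  3.62e-13
#>                bmi   -0.002  -0.070   0.066  9.56e-01
#>  heart_failureTRUE  -12.658 -13.755 -11.562 5.53e-108
#>               afbs   -4.295  -4.712  -3.879  1.72e-87
#> excluded candidates (p at last evaluation):
#>          term p_at_exclusion
#>  hypertension      0.8503021
#>          lvef      0.2363806
```

The stepwise search keeps exactly the true predictors (AF Burden, heart
failure) alongside the forced covariates, and the recovered coefficients
(−4.3% per AF-burden category, −12.7% for heart failure, −0.33% per year of
age) match the generating model.

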