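# voxelprog

Voxel-wise logistic modelling of malignant-glioma progression from
co-registered multiparametric imaging.

## The problem

After surgery and chemoradiotherapy, most malignant gliomas recur close to
the treated volume, but contrast-enhanced anatomical imaging alone is a weak
predictor of *where*. Functional maps acquired near the end of radiotherapy
carry complementary physiological signal:

* **CT perfusion** — blood flow (BF, mL/min per 100 g), blood volume
  (BV, mL/100 g) and the permeability–surface area product
  (PS, mL/min per 100 g), the contrast leakage rate of immature tumour
  vasculature;
* **FDG-PET** — the standard uptake value (SUV, normalised here by Du Bois
  body surface area) and the metabolism-to-flow ratio **SUV:BF**, a marker of
  metabolism–perfusion uncoupling (a hypoxia surrogate).

`voxelprog` implements the voxel-level analysis relating those maps to the
progressive tumour contoured on follow-up MR:

1. **Voxel tables** — per patient, a 2-cm bounding box is drawn around the
   union of the pre-radiotherapy gross tumour and the progressive tumour;
   vessels, surgical cavities and ventricles are excluded; every remaining
   voxel becomes a record with covariates (BF, BV, PS, SUV, SUV:BF) and three
   binary statuses (gross tumour, end-of-radiotherapy enhancing lesion,
   progressive tumour).
2. **Pooled logistic regression** — voxels from all patients are pooled and
   progression status is modelled as
   `logit P(prog) = β₀ + βᵀx`, fitted by iteratively reweighted least
   squares; effects are reported as odds ratios `e^β` with Wald 95% CIs and
   as per-unit probabilities `100·expit(β₀ + β)`.
3. **Leave-one-patient-out cross-validation** — per held-out patient, a
   probability-of-progression map, its ROC curve, AUC and the Youden-optimal
   sensitivity/specificity; cohort results as mean ± SD over patients.
4. **Model comparison** — Friedman test across models gating pairwise exact
   Wilcoxon signed-rank tests of per-patient AUCs against the anatomical
   baselines, with per-patient percent differences.

Because the underlying patient images are not public, the package ships a
**synthetic cohort generator**: 10 patients of co-registered 170×170 maps
over eight 5-mm sections (25-cm FOV) with lesion-dependent covariate
distributions and a *known* ground-truth logistic model (progression odds
rising with PS and SUV:BF, falling with BF, BV and SUV), so the entire
pipeline is testable end to end, including parameter recovery.

## Worked example

```r
library(voxelprog)

cfg <- synthetic_config(n_patients = 3, grid = c(96, 96, 4), seed = 11)
cohort <- generate_cohort(cfg)
tables <- lapply(cohort, function(pt) assemble_voxel_table(pt$maps, pt$masks))
pooled <- do.call(rbind, tables)

fit <- fit_logistic_irls(pooled, model_spec(c("BV", "PS", "SUV_BF")))
print(fit)
#> <logistic_fit>  n = 20965  df = 20961  converged = TRUE ( 10 iterations )
#>         term   beta     se odds_ratio   ci_low  ci_high probability_pct
#>  (Intercept) -7.940 0.3470   3.56e-04 1.80e-04 7.03e-04          0.0356
#>           BV -0.149 0.1020   8.62e-01 7.05e-01 1.05e+00          0.0307
#>           PS  1.320 0.0591   3.76e+00 3.35e+00 4.22e+00          0.1340
#>       SUV_BF 49.900 5.9600   4.64e+21 3.94e+16 5.47e+26        100.0000

scaled_odds(fit, "SUV_BF", 0.01)   # SUV:BF lives on a 0.02-0.1 scale
#> $or
#> [1] 1.646896
#>
#> $probability_pct
#> [1] 0.0585588

cv <- loocv(tables, model_spec("PS"))
print(cv)
#> <cv_result> model: PS - 3 patients
#>   auc          0.967 +/- 0.019
#>   sensitivity  0.920 +/- 0.053
#>   specificity  0.973 +/- 0.021
```

The fit reads like the published regression tables: `odds_ratio` is the
multiplicative change in progression odds per covariate unit (3.76 per
mL/min/100 g of PS here — the synthetic contrast is deliberately stronger
than clinical data), `probability_pct` the predicted progression probability
at one unit of that covariate with the others at zero. A *whole* unit of
SUV:BF is far outside its natural 0.02–0.1 range, which is why its per-unit
odds ratio is astronomical and why `scaled_odds()` reports the effect per
0.01 instead (odds ratio 1.65). `loocv` reports cross-validated
discrimination per held-out patient.

The full pipeline (generate → preprocess → fit → loocv → compare, with all
artefacts written to a run directory) is one call:

```r
res <- run_pipeline(pipeline_config("runs/demo", seed = 1))
```

or, from a shell, via the thin dispatcher
`Rscript inst/scripts/voxelprog.R run --config run.yaml`.

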