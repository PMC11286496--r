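# viscomarker

Machine-learning diagnosis of liver tissue state from viscoelastic creep
markers.

Fibrotic liver tissue stiffens, but a single elastic modulus cannot
separate early or drug-treated fibrosis from healthy tissue.  The creep
response of soft tissue under a step stress is far richer: the creep
compliance follows a two-stage scaling law, steep at short times and
shallow at long times.  `viscomarker` turns that observation into a
reusable, fully tested analysis pipeline for researchers in tissue
biomechanics and mechano-diagnostics:

1. **Simulate** cohorts of spherical-probe AFM creep measurements of
   healthy, drug-treated and fibrotic liver tissue from a fractional
   viscoelastic model with Laplace-domain relaxation modulus
   `G(s) = E3 + E2 (s/w0)^aR + E1 (s/w0)^aL + eta*s`, converted to
   indentation records through the Hertz contact model
   `J(t) = 4 sqrt(R) d(t)^(3/2) / (3 F (1 - nu^2))` and corrupted with
   multiplicative measurement noise.
2. **Extract** nine viscoelastic markers per measurement — `E1`, `E2`,
   `E3`, `Esum`, `eta`, `tau`, `fT`, `alphaL`, `alphaR` — by
   Levenberg–Marquardt fitting of the creep model (Gaver–Stehfest Laplace
   inversion, analytic derivatives, multi-start) plus two-window log–log
   regression for the power-law exponents.
3. **Classify** tissue state with a soft-margin Gaussian-kernel SVM
   (`min 1/2 ||w||^2 + C sum xi_i`,
   `kappa(xi, xj) = exp(-||xi - xj||^2 / 2 sigma^2)`): stratified 70/30
   splits, 10-fold cross-validated grid search, ROC/AUC, confusion
   matrices, Pearson marker–status correlations.
4. **Interrogate** the markers: SVM recursive feature elimination with the
   kernel-margin criterion, cross-validated optimal marker count, and
   cumulative Gaussian-noise feature ablation in both importance orders.
5. **Score drug efficacy** from the pair of treated-vs-healthy and
   treated-vs-diseased accuracies (recovery index and verdict).

## Worked example

```r
library(viscomarker)

# a small balanced cohort: 100 measurements per state, 3% noise
cohort <- generate_cohort(cohort_config(
  group_specs = default_group_specs(n = 100), seed = 21))
cohort
#> <cohort_dataset: 300 measurements (status 0: 100, status 1: 100, status 2: 100)>

# recover the nine markers from the noisy indentation records
features <- extract_features(cohort)
attr(features, "fit_report")$median_r2
#> [1] 0.9924558

# healthy (0) vs diseased (2), all nine markers, tuned RBF-SVM
hd <- features[features$status %in% c(0, 2), ]
sp <- split_train_test(hd, train_frac = 0.7, seed = 21)
cv <- cross_validate(sp$train, k = 10, seed = 21)       # picks C = 1, sigma = 2
clf <- train_classifier(sp$train, C = cv$best_C, sigma = cv$best_sigma)
evaluate_classifier(clf, sp$test)
#> <eval_metrics: accuracy 1.0000, AUC 1.0000>
#>      predicted
#> truth  0  2
#>     0 30  0
#>     2  0 30

# marker importance (three-state task) and drug-efficacy readout
rfe_rank(features, C = 10, sigma = 2)$ranking
#> [1] "alphaL" "Esum"   "tau"    "E2"     "E3"     "alphaR" "fT"     "eta"
#> [9] "E1"
recovery_report(features, C = 10, sigma = 2, seed = 21)
#> <recovery_report>
#>   treated vs healthy accuracy:  0.800
#>   treated vs diseased accuracy: 0.900
#>   recovery index: +0.100  ->  partial_recovery
```

The healthy/diseased contrast is essentially perfectly separable from the
marker set, with the short-time exponent `alphaL` and the total modulus
`Esum` ranked most important; the treated group is cleanly distinguished
from diseased tissue but still differs measurably from healthy tissue,
i.e. the simulated treatment produces a partial recovery.

`run_pipeline()` executes the whole chain (simulate, extract, classify,
rank, ablate, assess) for one configuration and writes `ground_truth.csv`,
`feature_table.csv`, `metrics.json`, `ablation_report.json`,
`recovery_report.json` and `run_manifest.json` into an output directory,
reproducibly per seed.

See the vignette `vignettes/liver-state-classification.Rmd` for the model,
the generator calibration, estimator design, and known limitations.

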