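# yieldclass

Classification-based genomic prediction for early-stage yield-trial
advancement decisions in plant breeding.

Early-stage soybean trials evaluate thousands of breeding lines, but seed is
scarce: each line is observed in only a few environments, with two plot
replicates at best. The decision a breeder actually makes is categorical —
advance or discard — so this package reframes genomic prediction as
classification. It is written for quantitative geneticists and breeding-program
analysts who have SNP markers and sparse multi-environment yield data (or want
to study the approach on simulated data first).

## What it computes

1. **Marker pipeline** — QC (monomorphic markers and those with ≥ 20% missing
   data are removed), iterative random-forest imputation (missForest-style),
   VanRaden's genomic relationship matrix
   `G = ZZ' / 2 Σ pⱼ(1 − pⱼ)` from 0/1/2 codes, and marker PCA.
2. **Genomic FA1 mixed model** (`fa1_gblup()`, EM-REML):

   ```
   y_lyg = μ + L_l + (L:Y)_ly + u_g + w_lg + ε_lyg,
   u ~ N(0, σ²g G),   w_lg = λ_l f_g + δ_lg,   w ~ N(0, (ΛΛ' + Ψ) ⊗ G)
   ```

   One latent environmental gradient (loading λ_l per location) plus
   location-specific deviations; information is borrowed across relatives
   through `G` and across environments through `Λ`, so `predict()` fills in
   every genotype × environment cell, observed or not.
3. **Check-referenced selection index** (MSI): per genotype, the average
   percentage-point deviation of its predicted yield from the mean of the
   reference checks of the same maturity group,

   ```
   MSI_i = (1/n) Σ_j (Y_ij / Check_j × 100 − 100)
   ```

   with three classes: high (MSI ≥ −5), moderate (−15 ≤ MSI < −5), low
   (MSI < −15).
4. **Classifiers** — multinomial elastic net and random forest on the SNP
   matrix, evaluated by repeated stratified cross-validation (outer 80/20
   splits; hyperparameters tuned on training data only by inner 5×5-fold CV;
   out-of-fold predictions pooled).
5. **Evaluation & decisions** — full confusion-matrix suite (one-vs-rest
   sensitivity/specificity/precision/NPV/F1/balanced accuracy, macro
   averages, Cohen's kappa, Wald CI, no-information rate with exact binomial
   p-value, per-class McNemar), misclassification severity (correct / mild /
   extreme), a probability-threshold discard rule (discard when
   p(low) ≥ 0.70), and a PCA overlap diagnostic of advance vs discard groups.
6. **Synthetic data** — `simulate_markers()` / `simulate_trials()` generate a
   full early-stage campaign (bi-parental families, sparse trials, checks)
   under the same FA1 model, so the whole pipeline is testable without
   proprietary data.

## Worked example

The MSI scale in three lines — a check reference of 100 in ten environments
and four genotypes at 95%, 100%, 88% and 80% of it:

```r
library(yieldclass)
envs   <- paste0("env", 1:10)
checks <- check_reference(data.frame(env = envs, maturity_group = 4, check_mean = 100))
g      <- gblup_matrix(matrix(c(95, 100, 88, 80), 4, 10,
                              dimnames = list(c("g1","g2","g3","g4"), envs)))
compute_msi(g, checks)
#>   genotype msi n_env yield_class
#> 1       g1  -5    10        high
#> 2       g2   0    10        high
#> 3       g3 -12    10    moderate
#> 4       g4 -20    10         low
```

MSI −5 is exactly 95% of check performance, the high/moderate boundary. And a
small end-to-end run on simulated data — 60 lines from 12 families plus 3
checks, 4 locations × 2 years at 75% observation density:

```r
cfg <- sim_config(n_families = 12, lines_per_family = 5, n_checks = 3,
                  n_markers = 120, n_locations = 4, n_years = 2,
                  lambda_loadings = c(180, 60, 130, 100),
                  psi_diag = c(7000, 10000, 8000, 9000),
                  location_effects = c(-250, 100, 0, 150),
                  ly_effects = matrix(c(-120, 80, 150, -60, 50, -100, 90, 40), 4, 2),
                  sparsity = matrix(0.75, 4, 2), missing_rate = 0, seed = 101)
mk  <- simulate_markers(cfg)
tr  <- simulate_trials(mk, cfg)
grm <- compute_grm(mk[!attr(mk, "is_check"), ])
fit <- fa1_gblup(tr$pheno[!tr$pheno$is_check, ], grm,
                 fa1_control(max_iter = 40, tol = 1e-5))
fit
#> Genomic FA1 multi-environment mixed model (EM-REML)
#>   60 genotypes, 4 locations, 8 environments, 370 records
#>   sigma2_g = 4.811e+04, sigma2_e = 1.51e+05
#>   loadings:  38.5, -19, 139, 141
#>   psi:       1.17e+04, 0, 1.68e+03, 7.05e+03
#>   logLik -2638.637 after 40 iterations (NOT converged)
#>   boundary estimates: psi_loc2

gb  <- predict(fit)          # complete 60 x 8 GBLUP matrix (77% cells observed)
ref <- fit_check_model(tr$pheno[tr$pheno$is_check, ],
                       fa1_control(max_iter = 40, tol = 1e-5))
mg  <- tapply(tr$pheno$maturity_group, tr$pheno$genotype, `[`, 1)
msi <- compute_msi(gb, ref, setNames(as.vector(mg), names(mg)))
msi
#> msi_result: 60 genotypes (mode = all)
#>   MSI mean -12.7, range [-24.0, 2.4]
#>   classes:  low 30.0%, moderate 63.3%, high 6.7%
```

The fit reports variance components (kg²/ha²), the per-location loadings, and
its convergence state (here the iteration cap was reached — estimates are
usable but a longer `max_iter` tightens them; boundary flags mark variance
components estimated at zero). The MSI table is the classifier's training
target; `run_repeated_cv()`, `confusion_matrix()`, `overall_metrics()`,
`severity_analysis()` and `apply_decision_rule()` take it from there.
`run_pipeline()` chains all stages and writes every artifact plus a
reproducibility manifest; `scripts/run_pipeline.R` wraps it for the shell.

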