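---
title: "Methods: classification-based genomic prediction for early-stage yield trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification-based genomic prediction for early-stage yield trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early-stage soybean yield trials evaluate thousands of breeding lines with
very little seed: each line can be planted in only a few of the target
environments, with two replicates at best. Advancement decisions at this
stage are categorical — advance or discard — yet they must integrate noisy,
sparse, multi-environment yield data. `yieldclass` implements a pipeline
that (i) predicts every genotype's yield in every environment with a genomic
mixed model, (ii) summarizes performance relative to elite check cultivars in
a single interpretable index, (iii) categorizes lines into three yield
classes, and (iv) trains SNP-based classifiers that can assign those classes
— with class probabilities — to candidates *before* they are ever planted.

## The genomic FA1 mixed model

Grain yield of genotype $g$ at location $l$ in year $y$ is modelled as

$$y_{lyg} = \mu + L_l + (L{:}Y)_{ly} + u_g + w_{lg} + \epsilon_{lyg},$$

with $u \sim N(0, \sigma^2_g G)$, where $G$ is VanRaden's genomic
relationship matrix computed from SNP codes $\{0,1,2\}$:
$G = ZZ^\top / 2\sum_j p_j(1-p_j)$ with $Z$ the column-centered code matrix.
The genotype-by-location term follows a factor-analytic structure of order 1:
$w_{lg} = \lambda_l f_g + \delta_{lg}$, so that
$w \sim N(0, (\Lambda\Lambda^\top + \Psi)\otimes G)$. One latent
environmental gradient ($f_g$ is genotype $g$'s sensitivity to it,
$\lambda_l$ the degree to which location $l$ expresses it) plus
location-specific deviations $\delta$ with variances $\psi_l$. This
parameterization borrows information across relatives (through $G$) and
across environments (through $\Lambda$), which is what makes predictions for
*unobserved* genotype-by-environment cells possible under sparse testing.

Assumptions worth stating plainly: yields are conditionally Gaussian with a
homogeneous residual variance; one latent factor suffices for the
between-location genetic correlation structure (no FA2 or unstructured
option); loadings are indexed by location, so the two years of a location
share a loading and differ only through the fixed $(L{:}Y)$ term; and checks
— which have no marker data — are modelled separately with an identity
relationship matrix.

### Estimation

`fa1_gblup()` works on the per-(genotype, location) genetic cells
$a_{lg} = u_g + w_{lg}$, whose prior covariance is $\Sigma_L \otimes G$ with
$\Sigma_L = \sigma^2_g \mathbf{1}\mathbf{1}^\top + \Lambda\Lambda^\top + \Psi$.
Each EM-REML iteration solves Henderson's mixed-model equations once (a
dense Cholesky of order $p + nL$), forms the conditional scatter
$S = E[A^\top G^{-1} A \mid y]$, and maximizes the expected complete-data
likelihood of $\Sigma_L$ over $(\sigma^2_g, \Lambda, \Psi)$ — a bounded
quasi-Newton problem in $2L+1$ unknowns — followed by the standard EM-REML
residual update. Because plain EM crawls near convergence, every iteration
also proposes an extrapolated step along the EM direction and keeps it only
if the REML log-likelihood improves; the likelihood trace is therefore
non-decreasing across accepted iterations, which the test suite asserts.

Numerical choices:

* **Convergence** is declared when the relative log-likelihood change falls
  below `tol` (default $10^{-6}$) *and* the maximum relative parameter
  change falls below `tol_par` (default $10^{-4}$). Non-convergence is a
  warning, never silent.
* **Boundary estimates.** $\psi_l$ is kept above a tiny positive floor
  during estimation (the Kronecker prior must stay invertible); estimates at
  the floor are reported as exactly 0 with a `boundary` flag. Negative
  variance estimates cannot occur by construction.
* **Identifiability.** The sign of $\Lambda$ is anchored by making the first
  location's loading non-negative; $f$ has unit prior variance. With a
  single location the FA term is not identifiable at all and the model
  reduces automatically to a main-effects genomic model (`gxl = FALSE`).
  Users should know that when the true loadings are all positive and nearly
  constant, $\sigma^2_g\mathbf{1}\mathbf{1}^\top$ and the mean component of
  $\Lambda\Lambda^\top$ are close to exchangeable: their sum is well
  estimated while the split between them has large sampling variance. The
  parameter-recovery tests therefore use crossover (mixed-sign) loadings,
  the regime in which the decomposition is well identified.
* **The GRM** is checked for positive semi-definiteness (tolerance $-10^{-8}$
  on the smallest eigenvalue relative to the largest) and receives a ridge
  of $10^{-8}\,\overline{\mathrm{diag}(G)}$ before inversion, so duplicated
  genotypes (a singular $G$) are handled.
* **Degenerate input.** A phenotype with no residual variation at all
  returns a fit with every variance component exactly 0 and zero GBLUPs.
* **BLUEs.** The model consumes one record per genotype-by-environment. The
  paper-style input is plot-level RCBD data; by default replicates are
  averaged within genotype and environment and the replicate count enters as
  a residual weight (`blues = "means"`). Precomputed BLUEs pass through with
  `blues = "none"`. How the original analysis computed its per-environment
  BLUEs is not stated in the source; genotype means are the natural choice
  for a two-replicate RCBD without spatial correction.
* **Fixed vs random.** Location and location-by-year effects are fixed by
  default; the source text lists them alongside the grand mean without
  distributional statements. A documented switch (`ly_random = TRUE`)
  treats $(L{:}Y)$ as an iid random effect instead.

`predict()` on a fit returns the complete genotype-by-environment matrix.
On the default `"yield"` scale a cell is
$\hat\mu_e + \hat u_g + \hat\lambda_l \hat f_g + \hat\delta_{lg}$; the fixed
environment mean is included because the selection index divides by the
check mean on the yield scale — a ratio of genetic deviations alone would
not be meaningful. `what = "genetic"` gives the genetic part only.

## The selection index and yield classes

For genotype $i$, with $Y_{ij}$ its predicted yield in environment $j$ and
$\mathrm{Check}_j$ the mean predicted yield of the reference checks of the
same maturity group,

$$\mathrm{MSI}_i = \frac{1}{n}\sum_{j=1}^{n}\left(\frac{Y_{ij}}{\mathrm{Check}_j}\times 100 - 100\right).$$

MSI is scale-free within environments, centered at 0 (equal to the checks),
and averages both yield level and consistency: $-5$ means 95% of check
performance on average. By default the sum runs over **all** environments,
observed and predicted alike — the framework exists precisely to use the
predicted cells; an `"observed"`-only mode is available because the index
definition has also been written with "environments where the genotype was
evaluated". Classes follow the printed thresholds exactly:
high-yielding $\mathrm{MSI} \ge -5$, moderate $-15 \le \mathrm{MSI} < -5$,
low-yielding $\mathrm{MSI} < -15$; both cutoffs are configurable
(`class_thresholds()`). If an environment has no checks of a genotype's
maturity group, the nearest group by numeric distance is used with a warning
(the source is silent on this case). Checks themselves are never classified
or used for classifier training: they have no marker data.

## Classifiers and the cross-validation protocol

Two model families, as in the source framework: a multinomial elastic net
(`glmnet`; predictors standardized internally) and a random forest
(`randomForest`; class probabilities are tree-vote fractions). The
evaluation protocol is repeated, stratified cross-validation: per outer
repetition an 80/20 split preserving class proportions; hyperparameters
tuned on the 80% only, by inner 5-fold cross-validation repeated 5 times;
refit on the full training part; class predictions and probabilities on the
held-out 20%; pooled across repetitions. A training split missing a class is
redrawn and logged. Tuning grids are not stated in the source, so the
defaults mirror common practice of the cited framework: elastic-net mixing
$\alpha \in \{0.1, 0.55, 1\}$ by 10 penalties log-spaced down from the
data-derived maximum; random-forest `mtry`
$\in \{\sqrt m/2, \sqrt m, 2\sqrt m\}$ with 500 trees. The number of outer
repetitions is likewise unstated; the default is 10. Tuning optimizes
accuracy (switchable to kappa). Ties between class probabilities resolve
deterministically in the order low < moderate < high. Class imbalance is
handled by stratification only, matching the source; no resampling or class
weights by default.

## Evaluation suite

All metrics are computed from the pooled 3×3 confusion matrix (class order
low < moderate < high). Class-level metrics use one-vs-rest collapses:
sensitivity, specificity, precision, NPV, F1, balanced accuracy, prevalence,
detection rate, detection prevalence. Zero denominators surface as `NaN`
with an `undefined` flag, never as 0. Overall: accuracy with a Wald 95%
interval using $z = 1.96$ and $n$ = the pooled prediction count (which $n$
belongs in the interval is not stated in the source; pooled count is the
default); Cohen's kappa from the row/column marginals; the no-information
rate (largest class prevalence) with a one-sided exact binomial tail for
accuracy above it; and macro averages as unweighted means over the three
classes. McNemar's test for a 3-class problem is not uniquely defined; it is
implemented per class on the one-vs-rest collapse as $(b-c)^2/(b+c)$ without
continuity correction, all three reported, undefined flagged when
$b + c = 0$. Misclassification severity grades each prediction by its
ordinal distance from the truth: correct (0), mild (1), extreme (2 —
low↔high confusions). The discard rule is boundary-inclusive:
$p(\text{low}) \ge 0.70$ (configurable) designates discard; with pooled CV
predictions, probabilities are first averaged per genotype across
repetitions. The diversity diagnostic compares advance/discard groups on the
first two marker principal components (centroids, mean distance to centroid,
and the fraction of discarded genotypes inside the advance group's 95%
dispersion radius).

## The synthetic-data generator

The study's breeding data are proprietary, so `sim_config()` +
`simulate_markers()` + `simulate_trials()` emulate the campaign the pipeline
targets: 172 bi-parental families × 10 F4:5-derived inbred lines plus 9
reference checks; 2,479 biallelic SNPs; 5 locations × 2 years with a sparse,
uneven observation pattern (per-environment observation probabilities
mirroring a published trial summary, from 5% to 58%); checks present in
every environment and every line observed at least once. Families are
simulated as two inbred parents with independent-locus Mendelian sampling
and residual heterozygosity 1/16 (appropriate to F4:5 lines); there is no
linkage map, because nothing downstream uses one. Yields are generated from
the same FA1 model the pipeline fits, with $u$, $f$ and $\delta$ drawn with
covariance proportional to the realized $G$ of the simulated markers;
checks, which carry no usable markers, receive independent latent values.

The variance defaults are **not** estimates of the proprietary data (the
source reports no variance components). They were chosen once, analytically:
a grand mean of 4,000 kg/ha and plot residual SD of 400 kg/ha are realistic
for mid-south US soybean trials; the checks' fixed advantage (570 kg/ha) and
a total genetic SD near 7% of check yield place the line MSI distribution at
mean ≈ −11.8 with SD ≈ 7, which reproduces the published class split
(≈17% high / 50% moderate / 33% low) under the −5/−15 thresholds. Check
latent effects are scaled to 0.3 of the line SDs — elite released cultivars
are a narrow, selected set — which also keeps the 9-check reference stable
across simulation replicates. Maturity groups III/IV/V are assigned at the
family level with early-stage-typical frequencies (≈8/86/6%).

What the generator does *not* emulate: linkage disequilibrium and map
structure (markers segregate independently), spatial field trend, year
effects on genetic covariance (loadings are location-specific by model
choice), genotype-by-management interaction, and selection during line
derivation. Passing tests on these data therefore demonstrate correctness of
the machinery and the statistical behaviour of the estimators under the
stated model — not performance on real breeding data.

## Test-suite problem sizes

The package's tests exercise the estimators at sizes chosen to make the
statistical checks meaningful while keeping the default suite quick:
parameter recovery and the masked-cell prediction experiment run 10
simulated campaigns of 300 genotypes (30 families × 10 lines), 400 markers
and 6 single-year locations at 80% observation density, with crossover
loadings as explained above; the end-to-end classification-signal check uses
300 lines × 500 markers under the default trial design with 3 outer
repetitions and a reduced inner tuning schedule. The EM solver runs with a
capped iteration budget in these tests; parameter estimates at that budget
are within the tested tolerances, which is the quantity of interest there.

## Known limitations

* FA order is fixed at 1; strongly multi-dimensional GxE will load onto
  $\Psi$ instead.
* The EM solver builds dense mixed-model equations of order $nL$; it is
  comfortable to a few thousand genotype-location cells but is not a sparse
  specialized REML solver, and full-campaign fits (1,780 lines × 10
  environments) take correspondingly longer.
* MSI inherits any bias of the check reference; with a single check per
  maturity group the reference is noisy, and the index is undefined in
  environments where the check mean is non-positive (an error).
* The classifiers see markers only; they cannot separate genotypes whose
  class differences are driven by non-genetic causes, and probability
  calibration is not assessed (no ROC/calibration analysis, as none is used
  in the source framework).
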