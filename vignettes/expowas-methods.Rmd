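---
title: "Methods: exposome-wide association scans for behavioural count scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposome-wide association scans for behavioural count scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`expowas` implements the statistical workflow of a pooled multi-cohort
exposome study: a panel of chemical exposure biomarkers (here 47, in 8
families: organochlorines, PBDEs, PFASs, metals/elements, phthalate
metabolites, phenols, organophosphate pesticide metabolites, cotinine)
measured in maternal blood or urine during pregnancy, related to two
non-negative integer behaviour scores per child (externalizing and
internalizing, each on a 0&ndash;20 scale). Because the scores are
overdispersed counts, the working model throughout is the NB2
negative-binomial regression with log link,

$$ y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
   \log \mu_i = \beta_0 + \beta_E x_i + \gamma' c_i, \qquad
   \mathrm{Var}(y_i) = \mu_i + \mu_i^2/\theta, $$

where $x_i$ is one exposure on its analysis scale and $c_i$ the a-priori
adjustment set (cohort, season of conception, child sex and age at
assessment, parity, maternal age, education, work status, active smoking,
pre-pregnancy BMI). Exposure effects are reported as incidence-rate ratios
$\mathrm{IRR} = e^{\beta_E}$ per interquartile-range (IQR) change of the
log-transformed concentration, which makes effects comparable across
chemicals with very different concentration ranges.

Two complementary strategies are run on the same data:

* an **ExWAS** (one adjusted model per exposure), pooled over multiply
  imputed datasets by Rubin's rules and corrected for multiplicity through
  the effective number of independent exposures, and
* an **adjusted LASSO** (all exposures in one penalized model, adjustment
  covariates unpenalized) with cross-validated penalty choice and
  stability selection across the imputed datasets.

## Exposure preprocessing

The fixed order is: detection filtering, below-LOD imputation,
concentration standardization, log transform, IQR scaling.

1. **Detection filter.** Detection frequency is the share of measured
   (non-missing) values at or above the limit of detection (LOD).
   Biomarkers below `min_detect = 0.10` are dropped. The threshold is a
   package default, chosen so that biomarkers detected in only a few
   percent of samples (for which no tail can be calibrated) are excluded;
   it is configurable.
2. **Below-LOD single imputation.** Left-censored values are drawn from
   the left tail of a log-normal fitted by regression on order statistics:
   observed log concentrations are regressed on their normal quantiles
   (Blom plotting positions computed over the full sample with the
   censored values occupying the lowest ranks), and censored entries are
   replaced by inverse-CDF draws truncated at the LOD, so every imputed
   value is strictly below the LOD and observed values are never touched.
   When fewer than 30% of values are observed the tail cannot be
   calibrated and the conventional LOD/&radic;2 substitution is used,
   flagged in the output.
3. **Standardization.** Urinary biomarkers are divided by creatinine (g/L;
   result in &mu;g/g creatinine); lipophilic blood biomarkers
   (organochlorines, PBDEs) by total serum lipids (g/L; result in ng/g
   lipid); PFASs and elements pass through in &mu;g/L.
4. **Transform and IQR scale.** Cotinine is ln-transformed, every other
   biomarker log2-transformed, and each column divided by the IQR of its
   transformed values. Quartiles use the type-7 (linear interpolation)
   convention; the IQR is computed on pooled all-cohort data because a
   single coefficient per exposure is reported for all cohorts, and it is
   computed *after* creatinine/lipid standardization so that the scale
   belongs to the final analysis variable. The divisors are persisted in a
   `transform_spec`, making the projection idempotent and reusable on new
   data.

The IOM gestational-weight-gain classifier (`classify_gwg`) bands total
gain against the pre-pregnancy-BMI-specific recommended ranges
(BMI &lt; 18.5: 12.5&ndash;18.0 kg; 18.5&ndash;24.9: 11.5&ndash;16.0;
25.0&ndash;29.9: 7.0&ndash;11.5; &ge; 30: 5.0&ndash;9.0), inclusive at
both edges.

## Multiple imputation

Missing exposure values (including biomarkers unmeasured in whole
cohorts) and covariates are completed by fully conditional specification
(`impute_chained`): continuous variables by predictive mean matching with
a Bayesian parameter draw and 5 donors, categorical variables by draws
from multinomial (or logistic) conditional models. The cohort indicator is
always a predictor, so block-missing biomarkers borrow strength across
cohorts. Child sex, child age and the outcome scores are never imputed;
BMI class and the weight-gain category are recomputed from their parents
rather than imputed. The study-scale default is $m = 100$ imputed
datasets with 10 sweeps; the package's desk-scale profiles use
$m = 3{-}10$ with 2&ndash;5 sweeps, which is sufficient because the
imputed fraction of cells is small. The predictor set defaults to "all
other variables"; no formal convergence testing is performed (trace
behaviour can be inspected from the completed stacks).

## The regression engine

`fit_negbin` alternates IRLS for $\beta$ (via `glm.fit` with the
fixed-$\theta$ negative-binomial family) with maximum-likelihood updating
of $\theta$ (`theta.ml`), stopping when the log-likelihood changes by less
than $10^{-8}$ (at most 200 outer iterations). The covariance matrix is
the inverse Fisher information $X'WX$ at the optimum. Along the penalized
path $\theta$ is instead held fixed at the covariates-only estimate,
because re-estimating the dispersion in the high-sparsity region is
unstable. Dose-response linearity is assessed by replacing the linear
exposure term with a restricted cubic spline (natural spline, knots at
the 10/50/90% quantiles for 3 knots; $k$ knots give $k-1$ basis columns,
linear beyond the boundary knots) and comparing nested fits by a
likelihood-ratio test on $k-2$ degrees of freedom; across imputations the
p-values are combined by their median, and the association is declared
linear when the combined p &ge; 0.05.

## The adjusted LASSO

The penalized objective is $-\ell(\beta)/n + \lambda \sum_{j \in
\text{exposures}} |\beta_j|$ with the NB2 log-likelihood at fixed
$\theta$ (a Poisson variant is available by flag). Adjustment covariates
are never penalized: confounders must stay in the model regardless of the
penalty. Exposure columns arrive IQR-standardized from preprocessing, so
no internal rescaling is applied and coefficients remain on the per-IQR
scale. The solver iterates IRLS; each working problem is solved by an
exact weighted-least-squares refit of the unpenalized block alternating
with cyclic soft-threshold coordinate descent over the exposures
(compiled, with precomputed Gram matrices and an active-set loop).
$\lambda_{\max}$ is the largest absolute per-observation score component
of the exposures at the covariates-only fit &mdash; the smallest penalty at
which all exposure coefficients are exactly zero &mdash; and the grid is
log-spaced down to $10^{-3}\lambda_{\max}$ (100 points at study scale, 12&ndash;25
in the desk-scale profiles).

The penalty is chosen by 10-fold cross-validation of the held-out
log-likelihood, folds stratified by cohort, with the **one-SE sparsest
rule**: among the penalties whose mean held-out log-likelihood is within
one standard error of the maximum (the band anchored at the SE of the
maximising penalty; a per-penalty-SE variant is available by flag), the
one with the fewest nonzero exposures on the full-data path is chosen,
ties breaking toward the larger penalty. **Stability selection** repeats
the whole procedure on each imputed dataset with deterministically
derived fold seeds and retains an exposure if it is selected in at least
50% of the runs (the threshold is inclusive). Note the one-SE rule is
deliberately conservative: the fold SE contains between-fold outcome
variability common to all penalties, so only signals whose likelihood
gain exceeds that noise floor survive; in this design that corresponds
roughly to per-IQR |log IRR| &ge; 0.25&ndash;0.3 at $n \approx 700$.

## Pooling, multiplicity, heterogeneity

Per-imputation estimates are combined by Rubin's rules
($\bar Q$, $\bar U$, $B$, $T = \bar U + (1+1/m)B$) with Barnard&ndash;Rubin
degrees of freedom using the complete-data residual df; per-imputation
fits that fail to converge are dropped (never zero-filled), with $m$
adjusted, and an exposure is flagged unreliable when more than 20% of its
fits are dropped.

The family-wise error correction divides $\alpha$ by the **effective
number of independent exposures** $M_e$, computed from the eigenvalues
$\lambda_i$ of the exposure correlation matrix (Pearson, on the
IQR-scaled transformed exposures, averaged across imputed datasets) as

$$ M_e = M - \sum_i I(\lambda_i > 1)(\lambda_i - 1), $$

clamped to $[1, M]$. The bare sum $\sum_i I(\lambda_i>1)(\lambda_i-1)$
degenerates to 0 for independent exposures, where a Bonferroni correction
must use the full $M$; the subtraction from $M$ restores exactly that
behaviour ($M_e = M$ at independence, $1$ under total correlation) and is
what the package uses; the bare form remains available via
`printed_form = TRUE` for comparability.

Between-cohort heterogeneity refits the adjusted model within each cohort
(cohort term removed, full adjustment set retained even in small
cohorts), pools per cohort across imputations, and combines cohorts by
DerSimonian&ndash;Laird random effects. $I^2 = \max(0, (Q - df)/Q)$ is
banded as low (&lt; 0.3), moderate (0.3&ndash;0.6) and
substantial-to-high (&ge; 0.6). The plain DL estimator was chosen over
robust variants for determinism and transparency.

The sensitivity battery mirrors the main scan: coexposure adjustment (all
exposures with main-scan p &lt; 0.2 in one model, iteratively removing
the highest-VIF exposure while any exposure VIF exceeds 10),
exposure-by-sex interactions, a complete-case scan, a scan excluding one
cohort, and a weight-gain-stratified scan of the organochlorines with
pre-pregnancy BMI removed from the adjustment set (the stratification
variable is BMI-specific).

## The synthetic-data generator

Real cohort data of this kind are confidential, so the generator is a
first-class module that emulates the study *structure* with known ground
truth: 708 subjects split 46/193/218/83/168 across five cohorts; 47
biomarkers in the 8 families (8/2/5/9/10/7/5/1) with within-family
correlation 0.5 and between-family correlation 0.1 on the log scale;
cohort-specific log-normal median shifts (SD 0.3); LOD censoring at the
5% quantile for 39 biomarkers and 30% for 8, reproducing the regime in
which most biomarkers are detected in &ge; 89% of samples; block
missingness (metals unmeasured in the two largest cohorts, PBDEs in one)
mirroring biomarkers never assayed in some cohorts; covariates drawn from
the marginal frequencies typical of such cohorts; and NB2 outcomes
(default $\theta = 2$) generated from the inverted analysis model on the
IQR-standardized latent exposures, truncated at 20 by resampling
overflowing draws (the instrument's range), with cohort-specific
intercepts that give one cohort a markedly lower externalizing level.
Exposures are independent of covariates by default (the dependence
structure is not identifiable from published summaries); both effects and
correlations are configurable.

What the generator does **not** emulate: the real joint covariate
distribution, questionnaire item scoring, laboratory batch effects, and
exposure-covariate confounding. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the study's
structure, not that the original cohort estimates are reproduced &mdash;
those depend on confidential data.

## Numerical choices and degenerate inputs

* Quartiles: type-7 everywhere, recorded in `transform_spec`.
* Engine convergence: log-likelihood change &lt; $10^{-8}$; penalized
  path: coefficient change &lt; $10^{-7}$ per penalty (inner coordinate
  descent $10^{-9}$); $\lambda_{\max}$ is inflated by $10^{-6}$
  relatively so finite-tolerance refits cannot push a coefficient across
  the boundary.
* Rank-deficient designs: offending columns are named in errors; aliased
  columns are dropped via pivoted QR inside imputation and scan design
  construction.
* Zero-IQR (constant) biomarkers are dropped with a warning; all-censored
  biomarkers raise an error ("cannot calibrate tail").
* Exact collinearity reports infinite VIF; the coexposure VIF loop
  removes the worst exposure first and logs removals.
* $I^2$ truncation at 0 is exact when cohort estimates are identical.

## Problem sizes used by the test suite

The suite exercises every stage at sizes chosen for a single-CPU desk
run: module tests use 3 cohorts &times; 60&ndash;120 subjects and 8
biomarkers; the calibration checks use the full 708 &times; 47 design
with 100&ndash;200 replicates for CI coverage, type-I error and censored-tail
calibration, 120 complete-data null scans for family-wise error, 10
master seeds at $m = 5$ for stability selection, and a deterministic
end-to-end pipeline at $m = 3$ with a 12-point penalty grid. The
acceptance script re-runs the full pipeline at $m = 5$ with a 20-point
grid plus the same calibration simulations. In the null scans the
completed copies of a complete dataset are identical, so the scan is run
once per dataset; nothing about the pooling changes in that degenerate
case ($B = 0$). For the injected-heterogeneity check the typical
within-cohort variance is set to 0.08 (per-cohort SE &asymp; 0.28, the
small-cohort regime of this design); the analytic reference
$\tau^2/(\tau^2 + v)$ is a large-$k$ approximation whose bias at 5
cohorts grows with the precision ratio, which is why a mid-range ratio is
the right regime for a calibration comparison.

## What the calibration checks show

Two findings from the package's own simulation checks deserve emphasis.

First, the eigenvalue-based effective-number-of-tests correction is a
heuristic, not an exact FWER guarantee: under this design's block
correlation the family-wise rejection rate of the $\alpha/M_e$ threshold
sits a little above the nominal 5% (the suite's null-scan check computes
the realized rate), between full Bonferroni (conservative here) and no
correction. The correction trades strict control for power on correlated
panels; users who need guaranteed control should use $\alpha/M$.

Second, the one-SE sparsest rule has a noise floor: the cross-validation
fold SE contains between-fold outcome variability common to all
penalties, so an exposure is only selected reliably once its held-out
likelihood gain clears that floor. Combined with the outcome truncation
of the score scale (which attenuates generating coefficients by roughly
a fifth) and occasional credit-sharing between correlated family
members, stability selection retains only decidedly strong signals;
weaker true effects are typically flagged by the ExWAS first. This
mirrors the empirical behaviour of such workflows, where the penalized
route selects far fewer exposures than the single-exposure scan.

## Known limitations

* The spline linearity assessment uses fixed-knot restricted cubic
  splines inside the GLM rather than penalized GAM smoothers; with 3
  knots the two approaches rarely disagree on monotone dose-response
  shapes, but the package does not reproduce penalized-smoother wiggle.
* The median rule for combining likelihood-ratio p-values across
  imputations is pragmatic (no exact MI combination rule exists for LRTs
  without refitting on stacked data); it is logged per imputation.
* Stability selection inherits the conservatism of the one-SE rule;
  effects below roughly 0.25 per IQR are usually found by the ExWAS
  before the LASSO retains them.
* The complete-case scan and cohort-exclusion scan are run on the same
  covariate set as the main model; no per-analysis re-selection of
  covariates is attempted.
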