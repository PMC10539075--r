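---
title: "Weighted imputed phenotypes: model, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted imputed phenotypes: model, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case–control GWAS of late-onset dementia (and of many other complex
diseases) discard a large fraction of recruited subjects: those with mild
cognitive impairment (MCI) or an otherwise unresolved diagnosis fit neither
the case nor the control stratum. `wipgwas` implements an association
framework that keeps those subjects. A disease *prediction model* built from
endophenotypes — regional MRI measures, cognitive test scores, demographics —
assigns each unlabeled subject an affection probability $p_i$; the subject is
then imputed as a case ($y_i = 1$) when $p_i \ge 0.5$ and as a control
otherwise, and enters the association test with the analysis weight
$$w_i = \max(p_i, 1 - p_i) \in [0.5, 1],$$
the confidence of its classification. Clinically labeled subjects keep
$w_i = 1$. The tie $p_i = 0.5$ is deliberately coded as a case (the rule is
"$\ge$"); on balanced data this choice is visible, which is why the package
documents it prominently.

## The estimator

Association is tested with a weighted generalized estimating equation under
working independence. With covariates $Z_i$ (intercept, sex, age, PCs, ...)
and SNP dosage $G_i$, the marginal model is
$\mathrm{logit}\,\mu_i = Z_i^\top\alpha + G_i^\top\beta$ and the quasi-score
$$U(\theta) = \sum_i x_i\, w_i\, (y_i - \mu_i(\theta)), \qquad
x_i = (Z_i^\top, G_i^\top)^\top,$$
is solved by Fisher scoring (`wgee()`). Because subjects are independent and
the working correlation is the identity, the Bernoulli-variance GEE with unit
weights *is* ordinary logistic regression; the three analysis methods are
therefore one estimator under different (subset, weight) inputs:

* **LR** — labeled subjects only, $w \equiv 1$;
* **IP** — labeled plus imputed subjects, $w \equiv 1$;
* **WIP** — labeled plus imputed subjects, $w_i = \max(p_i, 1-p_i)$.

The test suite asserts this "one code path" property directly.

Inference uses either the Wald statistic
$\hat\beta^\top \mathrm{cov}(\hat\beta)^{-1} \hat\beta$ or the generalized
score statistic $T = U_P^\top \widehat{\mathrm{var}}(U_P)^{-1} U_P$, where
$U_P$ is the SNP block of the quasi-score evaluated at the covariate-only
null fit. Two covariance flavours are available everywhere: the model-based
inverse weighted information, and the robust sandwich. With unit weights and
the model-based flavour, the score test reduces exactly to the classical Rao
score test, which the tests verify against `anova(..., test = "Rao")` to
$10^{-6}$. With fractional weights the weights are classification
confidences, not sampling frequencies, so the sandwich flavour is the default
for inference; the model-based flavour is kept for diagnostics. Whether the
original analyses used the sandwich or the model-based Wald is not decidable
from their description; providing both makes the choice explicit.

### Numerical choices

* Fisher scoring with step-halving whenever the weighted quasi-log-likelihood
  decreases. The acceptance tolerance of a halved step is *relative*
  ($10^{-8}(1 + |Q|)$): quasi-likelihood sums over $n \sim 10^4$ subjects
  carry rounding noise of order $n\,\varepsilon\,|Q|$, and an absolute
  tolerance below that noise level stalls the solver a few steps short of
  convergence.
* Convergence is declared on the max-norm of the quasi-score,
  $\|U(\hat\theta)\|_\infty < 10^{-8}$, with a 50-iteration cap; fits that
  hit the cap are flagged and the test functions refuse to use them.
* A cheap pre-check rejects single predictors that perfectly separate the
  response, naming the offending column.
* Genotypes are coded as additive dosages of the minor allele; variants whose
  counted allele exceeds frequency 0.5 on input are flipped (the flip is
  recorded, and flips only change the sign of $\hat\beta$, never the
  p-value). Subjects with a missing dosage are dropped per variant, matching
  the de-facto standard behaviour of GWAS tooling.

## The prediction model

`fit_prediction_model()` selects among registered algorithms (plain
logistic, elastic-net penalized logistic, and optionally random forest and
RBF-SVM) by nested cross-validation: outer folds estimate a test AUC per
algorithm, inner folds choose hyperparameters, the best mean outer AUC wins
(ties break by argument order), and the winner is refit on all labeled
subjects. SNP columns are refused as predictors — reusing the genotype both
to impute the phenotype and to test association manufactures false
positives — with a heuristic guard (rs-style names, or three-valued 0/1/2
columns). Hyperparameter grids are package defaults (documented in the
registry); rows with missing predictors are dropped with a warning; one
top-level seed drives fold assignment and all stochastic learners through
deterministic child seeds.

## Bias of imputed-label coefficients and its correction

Imputed labels are misclassified with probabilities $\gamma_0$ (true control
called case) and $\gamma_1$ (true case called control). For a small
coefficient, outcome misclassification attenuates a logistic slope by
$$\hat B = \frac{1 - \gamma_1 - \gamma_0}
  {(1 + \gamma_1 - \gamma_0)(1 - \gamma_1 + \gamma_0)},$$
which is 1 under perfect classification and $1 - 2\gamma$ for symmetric
rates. This expression is exactly the small-$\beta$ attenuation of a
balanced logistic model with flipped labels; the tests validate it against a
200 000-subject Monte-Carlo flip experiment to within 10%. Because the
prediction model is built from the mediating endophenotypes, it captures the
*indirect* part of the SNP effect; only the *direct* proportion
$$d^* = \frac{\beta_{GY}}{\beta_{GY} + \beta_{GX}\beta_{XY}}$$
is attenuated, giving $\beta^* \approx (\hat B d^* + 1 - d^*)\,\beta$ and the
correction $\hat\beta_{\mathrm{adj}} = \beta^* / (\hat B d^* + 1 - d^*)$.
In applications $d^*$ is estimated as the ratio of trait-adjusted to
unadjusted SNP heritability (user inputs; the package does not estimate
heritability). Cohort-level rates scale the imputed-stratum rates
$1-\pi_1, 1-\pi_0$ by the imputed fraction of each true class, with the true
case fraction among imputed subjects $\rho$ supplied by the user (0.15 is a
reasonable default for MCI populations, reflecting annual conversion rates);
the exact parameterization is a documented package choice. The adjustment
applies to effect sizes and odds ratios only — p-values are never modified,
and a test asserts this.

## The simulation study

`sim_config()` + `run_simulation()` reproduce a mediated SNP-effect power
study. Per replicate: a population of $n_{\mathrm{pop}}$ subjects with
equiprobable binary sex $D$, 55 standard-normal traits, one SNP
$G \sim \mathrm{Bin}(2, 0.1)$, and
$$p_i = \mathrm{logit}^{-1}\Big(D_i\alpha + \sum_{j=1}^{55} X_{ij}\gamma_j
  + (1-\nu) G_i \beta_D + \epsilon_i\Big), \quad \epsilon_i \sim N(0,1),$$
where the first $k$ traits mediate: $X_{ij} = X'_{ij} - \nu\beta_I G_i$.
From the population, 5000 cases and 5000 controls are labeled and $n_m/2$
further cases and controls are masked. Each replicate fits a plain logistic
prediction model (sex + 55 traits) on the labeled set, imputes the masked
subjects, runs LR/IP/WIP, and records Wald p-values and coefficients; the
replicate's empirical confusion matrix and the generator's true $d^*$ drive
the per-replicate bias adjustment.

### Calibration of the generator

The effect sizes derive from variance-explained parameters by inverting
$$h_d^2 = \frac{\beta_D^2\,\mathrm{var}(G)}{A + \beta_D^2\,\mathrm{var}(G)},
\qquad
h_i^2 = \frac{S_\gamma\,\beta_I^2\,\mathrm{var}(G)}
  {A + S_\gamma\,\beta_I^2\,\mathrm{var}(G)},$$
with $A = \alpha^2\mathrm{var}(D) + S_\gamma + \mathrm{var}(\epsilon)$ and
$S_\gamma = \sum_j \gamma_j^2$. At $(h_d^2, h_i^2) = (10^{-4}, 10^{-3})$ and
$(\beta_D, \beta_I) = (0.049, 0.088)$ this pins $A = 4.321370$ and
$S_\gamma = 3.103259$ (the package verifies the inversion round-trips to
$10^{-12}$), and hence $\alpha = 0.934$.

Two further quantities are *not* pinned by the aggregates and had to be
fixed as package choices:

1. **The signed indirect aggregate.** The mediated SNP effect on the
   liability scale is $\nu\beta_I S_k$ with
   $S_k = -\sum_{j\le k}\gamma_j$ — it depends on the signed sum of the
   mediating traits' coefficients, not on $S_\gamma$. Real endophenotype
   coefficients have mixed signs (in a dementia setting, atrophy measures
   load negatively), so equal positive $\gamma_j$ — which would force
   $S_k = k\sqrt{S_\gamma/55} = 2.38$ at $k = 10$ and make the total SNP
   effect non-monotone in $\nu$, contradicting the monotone reference power
   curves the simulator is calibrated against (tabulated in the acceptance
   tests) — is not a tenable default. The package instead uses
   $\gamma_j = -S_k/k$ on the mediating traits and alternating-sign
   coefficients elsewhere, with $S_k$ calibrated **once** by Monte-Carlo
   inversion of the labeled-only test's reference power at full mediation:
   $S_k = 0.90$ at $k = 10$ (scaled $\propto\sqrt{k}$ otherwise). With that
   single number fixed, the simulator reproduces the labeled-only power at
   *every* intermediate $\nu$ (0.3, 0.5, 0.8) within Monte-Carlo error —
   a four-point out-of-sample check of the calibration.
2. **The rejection counting rule.** At $\nu = 0$ every generator parameter
   is pinned, yet counting two-sided Wald p-values below 0.05 yields a
   labeled-only power of $\approx 0.095$ where the reference value is
   0.159 — irreconcilable with zero free parameters. Counting rejections
   directionally (one-sided in the risk-allele direction at level
   $\alpha$) predicts $\approx 0.16$ and simultaneously reproduces the
   whole pinned $\nu = 0$ row for all three methods. `run_simulation()`
   therefore counts directionally by default (`alternative = "greater"`),
   which under the null is calibrated at $\alpha$ exactly like the
   two-sided count (the type-I tables do not distinguish the two rules);
   two-sided counting remains available, and reported p-values elsewhere in
   the package are always conventional two-sided p-values.

### Imputed-label enrichment

One structural property of this generator deserves emphasis. The imputer's
residual noise — liability variance unexplained by sex and the traits — is
only $\mathrm{var}(\epsilon) = 1$, while the disease outcome carries the
full noise. At high mediation, imputed labels therefore associate with the
SNP *more* strongly than true labels do: the mean IP/WIP coefficient at
$\nu = 1$ sits a few percent above the labeled-only mean (the acceptance
tests measure this), and IP/WIP power at large $n_m$ can exceed even the
perfect-label bound. How strong the enrichment is depends on per-trait
nuisance structure that the recoverable aggregates do not pin down, so
reduced-scale rates in those high-$\nu$, high-$n_m$ cells should be read
with that caveat.

### What the generator does and does not emulate

It emulates the mediated-effect structure, the case/control/missing sampling
design, per-subject classification uncertainty, and realistic prediction
accuracy (outer AUC $\approx 0.82$ on masked subjects at these settings). It
does **not** emulate linkage disequilibrium, multiple causal variants,
population stratification, covariate-confounded traits, or miscalibrated
prediction probabilities — so passing simulations demonstrate the
operating characteristics of the tests under the stated model, not
robustness to those real-data complications.

### Problem sizes and the fast trait path

Two presets ship: the full design (50 000 subjects, 10 000 replicates) and a
reduced-scale `desk` preset (30 000 subjects, 1000 replicates) used by the
package's own acceptance runs; at 1000 replicates the binomial Monte-Carlo
standard error of a rate near 0.05 is 0.0069, which is the resolution all
reduced-scale comparisons quote. Several $n_m$ values evaluated jointly
share each replicate's population, labeled set and prediction model (masked
sets nested) — per-cell rates remain unbiased and grid studies become three
times cheaper.

By default the harness draws only the *study subjects'* trait vectors, from
the exact conditional law of $X'$ given the trait score
$S = \sum_j \gamma_j X'_j$ (a rank-one Gaussian conditioning), after drawing
$S \sim N(0, S_\gamma)$ for the whole population. Because selection into the
study depends on the data only through $y$, this is distributionally
identical to materializing the full $n_{\mathrm{pop}} \times 55$ trait
matrix — `traits = "full"` does exactly that, and a test checks the two
paths agree statistically. Identical seed and configuration reproduce a
`run_simulation()` result bit-for-bit.

## Known limitations

* The bias correction is a small-coefficient approximation; for
  $|\beta| \gtrsim 0.3$ or misclassification rates above $\approx 0.25$ the
  attenuation factor drifts from the Monte-Carlo truth.
* Weights are treated as known; uncertainty in $\hat p_i$ itself is not
  propagated into the sandwich variance.
* Probability calibration of the prediction model is assumed; strongly
  miscalibrated classifiers (e.g. deep networks) would need recalibration
  before their outputs are used as weights.
* Only binary phenotypes and working independence are implemented;
  longitudinal/clustered GEE and polytomous outcomes are out of scope.
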