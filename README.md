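# wipgwas — weighted imputed phenotypes for case–control genetic association

Case–control GWAS routinely discard subjects whose disease status is
intermediate or unresolved (for Alzheimer's disease, the large mild
cognitive impairment group). `wipgwas` keeps them: a prediction model built
from disease-related endophenotypes (MRI measures, cognitive scores) assigns
each unlabeled subject an affection probability *p*, the subject is imputed
as a case when *p* ≥ 0.5, and the association test weights that subject by
its classification confidence

&nbsp;&nbsp;&nbsp;&nbsp;*w* = max(*p*, 1 − *p*) ∈ [0.5, 1].

SNP association is then tested with a weighted GEE: the quasi-score

&nbsp;&nbsp;&nbsp;&nbsp;U(θ) = Σᵢ xᵢ wᵢ (yᵢ − μᵢ(θ)),&nbsp;&nbsp;
logit μᵢ = Zᵢᵀα + Gᵢᵀβ,

is solved by Fisher scoring, with Wald and generalized score tests of
H₀: β = 0 (model-based and robust sandwich covariances). With unit weights
this is exactly ordinary logistic regression, so the three analysis methods
— **LR** (labeled subjects only), **IP** (imputed labels, unit weights) and
**WIP** (imputed labels, confidence weights) — are one estimator under
different inputs. Because imputation errors attenuate effect estimates, the
package also implements the misclassification bias correction
β̂_adj = β* / (B̂·d* + 1 − d*), where B̂ is the attenuation factor implied by
the misclassification rates and d* the proportion of the SNP effect acting
directly on disease (not through the endophenotypes).

The package is aimed at statistical geneticists who want to (a) run
LR/IP/WIP scans on PLINK bed/bim/fam or VCF genotypes, (b) fit and select
disease prediction models by nested cross-validation, and (c) study the
operating characteristics of the weighted test with the built-in
mediated-SNP-effect simulator.

## Worked example

Fit the weighted association test on a small synthetic cohort with one
planted causal variant (`var1`, per-allele log-odds 0.5):

```r
library(wipgwas)

d <- tempfile()
make_fixtures(d, n = 2000, n_variants = 10, beta = 0.5, seed = 2)
geno  <- read_plink(file.path(d, "toy"))
pheno <- read_subject_table(file.path(d, "pheno.tsv"))
covar <- read_subject_table(file.path(d, "covar.tsv"))
probs <- read_subject_table(file.path(d, "probs.tsv"))

status <- subject_status(pheno$STATUS,
                         probs$P_AFFECTED[match(pheno$IID, probs$IID)])
cohort <- wip_cohort(status, as.matrix(covar[, "SEX", drop = FALSE]),
                     matrix(0, 2000, 1))

scan <- run_scan(geno, cohort, method = "wip",
                 adjust = list(d_star = 0.6, gamma0 = 0.04, gamma1 = 0.08))
head(scan[order(scan$P), c("SNP", "MAF", "OR", "ORADJ", "P")], 3)
#>    SNP     MAF       OR    ORADJ            P
#> 1 var1 0.16225 1.921066 2.019589 3.899571e-12
#> 3 var3 0.28075 1.136983 1.148220 7.810098e-02
#> 8 var8 0.35250 1.127463 1.137873 8.473174e-02
```

The causal variant tops the scan (*p* = 3.9 × 10⁻¹²); its odds ratio 1.92
is attenuated by the imputed labels, and the bias-adjusted `ORADJ` 2.02
moves it back toward the value a fully labeled analysis would give. The
remaining variants are null, as their p-values show. A labeled-only scan of
the same cohort (`method = "lr"`) gives *p* = 5.3 × 10⁻⁸ for `var1` —
keeping the 20% of subjects with imputed status strengthens the signal.

The simulator reproduces the power study that motivates the method
(directional rejection counting at α; see the methods vignette):

```r
cfg <- sim_config(preset = "desk", nu = 1, h2_d = 1e-4, h2_i = 1e-3)
sim <- run_simulation(cfg, reps = 200, seed = 7, n_m = 5000)
subset(sim$table, alpha == 0.05, c(method, rate, se, mean_beta))
#>   method  rate         se  mean_beta
#> 1     lr 0.260 0.03101612 0.04890228
#> 4     ip 0.440 0.03509986 0.05495548
#> 7    wip 0.455 0.03521186 0.05627478
```

With a fully mediated SNP effect (ν = 1), adding 5000 probability-weighted
imputed subjects raises power from 0.26 to 0.46 at no cost in type-I error
(h² = 0 configurations stay at the nominal level; see the test suite).

A thin command-line front end lives in `inst/cli/wip.R`
(`predict`, `assoc`, `simulate`, `adjust`, `make-fixtures` subcommands).

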