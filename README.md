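# curemix

Regularized semi-parametric mixture cure models for high-dimensional
survival data.

## The problem

In many remission cohorts — the motivating case is cytogenetically normal
acute myeloid leukemia (CN-AML) followed for relapse-free survival — the
Kaplan–Meier curve flattens into a long plateau above zero: a latent subset
of patients is effectively *cured* and will never experience the event. A
standard Cox model is misspecified for such mixtures. The mixture cure
model (MCM) separates the two questions the Cox model conflates:

```
S_pop(t | x, z) = (1 − π(x)) + π(x) · S_u(t | z)

π(x)      = expit(b0 + x'b)          incidence: who is susceptible
S_u(t|z)  = S0(t)^exp(z'β)           latency:   when the susceptible relapse
```

with gene-expression covariates feeding both components. `curemix` fits
this model with LASSO penalties on `b` and `β` by an EM algorithm:
posterior susceptibility weights in the E-step, then a fractional-response
penalized logistic regression, a case-weighted penalized Cox partial
likelihood (both by coordinate descent with an Rcpp core), and a weighted
Breslow baseline under the zero-tail constraint (`S_u ≡ 0` beyond the last
event time, which identifies the cure fraction). The nonzero coefficients
are the gene lists: genes associated with cure status, and genes associated
with relapse timing among the susceptible.

The package is aimed at biostatisticians analysing expression-profiled
survival cohorts with a plausible cured fraction, and ships a synthetic
cohort generator so the whole pipeline is testable without external data.

## Worked example

```r
library(curemix)

cfg <- generator_config(n_samples = 250, n_genes = 100, n_blocks = 10,
                        n_true_incidence = 4, n_true_latency = 4, seed = 8)
cohort <- simulate_cohort(cfg)
cohort$data
#> survival_dataset: 250 samples x 100 genes; 110 events ( 44 % ), median follow-up 2.39

pen <- penalty_config(lambda_incidence = 8, lambda_latency = 8, tolerance = 1e-4)
fit <- mcm_fit(cohort$data, pen)
fit
#> Regularized semi-parametric mixture cure model
#>   lambda (incidence, latency): 8 , 8
#>   selected genes: incidence 11 / latency 19
#>   EM iterations: 19 (converged)

head(selected_genes(fit)$cure, 5)
#>       gene coefficient component
#> 11 gene_94  -0.8243566 incidence
#> 1  gene_10   0.7510099 incidence
#> 6  gene_52  -0.5098125 incidence
#> 8  gene_67   0.4306184 incidence
#> 10 gene_84   0.1243048 incidence

strat <- stratify_training(fit, cohort$data)
table(strat$cure_label, strat$risk_group)
#>               high low not_applicable
#>   cured          0   0            123
#>   susceptible   65  62              0

report <- evaluate_fit(fit, cohort$data, horizon = 5)
sprintf("C-statistic: %.3f   5-year AUC: %.3f",
        report$c_statistic, report$auc_at_horizon)
#> "C-statistic: 0.793   5-year AUC: 0.889"
```

Reading the output: 11 genes carry incidence (cure-status) signal and 19
carry latency (relapse-timing) signal at these penalties; the posterior
stratification labels 123 of 250 patients cured (their KM curve is flat at
1 by construction, since every observed event forces posterior
susceptibility 1) and splits the susceptible patients at the training
median risk score into high/low relapse-risk groups of comparable size. The
C-statistic and 5-year time-dependent AUC quantify discrimination of the
combined marker `1 − S_pop(5)`.

For penalty selection use `mcm_cv()` (stratified k-fold CV over a 2-D
penalty grid, scored by held-out observed-data log-likelihood), or run the
whole workflow — simulate/read, cross-validate, fit, stratify, KM curves,
evaluation, all artifacts on disk — with `run_pipeline()`. A thin CLI
wrapper lives at `inst/scripts/curemix.R`. File formats: expression as TSV
(samples in rows, first column `sample_id`), survival tables as CSV
(`sample_id,time,event[,group]`), fitted models as JSON, gene tables / KM
curves / predictions as CSV.

## Documentation

The methods vignette (`vignettes/mixture-cure-modelling.Rmd`) documents the
model and its assumptions, the EM/coordinate-descent machinery, the
zero-tail constraint, penalty tuning, the posterior-vs-expression-based
classification rules, what the synthetic generator does and does not
emulate, and the package's numerical choices.
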