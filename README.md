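# pairprog

Rank-based gene-pair prognostic signatures for transcriptomic cohorts.

## The problem

Risk models built on absolute expression values travel badly between
platforms: microarray and RNA-seq cohorts measure the same biology on
different, nonlinearly related scales, and batch effects add per-sample
distortions on top. `pairprog` implements a prognostic-modelling approach
that removes this failure mode at the representation level. Instead of
expression values, the features are *within-sample gene-pair order
indicators*:

```
pair(A, B; s) = 1  if expression(A) > expression(B) in sample s
                0  otherwise (ties included)
```

Any strictly increasing per-sample transform — log, quantile
normalisation, scaling, the usual models of batch effects — leaves every
indicator unchanged, so a model built on them transfers across platforms
by construction. The package is aimed at computational biologists
building or evaluating survival signatures for bulk expression cohorts
(the motivating application is colon-cancer prognosis).

## The model

A risk score is an exponentiated linear combination of pair indicators
with Cox-fitted coefficients:

```
score(s) = exp( sum_j  beta_j * pair(A_j, B_j; s) )
```

with *high risk* defined as score > cutoff, the cutoff frozen at the
median training score. `mkpc()` builds the model with a four-stage
funnel: enumerate all n(n-1)/2 signature-gene pairs (66 genes → 2,145
pairs), drop uninformative pairs (1-frequency outside [0.2, 0.8] in the
training cohort), screen each survivor with a univariate Cox model
(Wald p < 0.05, Breslow ties), then select by cross-validated L1-penalised
Cox regression and assemble with a joint Cox fit plus one backward
elimination step. A published seven-pair colon-cancer model (cutoff
1.0544) ships as `published_mkpc()`.

Around the core model the package provides: a synthetic-cohort generator
with planted subtypes, planted prognostic pairs under Weibull
proportional hazards, calibrated censoring and monotone batch
distortions; Kaplan–Meier / log-rank evaluation and IPCW time-dependent
ROC AUC at 1/3/5 years; consensus clustering (PAM, subsampled, PAC-based
choice of k) with nearest-medoid and multilayer-perceptron subtype
classifiers (the full 60-combination activation/alpha/solver grid);
single-sample gene-set enrichment (ssGSEA) and tumour mutation burden;
and risk-related gene selection as the intersection of LASSO and
random-forest selectors. `run_pipeline()` sequences everything from one
seeded, manifest-checked configuration.

## Worked example

Simulate a 300-sample cohort with two planted prognostic pairs (log
hazard ratios +1 and −1) among 66 signature genes, fit the model, and
evaluate it:

```r
library(pairprog)

cohort <- simulate_cohort(sim_config(
  n_samples = 300, n_genes = 120, n_signature_genes = 66,
  planted_pairs = data.frame(gene_a = c("G001", "G003"),
                             gene_b = c("G002", "G004"),
                             coefficient = c(1, -1)),
  seed = 2024))

model <- mkpc(cohort$expression, cohort$survival,
              genes = cohort$signature_genes, seed = 7)
model
#> Gene-pair prognostic risk model (risk score = exp(Sum))
#>   Sum = 0.578019 * G001|G002 - 1.04182 * G003|G004 - 0.418598 * G003|G036 + 0.363859 * G004|G022 + 0.508915 * G015|G029
#>   cutoff (median training score): 1.17283
#>   funnel: 2145 pairs -> 895 informative -> 326 screened -> 7 selected -> 5 final
```

Both planted pairs survive the funnel with correctly signed
coefficients; the funnel line shows each reduction step. Scoring and
evaluation:

```r
scores <- predict(model, cohort$expression)
head(scores, 4)
#>   sample linear_sum mkpc_score risk_group
#> 1  S0001 -1.0418186  0.3528125        low
#> 2  S0002 -0.8823978  0.4137895        low
#> 3  S0003 -1.0418186  0.3528125        low
#> 4  S0004 -1.4604167  0.2321395        low

lr <- logrank_test(cohort$survival, scores$risk_group)
#> log-rank chi-square 72.3 (p = 1.8e-17)

td_auc(scores$mkpc_score, cohort$survival, horizons = c(1, 3))
#> Time-dependent AUC (IPCW, cumulative cases / dynamic controls)
#>  horizon horizon_time    auc n_cases n_controls
#>        1        365.2 0.7055      65        187
#>        3       1095.8 0.7812     146         57
```

The risk groups separate survival strongly (a chi-square of 72.3 on one
degree of freedom) and the score discriminates 1- and 3-year outcomes
well above chance (AUC 0.71 and 0.78). The bundled published model is
available directly:

```r
published_mkpc()
#> Gene-pair prognostic risk model (risk score = exp(Sum))
#>   Sum = 1.02806 * MPP2|CPT1C - 1.09876 * PPARGC1A|CD36 + 0.573201 * NOG|CD1B + 0.661607 * GAMT|CCL22 - 0.57286 * GSR|MAGEF1 + 0.593767 * NGF|CD1B + 0.927301 * CRIP2|ACTR8
#>   cutoff (median training score): 1.0544
```

See the methods vignette (`vignettes/pairprog-methods.Rmd`) for the
model assumptions, the synthetic-data design, numerical choices and
known limitations.

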