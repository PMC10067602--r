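---
title: "Gene-pair prognostic modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairprog)
```

## The problem and the model

Prognostic gene signatures trained on one transcriptomic platform often
transfer poorly to another because absolute expression values carry
platform- and batch-specific distortions. `pairprog` builds risk models
from a representation that side-steps this: the *within-sample gene-pair
order indicator*

$$
\mathrm{pair}(A, B; s) \;=\;
\begin{cases}
1 & \text{if } x_{A,s} > x_{B,s},\\
0 & \text{if } x_{A,s} \le x_{B,s},
\end{cases}
$$

where $x_{g,s}$ is the expression of gene $g$ in sample $s$. Ties fall in
the 0 branch. Because the indicator compares two measurements made on the
same sample, it is exactly invariant under any strictly increasing
per-sample transform — log, quantile normalisation, scaling, or the
monotone distortions that batch effects are usually modelled as. This
invariance is not approximate: the package tests it bit-for-bit, from the
raw encoding through to the final risk scores.

The risk model is a linear combination of such indicators with
proportional-hazards coefficients. For a sample $s$ with indicator vector
$z_s$ and fitted coefficients $\beta$, the risk score is

$$\mathrm{score}(s) = \exp(\beta^\top z_s),$$

and a sample is *high risk* when its score strictly exceeds a cutoff
frozen at the median training-cohort score.

### The model-building funnel

`mkpc()` composes four stages, each available separately:

1. **Enumeration** (`enumerate_pairs`): all $n(n-1)/2$ unordered pairs of
   the signature genes, in lexicographic orientation (66 genes give
   2,145 pairs). Orientation is information-neutral: reversing a pair
   flips its indicator and the regression sign absorbs the direction.
2. **Informative-frequency filter** (`filter_informative`): pairs whose
   1-frequency in the *training* cohort lies outside $[0.2, 0.8]$ order
   the same way in almost every sample and are removed; a frequency of
   exactly 0.2 or 0.8 survives (the removal rule is strict inequality).
   The surviving pair list is frozen into the model and reused verbatim
   on test cohorts, so no test-set frequencies ever influence the
   feature set.
3. **Univariate screen** (`univariate_screen`): one single-covariate Cox
   model per pair (Breslow tie handling), kept at Wald $p < 0.05$.
4. **Penalised selection and assembly** (`lasso_select`,
   `multivariate_fit`): an L1-penalised Cox fit over the surviving
   pairs, with the penalty chosen by 10-fold cross-validated partial
   likelihood at its maximiser (the `lambda.min` convention, which
   matches the aggressive reductions this kind of pipeline reports);
   the nonzero-coefficient pairs enter a joint Cox fit, pairs with
   multivariate Wald $p \ge 0.05$ are dropped, and the model is refit
   once. A single backward step is the minimal reading of the final
   reduction such pipelines describe; the threshold is configurable.

Every stage only ever shrinks the feature set, and the fitted object
records the funnel counts (enumerated → informative → screened →
selected → final).

An `mkpc` object prints as the published-style formula, and
`predict()`/`score_mkpc()` return per-sample linear sums, scores and risk
groups. `published_mkpc()` bundles a published seven-pair colon-cancer
score (five risk pairs, two protective pairs, cutoff 1.0544) exactly as
printed in its source; the source's prose mentions eight pairs while its
printed formula lists seven — the package bundles the printed formula
verbatim and does not invent an eighth term.

## The synthetic cohort generator

All statistical claims in the package are exercised on synthetic cohorts
with planted structure (`sim_config()` / `simulate_cohort()`), because
the real cohorts such pipelines are trained on are controlled-access
downloads. The generator emulates:

* **Expression**: log-normal marginals ($\log x \sim \mathcal N(\mu_g +
  \delta_{k,g}, 1)$ with gene baselines $\mu_g \sim U(2, 8)$) — positive
  and right-skewed like RNA-seq magnitudes. Genes are independent given
  the subtype; realistic co-expression beyond subtype structure is out
  of scope, so passing recovery tests demonstrate behaviour under the
  model's own assumptions, not under arbitrary real-data correlation.
* **Subtypes**: each of $K$ subtypes up-shifts its own round-robin block
  of the signature genes by `subtype_shift` log-units (default 1.5).
  The block design makes subtypes equidistant by construction; an
  earlier design with random shift signs could, by chance, give two
  subtypes nearly identical patterns and was replaced because the
  generator's contract is that clustering on signature genes *can*
  recover the subtypes. Defaults are a colon-cancer-like cohort: three
  subtypes with proportions 0.48/0.42/0.10.
* **Survival**: Weibull proportional hazards, $S(t \mid \eta) =
  \exp\{-(t/\lambda)^k e^{\eta}\}$ with shape $k = 1.2$ and scale
  $\lambda = 1500$ days (median survival around four years), where the
  true linear predictor $\eta$ is the sum of planted pair coefficients
  times the *observed* pair indicators. Inverse-CDF sampling gives exact
  draws for any shape.
* **Censoring**: independent exponential, with the rate calibrated by
  bisection (against the realized event times) so the realized censored
  fraction lands within a percentage point of the target; defaults to
  40%, in the 20–60% range typical of these cohorts.
* **Planted pairs**: the two genes of a planted pair share a baseline
  $\mu$, so the pair indicator splits the cohort roughly in half. This
  is deliberate: the pipeline only models frequency-balanced pairs, so
  a planted pair with a skewed baseline difference would be removed by
  the filter before any stage could see it, and the generator's purpose
  is to produce *learnable* truth.
* **Batch distortion**: optionally, each sample's expression column is
  passed through a random strictly increasing map $a x^b + c$
  ($a, b > 0$) or an additive shift. Distortion is applied after
  survival and truth are drawn, so the same seed with and without
  distortion yields identical ground truth — which is what makes the
  bit-for-bit invariance tests possible.

`make_worked_fixture()` is a hand-set 8-gene, 12-sample micro-cohort with
two designed expression ties, used for exact-value tests of the encoder.

## Survival evaluation

`km_estimate` and `logrank_test` wrap the standard product-limit
estimator and $k$-group log-rank statistic (samples censored at an event
time count as at risk for that time). `td_auc` implements the
cumulative-case / dynamic-control time-dependent AUC with
inverse-probability-of-censoring weights: cases at horizon $t$ are
samples with an observed event by $t$, weighted by $1/\hat G(T^-)$ where
$\hat G$ is the Kaplan–Meier estimate of the censoring distribution;
controls are samples still under observation after $t$. Among the several
"time-dependent ROC" definitions in use, the IPCW cumulative/dynamic
estimator was chosen because it is consistent under independent
censoring; published AUC figures computed with unknown estimators are
therefore comparable only qualitatively. Score ties count one half, a
horizon with no cases reports `NA` rather than 0.5, and horizons are
converted from years at 365.25 days/year (cohort times are assumed to be
days; pass `year_days = 1` for data already in years).

## Subtype discovery and classification

`consensus_cluster` reimplements consensus clustering, light-weight:
for each candidate $k$, `reps` subsampled PAM runs (Euclidean distance on
per-gene standardised expression; 80% of samples per run; 1,000
repetitions by default), a consensus matrix of co-clustering frequencies,
and final labels from an average-linkage cut of $1 - $ consensus.

**Choosing $k$.** The package summarises each consensus CDF by the
proportion of ambiguous clustering, $\mathrm{PAC}(k) = F_k(0.9) -
F_k(0.1)$, and chooses the *largest stable* $k$ (PAC $\le 0.1$), falling
back to the PAC minimiser when no candidate is stable. The rationale:
a $k$ at or below the truth clusters stably because the merge of true
clusters is deterministic, while any $k$ above the truth forces
arbitrary splits and ambiguous consensus values; the raw "maximal
incremental CDF area" rule is degenerate in the other direction (the
area gain from $k-1$ to $k$ is dominated by the mechanical increase of
zero entries). The rule was validated on planted cohorts with true
$K = 2, 3, 4$. The 0.1 bound is the conventional PAC ambiguity window.

**A structural limitation worth knowing.** With a minority subtype of
around 10% of samples and per-gene standardisation, the $k$-medoids
*objective itself* can prefer splitting a large cluster over isolating
the minority cluster — the mis-clustered solution has lower total
dissimilarity than the truth, so no amount of restarts fixes it, and
standardisation caps how far a stronger shift can move the clusters
apart. Recovery experiments in this package therefore define "strong
separation" as subtype proportions (0.45, 0.35, 0.20) with a 2-log-unit
shift; with a 0.48/0.42/0.10 cohort the chosen $k$ frequently collapses
to 2 at any shift. This mirrors practice, where very small expression
subtypes are routinely absorbed unless bespoke weighting is used.

**Classifiers.** Two new-sample classifiers are compared, both operating
on per-gene z-scores frozen from training: a nearest-medoid rule (the
medoid of each cluster is the member minimising summed within-cluster
distance, consistent with PAM; ties go to the lowest cluster index) and
a multilayer perceptron with three hidden layers of 16, 64 and 64
neurons, softmax output and mean cross-entropy loss with L2 penalty.
`mlp_grid_search` scans the full $4 \times 5 \times 3 = 60$ grid —
activation (identity, logistic, tanh, relu), penalty $\alpha$ ($10^{-5}
\ldots 10^{-1}$), solver (L-BFGS, SGD with momentum, Adam) — by
stratified cross-validated accuracy (correct patients over all patients,
pooled across folds), and refits the winner on all data. Stratified
folds protect small clusters; everything is deterministic given the
seed. The MLP is implemented in base R (full-batch L-BFGS via `optim`,
hand-written SGD/Adam) with analytically verified gradients, since no
installed R package provides a three-hidden-layer perceptron with this
exact grid. `compare_classifiers` classifies a held-out cohort with both
and prefers the one with the smaller log-rank $p$ across predicted
labels, surfacing degenerate single-class predictions as "not
evaluable" rather than failing.

## Characterisation

`ssgsea_score` implements the single-sample enrichment running sum: per
sample, genes are ranked by expression; walking the ranked list from the
most expressed gene down, the score of a set is the summed difference
between the weighted in-set ECDF (weights $\mathrm{rank}^{0.25}$, the
original single-sample exponent) and the uniform out-of-set ECDF. Scores
depend only on within-sample ranks, hence are monotone-invariant —
matching the pair encoding's robustness rationale. No cross-sample
normalisation is applied by default (`normalize = "minmax"` is
available).

`compute_tmb` counts mutations per megabase. Two conventions are
deliberately explicit because sources often leave them unstated: the
denominator defaults to 38 Mb (the conventional whole-exome territory)
and the counted classes default to the nonsynonymous MAF classes
(missense, nonsense, frameshifts, splice site, in-frame indels,
nonstop, translation start). Both are arguments, not assumptions.
Group comparisons use the two-sided rank-sum test (normal approximation
with tie correction, no continuity correction) and the plain Pearson
chi-square without Yates correction.

## Risk-related gene selection

`differential_expression` uses limma's empirical-Bayes moderated test
between risk groups with Benjamini–Hochberg adjustment (flag threshold:
adjusted $p < 0.01$); genes constant within both groups get $p = 1$ with
a warning rather than an error. `select_rrg` then runs two independent
selectors against a per-sample risk target and intersects them: an
L1-penalised regression (penalty by cross-validated error at its
minimiser) and a random-forest regression whose feature count minimises
cross-validated RMSE over importance-ranked subsets (500 trees for the
importance ranking, permutation importance, 200-tree fits inside the
size scan). The default target is the *continuous* risk linear
predictor: an RMSE-based forest criterion implies a regression target,
and the continuous sum carries strictly more information than the
dichotomised group; `mode = "binary"` provides the logistic/
classification-forest variant for the other reading. An empty
intersection is a valid, logged outcome.

## Pipeline and reproducibility

`run_pipeline()` sequences the stages (simulate-or-load, encode, train
or use the bundled published model, score, evaluate, cluster, classify,
characterise, select risk genes) from one flat configuration (a named
list or YAML file; unknown keys fail validation before anything runs).
One global seed drives everything; each stage derives its own seed
deterministically from the global seed and the stage name, so stages are
reproducible independently and never share RNG streams. Every stage
writes its artifact plus a JSON manifest with parameters, the stage seed
and input/output MD5 checksums keyed by file name — no timestamps — so
a rerun with the same configuration is byte-identical. Model JSON stores
coefficients as full-precision decimal strings parsed once, making
serialisation platform-stable; all randomness in the package goes
through explicit seeds and R's Mersenne-Twister generator with the
caller's RNG state restored afterwards.

## Numerical choices and degenerate inputs

* Cox fits use Breslow tie handling everywhere, so small-sample fits
  match an independent Newton maximisation of the written partial
  likelihood to $10^{-6}$ (tested).
* Cross-validation folds for the Cox LASSO are redrawn (up to five
  times) if a fold has no events; single-feature inputs bypass the
  penalised step, which cannot meaningfully zero the only feature.
* An all-decoy cohort produces an *empty* model with a message; scoring
  an empty model gives every sample score $e^0 = 1$ and the low-risk
  label.
* Expression ties produce indicator 0 (forced by the $\le$ branch);
  duplicate gene rows collapse by mean on load (the common microarray
  convention); gene identifiers are matched case-sensitively after
  whitespace trimming, with no alias resolution.
* Zero-variance genes are guarded in the screen (skipped, warned), in
  z-scaling (unit scale substituted) and in differential expression
  ($p = 1$, warned).

## Problem sizes used in the shipped experiments

The package's own test-and-demonstration experiments run at sizes chosen
to exercise the statistics honestly on a single CPU: funnel-recovery
replicates use $n = 400$ with 3 planted pairs among 50 balanced decoys
(100 replicates), null-calibration uses 200 replicates of $n = 150$,
subtype recovery uses $n = 240$ cohorts with 66 signature genes, and the
acceptance script's survival split is 300 training / 300 test samples.
These sizes match the few-hundred-sample cohorts the method is intended
for; nothing in the implementation depends on them.
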