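---
title: "Prognostic protein signatures: scoring, cross-validated evaluation, and the permutation null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic protein signatures: scoring, cross-validated evaluation, and the permutation null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigsurv)
options(sigsurv.verbose = FALSE)
```

## The problem

Reverse-phase protein arrays (RPPA) measure a few hundred (phospho)protein
abundances per tumor. A *prognostic signature* compresses such a profile
into one risk score per patient,

$$\mathrm{score}_j \;=\; \sum_i w_i\, Y_{ij},$$

where $Y$ is the protein expression matrix after training-set
normalization and $w$ is a sparse weight vector. sigsurv implements three
ways of obtaining $w$ and two protocols for judging whether the resulting
score actually stratifies survival — both designed so that no sample ever
contributes to the model that labels it.

## The three score constructions

**Unweighted pathway score.** $w_i \in \{+1, -1\}$, assigned by curated
biology: positive regulators of a pathway get $+1$, negative regulators
$-1$. The packaged example is the seven-phosphoprotein receptor tyrosine
kinase (RTK) activity signature (EGFR-pY1068, EGFR-pY1173, HER2-pY1248,
HER3-pY1289, SHC-pY317, SRC-pY416, SRC-pY527; all $+1$). No outcome data
enter the weights; only the median threshold (below) depends on the
training set, and even that only through expression.

**Cox-reweighted pathway score.** The same members, but $w$ is the
coefficient vector of a multivariable Cox proportional-hazards fit of the
member proteins on the normalized training data (Efron tie handling).
The score becomes the training-estimated log-hazard linear predictor
restricted to the pathway.

**LASSO-Cox signature.** $w$ is the solution of an $L_1$-penalized Cox
regression over *all* retained proteins; the penalty $\lambda$ is chosen
by internal k-fold cross-validation on the training samples only,
minimizing partial-likelihood deviance (`lambda.min` convention; the
sparser 1-SE rule is available via `lasso_config(rule = "lambda.1se")`).
Proteins with zero coefficients are dropped, so the signature is
pathway-independent and usually sparse.

## Training-set normalization travels with the model

All scores operate on median-centered, SD-scaled expression:
$Y_{ij} = (X_{ij} - m_i)/s_i$ with $m_i, s_i$ the *training-set* median
and sample standard deviation of protein $i$. A fitted `signature_model`
therefore carries its `normalization_params`, and scoring a new sample
applies the training parameters — never statistics of the test data.
Proteins that are constant in training (s.d. $< 10^{-12}$) or more than
20% missing there are dropped for that fit; remaining missing values are
imputed to the training median, i.e. to 0 after scaling, which is neutral
under the linear score.

## Risk groups by median cut

The stratification threshold is the median score of the training samples;
a sample is high-risk iff its score exceeds the threshold *strictly*.
Ties go to low-risk — a deterministic rule worth stating because half of
the training samples sit at or below the median by construction. Constant
scores (e.g. an empty LASSO model) label everyone low-risk with a
warning; downstream statistics record such folds as degenerate rather
than failing or silently propagating `NaN`.

## Protocol 1: repeated three-fold cross-validation

`run_cv()` repeats, ten times by default with seed `base_seed + i`, a
random three-way split. For each fold: normalization and model are fitted
on the out-of-fold two thirds, all samples are scored, the training-median
cut is applied, and four statistics are evaluated **on the held-out third
only**: the two-group log-rank statistic, the hazard ratio of high vs low
(HR $> 1$ means the high group fares worse), the Kaplan–Meier survival
difference $S_{\text{low}}(60) - S_{\text{high}}(60)$ at the 60-month
horizon, and optionally the cumulative/dynamic time-dependent AUC at the
same horizon. Ten iterations of three folds give 30 fold results;
summaries are medians over non-degenerate folds, with degenerate counts
reported. For the LASSO, every training fit also contributes its selected
proteins to a selection-frequency tally — a stability view of the
signature (`top_selected_proteins()`).

Folds are simple random balanced partitions by default; an
event-stratified mode (`stratify_folds = TRUE`) is available for small or
heavily censored cohorts.

## Protocol 2: permutation test of the cross-validated log-rank statistic

A log-rank test on cross-validated labels still has no analytic null:
the labels are data-dependent. `run_permutation_test()` builds the null
empirically:

1. Split the cohort into ten folds; label each sample high/low while its
   fold is held out (model, normalization and threshold all from the
   other nine tenths). The *observed statistic* is the two-group log-rank
   over the pooled labels on the full cohort.
2. For each of $M$ permutations, permute the phenotype — the pair
   (survival time, event status) moves as a unit — against the expression
   rows, and repeat the **entire** procedure: new fold split (unless
   `frozen_folds = TRUE`), refitted normalization and models, re-selected
   $\lambda$. Record the statistic.
3. With $N$ = number of permuted statistics $\geq$ the observed one
   (ties inclusive),

$$p \;=\; \frac{N + 0.5}{M + 1},$$

the continuity-corrected permutation p-value. Its attainable range is
$[0.5/(M{+}1),\ (M{+}0.5)/(M{+}1)]$: with $M = 1000$ the best possible
p-value is $5\times10^{-4}$; desk-scale runs with $M = 99$ bottom out at
$5\times10^{-3}$.

Degenerate runs — a pooled group empty (constant scores in every fold) or
a training fold with fewer than two events for a fitted method — score
statistic 0 and are flagged. Zeros sit at the *bottom* of the null, so
they are conservative for $N$; but note the consequence that when the
observed run itself is degenerate, $N = M$ and $p$ is pinned near 1. On
null data the p-value distribution is therefore super-uniform (valid but
conservative), with an atom near 1, rather than exactly uniform. Fold
balance on stage and sex is checked descriptively (chi-square p-values in
the result) and not enforced.

## The synthetic-cohort generator

`simulate_cohort()` produces cohorts with the structure the analysis
assumes, so that every downstream stage is testable without patient data:

* expression: block-equicorrelated multivariate normal, unit marginal
  variance; defaults `block_size = 10`, `block_correlation = 0.4` — a
  stylized stand-in for the correlated antibody clusters of RPPA panels;
* a random set of `n_causal` proteins carries a proportional-hazards
  effect with alternating-sign coefficients of magnitude
  `beta_magnitude` (default 0.5 per SD of expression);
* event times are Weibull with shape 1.2 (gently increasing hazard) and
  scale 60 months, modulated by $\exp(-x^\top\beta/\text{shape})$;
* censoring is exponential, truncated at 144 months of follow-up, with
  the rate solved numerically (bisection) so the expected censored
  fraction matches `censor_rate` — cohorts of this kind vary widely in
  event fraction, so the target is a first-class parameter;
* sex, stage and age are drawn at fixed marginal frequencies,
  independent of outcome by default.

Default sizes (445 samples, 233 proteins, 10 causal, 65% censored) mirror
a large kidney-cancer RPPA cohort. Covariates and survival come from two
separately seeded RNG streams, so editing non-causal covariates provably
cannot perturb the outcome draws — a property the test suite exercises.

What the generator does *not* emulate: replicate-level antibody noise,
cross-reactivity, batch effects, informative censoring, or non-proportional
hazards. Passing tests on synthetic cohorts therefore demonstrate that the
machinery is correct and calibrated under the assumed model, not that any
particular biological signature is real.

## Numerical choices

* **Survival machinery.** Kaplan–Meier, log-rank and the group hazard
  ratio delegate to the survival package (events precede censorings at
  ties; Efron approximation for Cox ties); the test suite checks them
  against independent brute-force implementations of the product-limit
  and $O-E/V$ formulas.
* **Time-dependent ROC.** Cumulative cases / dynamic controls at the
  60-month horizon, with inverse-probability-of-censoring weights from a
  Kaplan–Meier estimate of the censoring distribution (cases weighted by
  $1/G(T^-)$, controls by $1/G(t)$). This estimator is monotone along the
  threshold sweep by construction; AUC is the trapezoid area.
* **LASSO defaults.** `lasso_config()` defaults to a 10-point
  regularization path down to $0.30\,\lambda_{\max}$, internal 3-fold CV
  for $\lambda$, and convergence threshold $10^{-5}$. These are
  deliberately lean: the permutation protocol re-selects $\lambda$ inside
  every fold of every permutation, so a full permutation null performs
  thousands of penalized fits, and path depth is the dominant cost. On
  planted-signal cohorts of the default scale the truncated path selects
  the same model as a dense path; users fitting a single final model can
  ask for glmnet-like resolution with
  `lasso_config(cv_folds = 10, nlambda = 100, lambda_min_ratio = 1e-4)`.
* **λ-selection loop.** The internal CV computes the grouped (van
  Houwelingen) partial-likelihood deviance
  $\mathrm{dev}(\text{all};\beta_{-k}) - \mathrm{dev}(\text{train}_{-k};\beta_{-k})$
  directly from glmnet path fits with a vectorized Breslow deviance; the
  coordinate descent itself is glmnet's, and the selected $\lambda$
  equals `cv.glmnet`'s `lambda.min` on shared folds and path (asserted in
  the tests). glmnet is called with `standardize = FALSE` because the
  design matrix is already training-normalized; re-standardizing
  internally (by mean rather than median) would silently change the
  normalization scheme.
* **Seeding.** Every stochastic component — generator covariates,
  generator survival draws, outer fold splits, internal $\lambda$ folds,
  each permutation — draws from its own stream derived by a
  multiplicative hash (`derive_seed()`) of the user-visible base seed,
  so results are bit-reproducible and independent of execution order.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at reduced scale, chosen so the
suite exercises every code path with meaningful power: null calibration
of the permutation test uses 40 generated cohorts of 200 samples × 100
proteins with $M = 99$; signal-recovery checks use cohorts of 400 samples
× 200 proteins with 10 causal proteins at $\beta = 0.8$. The acceptance
script runs the default 445 × 233 scale with $M = 99$.

## Known limitations

* Only two-group (high/low) stratification; no multi-group log-rank or
  covariate-adjusted hazard ratios.
* The hazard ratio is Cox-based on the group indicator; with zero events
  in a group it is reported as 0/∞ with a monotone-likelihood flag rather
  than estimated.
* The ROC estimator offers only the IPCW/KM variant (deterministic, no
  bandwidth); nearest-neighbor smoothing is not implemented.
* Pathway definitions beyond the packaged RTK set are user-supplied; the
  package validates the schema (signed unit weights, unique members) but
  cannot validate the biology.
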