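# sigsurv

Prognostic protein-signature risk scores for survival cohorts, evaluated
the unbiased way.

High-throughput protein panels (e.g. reverse-phase protein arrays, RPPA)
yield a few hundred measurements per tumor. Clinical researchers want to
know whether some weighted combination of those measurements predicts
overall survival — and, crucially, whether an apparently impressive
stratification would survive honest out-of-sample evaluation. sigsurv
packages that workflow end to end for biostatisticians and computational
biologists working with samples × proteins matrices plus clinical
follow-up.

## What it computes

Every signature is a linear risk score over training-normalized
expression,

    score_j = Σ_i  w_i · Y_ij ,      Y_ij = (X_ij − median_i) / sd_i ,

with the median and SD taken from the **training set only**. Three weight
constructions are provided:

| method | weights `w` |
|---|---|
| `unweighted_pathway` | curated ±1 per pathway member (packaged example: the 7-phosphoprotein RTK activity signature) |
| `cox_weighted_pathway` | multivariable Cox coefficients of the pathway members, fitted on the training set |
| `lasso` | L1-penalized Cox over all proteins; λ by internal cross-validated partial-likelihood deviance |

Samples are split into high/low risk at the training-set median score
(strict inequality; ties → low). Two evaluation protocols keep every
statistic out-of-sample:

* **Repeated 3-fold cross-validation** (`run_cv`, default 10×3): per
  held-out fold, the log-rank statistic, the high-vs-low hazard ratio,
  the 5-year Kaplan–Meier survival difference, and a censoring-weighted
  time-dependent AUC at 60 months; plus LASSO selection-frequency
  tallies across the 30 training fits.
* **Permutation test of the cross-validated log-rank statistic**
  (`run_permutation_test`): 10-fold cross-validated labeling of every
  sample, then M permutations of the (time, status) phenotype against
  the expression rows with the *entire* cross-validation repeated each
  time, and

      p = (N + 0.5) / (M + 1)

  where N counts permuted statistics ≥ the observed one. With M = 1000
  the best attainable p is 5e−04.

A seeded synthetic-cohort generator (`simulate_cohort`) with correlated
protein blocks, a sparse planted proportional-hazards signal, Weibull
event times and tuned censoring makes the whole pipeline testable
without patient data. See the methods vignette
(`vignettes/signature-evaluation-methods.Rmd`) for the model details and
design choices.

## Worked example

```r
library(sigsurv)
options(sigsurv.verbose = FALSE)

sim <- simulate_cohort(simulation_config(n_samples = 300, n_proteins = 120,
                                         n_causal = 8, beta_magnitude = 0.8,
                                         seed = 7))
cohort <- sim$cohort
cohort
#> cohort: 300 samples x 120 proteins; 102 events

cv <- run_cv(cohort, cv_config("lasso", n_iterations = 10, n_folds = 3,
                               base_seed = 1))
cv
#> cv_summary: 30 folds ( 0 degenerate )
#>   median log-rank 34.576 | median HR 12.922 | median 5-yr diff 0.666
#>   median AUC(60mo) 0.917

head(top_selected_proteins(cv$selection_counts, 5))
#>   protein count
#> 1    P005    30
#> 2    P013    30
#> 3    P023    30
#> 4    P041    30
#> 5    P057    30
sim$truth$causal_protein_ids
#> [1] "P005" "P013" "P023" "P041" "P057" "P087" "P093" "P106"

perm <- run_permutation_test(cohort,
  permutation_config("lasso", n_folds = 10, n_permutations = 99,
                     base_seed = 2))
perm
#> permutation_result: observed log-rank 103.446 | N = 0 of M = 99 >= observed | p = 0.005
#>   degenerate permutations (statistic 0): 21
```

Reading the output: across the 30 held-out folds the LASSO signature
stratifies the cohort with a median hazard ratio of 12.9 and a 66.6
percentage-point 5-year survival gap — unsurprising, since the generator
planted a strong 8-protein signal, and indeed the five most frequently
selected proteins (chosen in all 30 training fits) are planted causal
proteins. The pooled cross-validated log-rank statistic, 103.4, exceeds
all 99 phenotype-permutation replicates, giving the smallest p this M
can produce, (0 + 0.5)/(99 + 1) = 0.005. The 21 flagged permutations are
null refits in which the LASSO selected the empty model in every fold
(constant scores, statistic 0) — counted conservatively in the null.

Real cohorts enter through `read_expression_csv()` (TCPA level-4 style
CSV), `read_clinical_table()` (TSV with sample_id / os_months / os_event
/ sex / stage / age_years) and `build_cohort()`, which matches the two by
specimen ID. Pathway definitions load from a 3-column TSV via
`read_pathway_definitions()`; `rtk_pathway()` returns the packaged RTK
set. A thin command-line front end with `simulate`, `cv-eval`,
`perm-test` and `compare` subcommands lives at `inst/cli/sigsurv.R`; every
run writes TSV/JSON outputs plus a `manifest.json` with seeds and file
digests.

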