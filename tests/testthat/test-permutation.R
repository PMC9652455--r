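test_that("the continuity-corrected p-value matches its closed form", {
  expect_equal(permutation_p_value(0, 1000), 0.5 / 1001)
  expect_equal(signif(permutation_p_value(0, 1000), 2), 5e-04)
  expect_equal(permutation_p_value(1, 1000), 1.5 / 1001)
  expect_equal(signif(permutation_p_value(1, 1000), 2), 1.5e-03)
  expect_equal(permutation_p_value(1, 1), 0.75)
  expect_equal(permutation_p_value(1000, 1000), 1000.5 / 1001)
  expect_error(permutation_p_value(5, 4), "\\[0, M\\]")
  expect_error(permutation_p_value(-1, 4), "\\[0, M\\]")
})

test_that("increasing the observed statistic never increases N or p", {
  perm <- c(0.5, 1.2, 3.0, 3.0, 7.7)
  n_for <- function(obs) sum(perm >= obs)
  obs_grid <- c(0, 1, 3, 5, 8)
  ns <- vapply(obs_grid, n_for, numeric(1))
  expect_true(all(diff(ns) <= 0))
  ps <- vapply(ns, permutation_p_value, numeric(1), M = 5)
  expect_true(all(diff(ps) <= 0))
})

test_that("cross-validated labeling assigns every sample exactly once", {
  co <- tiny_cohort(n = 100, p = 10)
  pw <- pathway_definition("p", c("P01", "P02"), c(1, -1))
  res <- cross_validated_labels(co, permutation_config(
    "unweighted_pathway", n_folds = 10, base_seed = 3, pathway = pw))
  expect_length(res$labels, 100L)
  expect_true(all(res$labels %in% c("high", "low")))
  expect_named(res$labels, co$clinical$sample_id)
  expect_false(res$degenerate)
  expect_gte(res$statistic, 0)
})

test_that("unweighted-pathway labels ignore the outcome entirely", {
  co <- tiny_cohort(n = 80, p = 10)
  pw <- pathway_definition("p", c("P01", "P03"), c(1, 1))
  cfg <- permutation_config("unweighted_pathway", n_folds = 5,
                            base_seed = 11, pathway = pw)
  res1 <- cross_validated_labels(co, cfg)
  shuffled <- co
  perm <- withr::with_seed(99, sample(80))
  shuffled$clinical$os_months <- co$clinical$os_months[perm]
  shuffled$clinical$os_event <- co$clinical$os_event[perm]
  res2 <- cross_validated_labels(shuffled, cfg)
  expect_identical(res1$labels, res2$labels)
})

test_that("a strong planted signal separates the pooled KM curves", {
  ok <- vapply(1:3, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_samples = 250, n_proteins = 50, n_causal = 5, beta_magnitude = 1.0,
      seed = 40 + s))
    res <- cross_validated_labels(sim$cohort, permutation_config(
      "lasso", n_folds = 10, base_seed = s))
    cl <- sim$cohort$clinical
    s_low <- survival_at(km_estimate(cl$os_months[res$labels == "low"],
                                     cl$os_event[res$labels == "low"]), 60)
    s_high <- survival_at(km_estimate(cl$os_months[res$labels == "high"],
                                      cl$os_event[res$labels == "high"]), 60)
    as.numeric(s_low) - as.numeric(s_high) > 0
  }, logical(1))
  expect_gte(mean(ok), 2 / 3)
})

test_that("the permutation test is deterministic and respects its bounds", {
  co <- tiny_cohort(n = 80, p = 10)
  cfg <- permutation_config("lasso", n_folds = 5, n_permutations = 10,
                            base_seed = 21)
  r1 <- run_permutation_test(co, cfg, progress_every = 0)
  r2 <- run_permutation_test(co, cfg, progress_every = 0)
  expect_identical(r1, r2)
  M <- cfg$n_permutations
  expect_gte(r1$p_value, 0.5 / (M + 1))
  expect_lte(r1$p_value, (M + 0.5) / (M + 1))
  expect_equal(r1$p_value,
               permutation_p_value(r1$n_exceeding, M))
  expect_length(r1$permuted_statistics, M)
  expect_true(all(r1$permuted_statistics >= 0))
})

test_that("frozen-fold and re-split nulls both run and differ as expected", {
  co <- tiny_cohort(n = 60, p = 8)
  pw <- pathway_definition("p", c("P01", "P02"), c(1, 1))
  base <- permutation_config("unweighted_pathway", n_folds = 5,
                             n_permutations = 8, base_seed = 2, pathway = pw)
  frozen <- permutation_config("unweighted_pathway", n_folds = 5,
                               n_permutations = 8, base_seed = 2, pathway = pw,
                               frozen_folds = TRUE)
  r_base <- run_permutation_test(co, base, progress_every = 0)
  r_frozen <- run_permutation_test(co, frozen, progress_every = 0)
  expect_identical(r_base$observed_statistic, r_frozen$observed_statistic)
  # with frozen folds and an outcome-blind score, labels equal the observed
  # run's labels, so every permuted statistic is a relabeling of the same
  # pooled groups
  expect_length(r_frozen$permuted_statistics, 8L)
})

test_that("degenerate permutation runs score zero and are flagged", {
  co <- tiny_cohort(n = 50, p = 8)
  # heavy penalty forces empty models -> constant scores -> all-low labels
  cfg <- permutation_config("lasso", n_folds = 5, n_permutations = 5,
                            base_seed = 3, lasso = lasso_config(
                              lambda = c(60, 50, 40)))
  r <- suppressWarnings(run_permutation_test(co, cfg, progress_every = 0))
  expect_true(r$observed_degenerate)
  expect_equal(r$observed_statistic, 0)
  expect_equal(r$n_degenerate_permutations, 5L)
  expect_true(all(r$permuted_statistics == 0))
  # every permuted statistic ties the observed zero: p at its maximum
  expect_equal(r$p_value, (5 + 0.5) / 6)
})

test_that("fold balance diagnostics are reported descriptively", {
  co <- tiny_cohort(n = 100, p = 8)
  cfg <- permutation_config("lasso", n_folds = 5, n_permutations = 3,
                            base_seed = 13)
  r <- run_permutation_test(co, cfg, progress_every = 0)
  expect_named(r$balance, c("stage", "sex"))
})
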