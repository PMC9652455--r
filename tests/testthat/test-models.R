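test_that("Cox-reweighted pathway recovers a planted single-protein effect", {
  sim <- simulate_cohort(simulation_config(
    n_samples = 1000, n_proteins = 10, n_causal = 1, beta_magnitude = 0.5,
    block_correlation = 0, seed = 17))
  causal <- sim$truth$causal_protein_ids
  pw <- pathway_definition("causal", causal, 1)
  m <- fit_cox_weighted_pathway_model(sim$cohort, pw,
                                      sim$cohort$clinical$sample_id)
  expect_equal(m$method, "cox_weighted_pathway")
  expect_lt(abs(unname(m$weights[causal]) - sim$truth$true_betas[[1]]), 0.15)
})

test_that("Cox weights of outcome-independent proteins concentrate near zero", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_samples = 1000, n_proteins = 4, n_causal = 0,
      block_correlation = 0, seed = 700 + s))
    pw <- pathway_definition("null", colnames(sim$cohort$expression)[1], 1)
    m <- fit_cox_weighted_pathway_model(sim$cohort, pw,
                                        sim$cohort$clinical$sample_id)
    abs(unname(m$weights)) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Cox pathway weights are invariant to training-set order", {
  co <- tiny_cohort(n = 120)
  pw <- pathway_definition("p", c("P01", "P02", "P03"), c(1, 1, -1))
  ids <- co$clinical$sample_id[1:80]
  m1 <- fit_cox_weighted_pathway_model(co, pw, ids)
  m2 <- fit_cox_weighted_pathway_model(co, pw, rev(ids))
  expect_equal(m1$weights, m2$weights, tolerance = 1e-12)
})

test_that("collinear pathway members produce a singular-design error", {
  co <- tiny_cohort(n = 60)
  co$expression[, "P02"] <- co$expression[, "P01"]
  pw <- pathway_definition("dup", c("P01", "P02"), c(1, 1))
  expect_error(
    suppressWarnings(fit_cox_weighted_pathway_model(co, pw,
                                                    co$clinical$sample_id)),
    "singular")
})

test_that("a forced heavy penalty returns the empty model with a warning", {
  co <- tiny_cohort(n = 80)
  cfg <- lasso_config(lambda = c(50, 40, 30))
  expect_warning(
    m <- fit_lasso_model(co, co$clinical$sample_id, cfg, seed = 1),
    "empty model")
  expect_length(m$weights, 0L)
  expect_equal(unname(score_cohort(co, m)), rep(0, 80))
})

test_that("the unpenalized limit of the lasso path matches the Cox fit", {
  sim <- simulate_cohort(simulation_config(
    n_samples = 400, n_proteins = 5, n_causal = 2, beta_magnitude = 0.5,
    block_correlation = 0, seed = 31))
  co <- sim$cohort
  ids <- co$clinical$sample_id
  norm <- fit_normalization(co$expression, ids)
  xn <- apply_normalization(co$expression, norm)
  cl <- co$clinical
  cfg <- lasso_config(lambda = c(0.5, 0.1, 0.02, 0.004, 1e-4, 1e-6),
                      thresh = 1e-14, maxit = 1e7)
  res <- sigsurv:::fit_lasso_weights(xn, cl$os_months, cl$os_event, cfg, seed = 1)
  beta_path_end <- res$fit$beta[, ncol(res$fit$beta)]
  beta_cox <- sigsurv:::fit_cox_weights(xn, cl$os_months, cl$os_event,
                                        colnames(xn))
  expect_lt(max(abs(beta_path_end - beta_cox)), 1e-3)
})

test_that("lambda selection matches cv.glmnet on shared folds and path", {
  for (s in 1:3) {
    withr::with_seed(s, {
      x <- matrix(rnorm(150 * 30), 150, 30,
                  dimnames = list(sprintf("s%d", 1:150), sprintf("p%d", 1:30)))
      tt <- rexp(150, exp(0.6 * x[, 1]))
      ee <- rbinom(150, 1, 0.7)
    })
    res <- sigsurv:::fit_lasso_weights(
      x, tt, ee, lasso_config(cv_folds = 5, nlambda = 20,
                              lambda_min_ratio = 0.05), seed = s)
    ref <- glmnet::cv.glmnet(x, survival::Surv(tt, ee), family = "cox",
                             foldid = res$foldid, lambda = res$fit$lambda,
                             standardize = FALSE, thresh = 1e-5)
    expect_equal(res$lambda, ref$lambda.min)
  }
})

test_that("sparsity shrinks toward the empty model as the penalty grows", {
  sim <- simulate_cohort(simulation_config(
    n_samples = 200, n_proteins = 50, n_causal = 5, beta_magnitude = 0.6,
    seed = 13))
  co <- sim$cohort
  norm <- fit_normalization(co$expression, co$clinical$sample_id)
  xn <- apply_normalization(co$expression, norm)
  res <- sigsurv:::fit_lasso_weights(
    xn, co$clinical$os_months, co$clinical$os_event,
    lasso_config(nlambda = 30, lambda_min_ratio = 0.05), seed = 2)
  df <- res$fit$df  # path runs from the largest lambda downward
  expect_equal(df[1], 0)                   # full shrinkage at the path top
  expect_equal(max(df), df[length(df)], tolerance = 1e-12)
  # active-set size grows strongly monotonically; the lasso path permits
  # transient single-variable exits, so allow bounded dips only
  expect_true(all(cummax(df) - df <= 2))
  expect_gt(cor(seq_along(df), df, method = "kendall"), 0.8)
})

test_that("lasso support recovers a strong planted signal", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_samples = 400, n_proteins = 200, n_causal = 10,
      beta_magnitude = 0.8, seed = 900 + s))
    m <- fit_lasso_model(sim$cohort, sim$cohort$clinical$sample_id,
                         seed = s)
    sum(sim$truth$causal_protein_ids %in% names(m$weights)) >= 7
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("lasso stays sparse on null data", {
  sizes <- vapply(1:10, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_samples = 200, n_proteins = 100, n_causal = 0, seed = 1100 + s))
    m <- suppressWarnings(
      fit_lasso_model(sim$cohort, sim$cohort$clinical$sample_id, seed = s))
    length(m$weights)
  }, numeric(1))
  expect_lte(median(sizes), 5)
})

test_that("model fits demand enough events in the training set", {
  co <- tiny_cohort(n = 30)
  co$clinical$os_event <- 0
  co$clinical$os_event[1] <- 1
  pw <- pathway_definition("p", "P01", 1)
  expect_error(fit_cox_weighted_pathway_model(co, pw, co$clinical$sample_id),
               ">= 2 events")
  expect_error(fit_lasso_model(co, co$clinical$sample_id, seed = 1),
               ">= 2 events")
})
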