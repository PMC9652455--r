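test_that("Kaplan-Meier matches hand-computed product limits", {
  # no events: survival is 1 everywhere
  cv0 <- km_estimate(c(5, 10), c(0, 0))
  expect_length(cv0$times, 0L)
  expect_equal(survival_at(cv0, 7), 1)

  # all events at distinct times
  cv1 <- km_estimate(1:4, rep(1, 4))
  expect_equal(cv1$survival, c(3/4, 1/2, 1/4, 0))
  expect_equal(cv1$at_risk, c(4L, 3L, 2L, 1L))

  # censored observation tied with an event stays at risk at that time
  cv2 <- km_estimate(c(2, 2, 5), c(1, 0, 1))
  expect_equal(cv2$times, c(2, 5))
  expect_equal(cv2$survival, c(2/3, 0))
})

test_that("KM agrees with the brute-force oracle on random censored data", {
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(4:10, 1)
      times <- sample(1:8, n, replace = TRUE)
      events <- rbinom(n, 1, 0.7)
    })
    if (sum(events) == 0) next
    got <- km_estimate(times, events)
    ref <- km_brute(times, events)
    expect_equal(got$times, ref$times)
    expect_lt(max(abs(got$survival - ref$survival)), 1e-9)
  }
})

test_that("KM with no censoring equals the empirical survival function", {
  withr::with_seed(3, times <- rexp(40))
  cv <- km_estimate(times, rep(1, 40))
  emp <- vapply(cv$times, function(t) mean(times > t), numeric(1))
  expect_lt(max(abs(cv$survival - emp)), 1e-12)
})

test_that("survival_at does right-continuous step lookup with extrapolation flag", {
  cv <- km_estimate(1:4, rep(1, 4))
  expect_equal(survival_at(cv, 0), 1)
  expect_equal(survival_at(cv, 2.5), 0.5)
  beyond <- survival_at(cv, 10)
  expect_equal(as.numeric(beyond), 0)
  expect_true(attr(beyond, "extrapolated"))
})

test_that("log-rank matches the brute-force O-E/V oracle and is label-symmetric", {
  times <- 1:6; events <- rep(1, 6)
  g <- c("A", "A", "A", "B", "B", "B")
  lr <- logrank_two_group(times, events, g)
  expect_lt(abs(lr$statistic - logrank_brute(times, events, g)), 1e-9)
  expect_equal(sum(lr$observed_events), sum(lr$expected_events), tolerance = 1e-9)

  swapped <- logrank_two_group(times, events, ifelse(g == "A", "B", "A"))
  expect_equal(lr$statistic, swapped$statistic)

  for (s in 1:8) {
    withr::with_seed(100 + s, {
      n <- sample(6:10, 1)
      tt <- sample(1:9, n, replace = TRUE)
      ee <- rbinom(n, 1, 0.8)
      gg <- c("A", "B", sample(c("A", "B"), n - 2, replace = TRUE))
    })
    if (sum(ee) == 0) next
    expect_lt(abs(logrank_two_group(tt, ee, gg)$statistic -
                    logrank_brute(tt, ee, gg)), 1e-9)
  }
})

test_that("identical survival in both groups gives a null log-rank statistic", {
  times <- c(2, 5, 7, 9); events <- c(1, 0, 1, 1)
  lr <- logrank_two_group(rep(times, 2), rep(events, 2),
                          rep(c("A", "B"), each = 4))
  expect_lt(lr$statistic, 1e-9)
})

test_that("log-rank equals the Cox score test on no-ties data", {
  for (s in 1:5) {
    withr::with_seed(200 + s, {
      n <- 40
      g <- rep(c("A", "B"), each = n / 2)
      tt <- rexp(n, ifelse(g == "A", 1, 1.8))
      ee <- rbinom(n, 1, 0.85)
    })
    lr <- logrank_two_group(tt, ee, g)
    sc <- survival::coxph(survival::Surv(tt, ee) ~ I(g == "B"))$score
    expect_lt(abs(lr$statistic - sc), 1e-6)
  }
})

test_that("degenerate group configurations raise, not return, silent zeros", {
  expect_error(logrank_two_group(1:4, rep(1, 4), rep("A", 4)), "single_group")
  expect_error(logrank_two_group(1:4, rep(0, 4), c("A", "A", "B", "B")),
               "no_events")
})

test_that("hazard ratio is oriented high-vs-low, reciprocal, and unbiased", {
  times <- c(2, 5, 7, 9); events <- c(1, 0, 1, 1)
  hr1 <- hazard_ratio_high_vs_low(rep(times, 2), rep(events, 2),
                                  rep(c("high", "low"), each = 4))
  expect_equal(as.numeric(hr1), 1, tolerance = 1e-6)

  withr::with_seed(5, {
    g <- rep(c("high", "low"), each = 1000)
    tt <- rexp(2000, ifelse(g == "high", 3, 1))
    ee <- rep(1, 2000)
  })
  hr <- hazard_ratio_high_vs_low(tt, ee, g)
  expect_lt(abs(hr - 3) / 3, 0.15)
  hr_swap <- hazard_ratio_high_vs_low(tt, ee, ifelse(g == "high", "low", "high"))
  expect_equal(as.numeric(hr * hr_swap), 1, tolerance = 1e-6)
})

test_that("log hazard ratio is nearly unbiased on large two-group exponential data", {
  est <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      g <- rep(c("high", "low"), each = 1000)
      tt <- rexp(2000, ifelse(g == "high", 2, 1))
      ee <- rbinom(2000, 1, 0.8)
    })
    log(hazard_ratio_high_vs_low(tt, ee, g))
  }, numeric(1))
  expect_lt(abs(mean(est) - log(2)) / log(2), 0.05)
})

test_that("monotone-likelihood hazard ratios are flagged, not fabricated", {
  tt <- c(1, 2, 3, 10, 11, 12)
  hr <- hazard_ratio_high_vs_low(tt, c(1, 1, 1, 0, 0, 0),
                                 rep(c("high", "low"), each = 3))
  expect_equal(as.numeric(hr), Inf)
  expect_true(attr(hr, "monotone"))
  hr2 <- hazard_ratio_high_vs_low(tt, c(0, 0, 0, 1, 1, 1),
                                  rep(c("high", "low"), each = 3))
  expect_equal(as.numeric(hr2), 0)
})

test_that("time-dependent ROC behaves at the null, at perfection, and under negation", {
  withr::with_seed(9, {
    n <- 500
    tt <- rexp(n, 1 / 60)
    ee <- rbinom(n, 1, 0.8)
    sc <- rnorm(n)  # independent of outcome
  })
  roc0 <- time_dependent_roc(sc, tt, ee, horizon_months = 60)
  expect_lt(abs(roc0$auc - 0.5), 0.07)
  expect_true(all(diff(roc0$tpr) <= 1e-12))
  expect_true(all(diff(roc0$fpr) <= 1e-12))

  # perfect ranking, no censoring
  withr::with_seed(10, tt2 <- runif(100, 1, 120))
  roc1 <- time_dependent_roc(-tt2, tt2, rep(1, 100), horizon_months = 60)
  expect_equal(roc1$auc, 1)

  roc_neg <- time_dependent_roc(-sc, tt, ee, horizon_months = 60)
  expect_equal(roc_neg$auc, 1 - roc0$auc, tolerance = 1e-9)

  expect_error(time_dependent_roc(sc, tt, rep(0, 500), horizon_months = 60),
               "no cases")
  expect_error(time_dependent_roc(1:3, c(1, 2, 3), c(1, 1, 1),
                                  horizon_months = 60), "no controls")
})

test_that("km_table exports per-group curves", {
  tab <- km_table(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(sort(unique(tab$group)), c("a", "b"))
  expect_equal(tab$survival[tab$group == "a"], c(0.5, 0))
})
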