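# Permutation test of the cross-validated log-rank statistic. Every
# sample receives its risk label while held out of a k-fold
# cross-validation (default ten folds); the observed statistic is the
# two-group log-rank over the pooled labels on the full cohort. The null
# is built by permuting the phenotype (survival time and status together)
# against the expression rows and repeating the ENTIRE cross-validation
# - fold split, normalization, model fit and lambda selection included -
# for each permutation. p = (N + 0.5)/(M + 1).

#' Configuration of the permutation test
#'
#' @param method,pathway,lasso as in [cv_config()].
#' @param n_folds folds of the label-assigning cross-validation
#'   (default 10).
#' @param n_permutations number of permutations M (default 1000; use a
#'   smaller M such as 99 for desk-scale runs).
#' @param base_seed integer seed; each permutation derives its own stream.
#' @param frozen_folds reuse the observed fold assignment for every
#'   permutation instead of re-splitting (default FALSE: the full
#'   procedure, splitting included, is inside the null).
#' @param stratify_folds balance folds on the event indicator.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(method = c("lasso", "unweighted_pathway",
                                          "cox_weighted_pathway"),
                               n_folds = 10L, n_permutations = 1000L,
                               base_seed = 1L, pathway = NULL,
                               lasso = lasso_config(),
                               frozen_folds = FALSE,
                               stratify_folds = FALSE) {
  method <- match.arg(method)
  stopifnot(n_folds >= 2, n_permutations >= 1)
  if (method != "lasso" && is.null(pathway)) {
    stop("pathway methods require a pathway definition", call. = FALSE)
  }
  structure(list(method = method, n_folds = as.integer(n_folds),
                 n_permutations = as.integer(n_permutations),
                 base_seed = as.integer(base_seed), pathway = pathway,
                 lasso = lasso, frozen_folds = isTRUE(frozen_folds),
                 stratify_folds = isTRUE(stratify_folds)),
            class = "permutation_config")
}

# one full cross-validated labeling pass over given outcome vectors
cv_label_pass <- function(expr, times, events, config, split_seed,
                          folds = NULL) {
  n <- nrow(expr)
  if (is.null(folds)) {
    folds <- withr::with_seed(
      split_seed,
      make_folds(n, config$n_folds,
                 stratify = if (config$stratify_folds) events else NULL))
  }
  labels <- character(n)
  degenerate <- FALSE
  reason <- ""
  for (f in seq_len(config$n_folds)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    if (sum(events[train_idx]) < 2 &&
        config$method != "unweighted_pathway") {
      degenerate <- TRUE
      reason <- "training fold with < 2 events"
      break
    }
    fit <- fit_fold(expr, times, events, train_idx, config$method,
                    config$pathway, config$lasso, derive_seed(split_seed, f))
    labels[test_idx] <- fit$group[test_idx]
  }
  statistic <- 0
  if (!degenerate) {
    reason_lr <- degenerate_groups(times, events, labels)
    if (is.null(reason_lr)) {
      statistic <- logrank_two_group(times, events, labels)$statistic
    } else {
      degenerate <- TRUE
      reason <- reason_lr
    }
  }
  list(labels = labels, statistic = statistic, folds = folds,
       degenerate = degenerate, reason = reason)
}

#' Cross-validated risk labels and pooled log-rank statistic
#'
#' Splits the cohort into `n_folds` folds; each sample is labeled high or
#' low risk by a model (normalization and training-median threshold
#' included) fitted while the sample's fold was held out. After the last
#' fold every sample carries exactly one label; the cross-validated
#' log-rank statistic is the two-group log-rank of those pooled labels on
#' the full cohort. Degenerate runs (a pooled group empty, or a training
#' fold with < 2 events for a fitted method) report `statistic = 0` with
#' the reason flagged.
#'
#' @param cohort a `cohort`.
#' @param config a [permutation_config()].
#' @return list with `labels` (named per-sample vector), `statistic`,
#'   `folds`, `degenerate`, `reason`.
#' @export
cross_validated_labels <- function(cohort, config) {
  validate_cohort(cohort)
  stopifnot(inherits(config, "permutation_config"))
  if (nrow(cohort$expression) < config$n_folds) {
    stop("fewer samples than folds", call. = FALSE)
  }
  if (sum(cohort$clinical$os_event) < 1) stop("no events", call. = FALSE)
  res <- cv_label_pass(cohort$expression, cohort$clinical$os_months,
                       cohort$clinical$os_event, config,
                       split_seed = derive_seed(config$base_seed, 0L))
  res$labels <- stats::setNames(res$labels, rownames(cohort$expression))
  res
}

#' Continuity-corrected permutation p-value
#'
#' `p = (N + 0.5) / (M + 1)`, where `N` of `M` permutations reached a
#' statistic at least as large as the observed one and 0.5 is the
#' continuity correction, so `0.5/(M+1) <= p <= (M+0.5)/(M+1)`: the best
#' attainable p with M = 1000 is 5e-04.
#'
#' @param N number of permutations with statistic >= observed.
#' @param M number of permutations.
#' @return the p-value.
#' @export
permutation_p_value <- function(N, M) {
  stopifnot(M >= 1)
  if (N < 0 || N > M) stop("N must lie in [0, M]", call. = FALSE)
  (N + 0.5) / (M + 1)
}

#' Permutation test of the cross-validated log-rank statistic
#'
#' Computes the observed cross-validated log-rank statistic, then for each
#' of M permutations jointly permutes the (os_months, os_event) pairs
#' against the expression rows and repeats the whole cross-validation from
#' scratch (fold re-split unless `frozen_folds`, normalization, model
#' refit, lambda re-selection). Degenerate permutation runs score 0
#' (conservative for N) and are flagged. The fold-balance of the observed
#' partition on stage and sex is reported descriptively (chi-square
#' p-values), not enforced.
#'
#' @param cohort a `cohort`.
#' @param config a [permutation_config()].
#' @param progress_every emit a progress message every this many
#'   permutations (0 = silent).
#' @return object of class `permutation_result`: list with
#'   `observed_statistic`, `permuted_statistics`, `n_exceeding`,
#'   `p_value`, `pooled_labels`, `n_degenerate_permutations`,
#'   `balance`, `config`.
#' @export
run_permutation_test <- function(cohort, config, progress_every = 100L) {
  validate_cohort(cohort)
  stopifnot(inherits(config, "permutation_config"))
  obs <- cross_validated_labels(cohort, config)
  if (obs$degenerate) {
    warning("observed cross-validation pass is degenerate: ", obs$reason,
            call. = FALSE)
  }
  expr <- cohort$expression
  times <- cohort$clinical$os_months
  events <- cohort$clinical$os_event
  n <- nrow(expr)
  M <- config$n_permutations
  stat_perm <- numeric(M)
  degen <- logical(M)
  for (m in seq_len(M)) {
    pseed <- derive_seed(config$base_seed, m)
    perm <- withr::with_seed(pseed, sample.int(n))
    res <- cv_label_pass(expr, times[perm], events[perm], config,
                         split_seed = derive_seed(pseed, 1L),
                         folds = if (config$frozen_folds) obs$folds else NULL)
    stat_perm[m] <- res$statistic
    degen[m] <- res$degenerate
    if (progress_every > 0 && m %% progress_every == 0L) {
      msg("permutation ", m, "/", M)
    }
  }
  N <- sum(stat_perm >= obs$statistic)
  structure(list(
    observed_statistic = obs$statistic,
    permuted_statistics = stat_perm,
    n_exceeding = N,
    p_value = permutation_p_value(N, M),
    pooled_labels = obs$labels,
    observed_degenerate = obs$degenerate,
    n_degenerate_permutations = sum(degen),
    balance = fold_balance(cohort, obs$folds),
    config = config
  ), class = "permutation_result")
}

# descriptive chi-square check of fold balance on stage and sex
fold_balance <- function(cohort, folds) {
  out <- list()
  for (v in c("stage", "sex")) {
    tab <- table(cohort$clinical[[v]], folds)
    out[[v]] <- tryCatch(
      suppressWarnings(stats::chisq.test(tab)$p.value),
      error = function(e) NA_real_)
  }
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  M <- length(x$permuted_statistics)
  cat(sprintf(
    "permutation_result: observed log-rank %.3f | N = %d of M = %d >= observed | p = %.4g\n",
    x$observed_statistic, x$n_exceeding, M, x$p_value))
  if (x$n_degenerate_permutations > 0) {
    cat("  degenerate permutations (statistic 0):",
        x$n_degenerate_permutations, "\n")
  }
  invisible(x)
}
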