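# Repeated k-fold cross-validation evaluation: for every iteration the
# cohort is split into folds; models (normalization included) are fitted
# on the out-of-fold training 2/3, scores computed for all samples, the
# training-median cut applied, and survival statistics evaluated on the
# held-out fold only.

#' Configuration of the cross-validation evaluation
#'
#' @param method `"unweighted_pathway"`, `"cox_weighted_pathway"` or
#'   `"lasso"`.
#' @param n_iterations number of CV repetitions, each with its own seed.
#' @param n_folds folds per iteration (>= 2).
#' @param base_seed integer; iteration `i` uses seed `base_seed + i`.
#' @param pathway a [pathway_definition()]; required for the two pathway
#'   methods.
#' @param horizon_months horizon for the KM survival difference and ROC.
#' @param lasso a [lasso_config()].
#' @param stratify_folds balance folds on the event indicator.
#' @param compute_roc also compute the time-dependent AUC per fold.
#' @return a `cv_config` list.
#' @export
cv_config <- function(method = c("lasso", "unweighted_pathway",
                                 "cox_weighted_pathway"),
                      n_iterations = 10L, n_folds = 3L, base_seed = 1L,
                      pathway = NULL, horizon_months = 60,
                      lasso = lasso_config(), stratify_folds = FALSE,
                      compute_roc = TRUE) {
  method <- match.arg(method)
  stopifnot(n_iterations >= 1, n_folds >= 2, horizon_months > 0)
  if (method != "lasso" && is.null(pathway)) {
    stop("pathway methods require a pathway definition", call. = FALSE)
  }
  structure(list(method = method, n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds),
                 base_seed = as.integer(base_seed), pathway = pathway,
                 horizon_months = horizon_months, lasso = lasso,
                 stratify_folds = isTRUE(stratify_folds),
                 compute_roc = isTRUE(compute_roc)),
            class = "cv_config")
}

# internal: fit normalization + model on the training rows, score all
# samples, apply the training-median cut. `seed` feeds the lasso's
# internal-CV fold stream only.
fit_fold <- function(expr, times, events, train_idx, method, pathway,
                     lasso_cfg, seed) {
  train_ids <- rownames(expr)[train_idx]
  norm <- fit_normalization(expr, train_ids)
  xn <- apply_normalization(expr, norm)
  if (method == "unweighted_pathway") {
    retained <- intersect(names(pathway$weights), norm$protein_ids)
    if (length(retained) == 0L) stop("no pathway member retained", call. = FALSE)
    w <- pathway$weights[retained]
    lambda <- NA_real_
  } else if (method == "cox_weighted_pathway") {
    retained <- intersect(names(pathway$weights), norm$protein_ids)
    if (length(retained) == 0L) stop("no pathway member retained", call. = FALSE)
    w <- fit_cox_weights(xn[train_idx, , drop = FALSE],
                         times[train_idx], events[train_idx], retained)
    lambda <- NA_real_
  } else {
    res <- fit_lasso_weights(xn[train_idx, , drop = FALSE],
                             times[train_idx], events[train_idx],
                             lasso_cfg, seed)
    w <- res$weights
    lambda <- res$lambda
  }
  scores <- if (length(w) > 0) {
    drop(xn[, names(w), drop = FALSE] %*% w)
  } else {
    stats::setNames(rep(0, nrow(xn)), rownames(xn))
  }
  threshold <- stats::median(scores[train_idx])
  group <- ifelse(scores > threshold, "high", "low")
  list(weights = w, lambda = lambda, norm = norm, scores = scores,
       threshold = threshold, group = group)
}

evaluate_heldout <- function(times, events, group, scores, horizon,
                             compute_roc) {
  out <- list(logrank_statistic = NA_real_, hazard_ratio = NA_real_,
              hr_flagged = FALSE, surv_diff = NA_real_, auc = NA_real_,
              n_high = sum(group == "high"), n_low = sum(group == "low"),
              degenerate = FALSE, reason = "")
  reason <- degenerate_groups(times, events, group)
  if (!is.null(reason)) {
    out$degenerate <- TRUE
    out$reason <- reason
    return(out)
  }
  lr <- logrank_two_group(times, events, group)
  out$logrank_statistic <- lr$statistic
  hr <- hazard_ratio_high_vs_low(times, events, group)
  out$hr_flagged <- isTRUE(attr(hr, "monotone"))
  out$hazard_ratio <- as.numeric(hr)
  s_low <- survival_at(km_estimate(times[group == "low"],
                                   events[group == "low"]), horizon)
  s_high <- survival_at(km_estimate(times[group == "high"],
                                    events[group == "high"]), horizon)
  out$surv_diff <- as.numeric(s_low) - as.numeric(s_high)
  if (compute_roc) {
    out$auc <- tryCatch(
      time_dependent_roc(scores, times, events, horizon)$auc,
      error = function(e) NA_real_)
  }
  out
}

#' Run the repeated k-fold cross-validation evaluation
#'
#' For each iteration (seed `base_seed + iteration`) the cohort is
#' partitioned into `n_folds` folds. For each fold the signature
#' (normalization included) is fitted on the out-of-fold samples, scores
#' are computed for all samples, the training-score median becomes the
#' risk cutoff, and the log-rank statistic, high-vs-low hazard ratio,
#' Kaplan-Meier survival difference at the horizon and (optionally) the
#' time-dependent AUC are evaluated on the held-out fold only. For the
#' LASSO method the non-zero proteins of every training fit are tallied
#' into selection counts.
#'
#' @param cohort a `cohort`.
#' @param config a [cv_config()].
#' @return object of class `cv_summary`; see [summarize_cv()].
#' @export
run_cv <- function(cohort, config) {
  validate_cohort(cohort)
  stopifnot(inherits(config, "cv_config"))
  expr <- cohort$expression
  times <- cohort$clinical$os_months
  events <- cohort$clinical$os_event
  n <- nrow(expr)
  if (n < config$n_folds) stop("fewer samples than folds", call. = FALSE)
  if (sum(events) < config$n_folds) {
    stop("fewer events than folds; cross-validation not meaningful",
         call. = FALSE)
  }
  rows <- vector("list", config$n_iterations * config$n_folds)
  counts <- integer(0)
  r <- 0L
  for (i in seq_len(config$n_iterations)) {
    iter_seed <- config$base_seed + i
    folds <- withr::with_seed(
      iter_seed,
      make_folds(n, config$n_folds,
                 stratify = if (config$stratify_folds) events else NULL))
    for (f in seq_len(config$n_folds)) {
      train_idx <- which(folds != f)
      test_idx <- which(folds == f)
      fit <- fit_fold(expr, times, events, train_idx, config$method,
                      config$pathway, config$lasso,
                      derive_seed(iter_seed, f))
      if (config$method == "lasso" && length(fit$weights) > 0) {
        sel <- names(fit$weights)
        new <- setdiff(sel, names(counts))
        if (length(new) > 0) counts[new] <- 0L
        counts[sel] <- counts[sel] + 1L
      }
      ev <- evaluate_heldout(times[test_idx], events[test_idx],
                             fit$group[test_idx], fit$scores[test_idx],
                             config$horizon_months, config$compute_roc)
      r <- r + 1L
      rows[[r]] <- data.frame(
        iteration = i, fold = f,
        logrank_statistic = ev$logrank_statistic,
        hazard_ratio = ev$hazard_ratio, hr_flagged = ev$hr_flagged,
        surv_diff_5yr = ev$surv_diff, auc = ev$auc,
        n_test_high = ev$n_high, n_test_low = ev$n_low,
        n_selected = length(fit$weights),
        lambda = fit$lambda,
        degenerate = ev$degenerate, reason = ev$reason,
        stringsAsFactors = FALSE)
    }
  }
  fold_results <- do.call(rbind, rows)
  out <- summarize_cv(fold_results)
  out$selection_counts <- sort(counts, decreasing = TRUE)
  out$config <- config
  out
}

#' Summarize cross-validation fold results
#'
#' Medians are taken over non-degenerate folds only (a fold is degenerate
#' when its held-out part has a single risk group or no events); hazard
#' ratios flagged for monotone likelihood (zero events in one group) are
#' additionally excluded from the HR median. Degenerate counts are
#' reported rather than silently propagated.
#'
#' @param fold_results data.frame of per-fold results from [run_cv()].
#' @return object of class `cv_summary`: list with `fold_results`,
#'   `median_logrank`, `median_hr`, `median_surv_diff`, `median_auc`,
#'   `n_degenerate`, `selection_counts`.
#' @export
summarize_cv <- function(fold_results) {
  ok <- !fold_results$degenerate
  if (!any(ok)) stop("all folds degenerate", call. = FALSE)
  hr_ok <- ok & !fold_results$hr_flagged
  structure(list(
    fold_results = fold_results,
    median_logrank = stats::median(fold_results$logrank_statistic[ok]),
    median_hr = stats::median(fold_results$hazard_ratio[hr_ok]),
    median_surv_diff = stats::median(fold_results$surv_diff_5yr[ok]),
    median_auc = stats::median(fold_results$auc[ok], na.rm = TRUE),
    n_degenerate = sum(!ok),
    selection_counts = integer(0)
  ), class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("cv_summary:", nrow(x$fold_results), "folds (",
      x$n_degenerate, "degenerate )\n")
  cat(sprintf("  median log-rank %.3f | median HR %.3f | median 5-yr diff %.3f\n",
              x$median_logrank, x$median_hr, x$median_surv_diff))
  if (!is.na(x$median_auc)) cat(sprintf("  median AUC(60mo) %.3f\n", x$median_auc))
  invisible(x)
}

#' Rank proteins by LASSO selection frequency
#'
#' Sorts proteins by how often they received a non-zero LASSO weight
#' across the cross-validation training fits; ties broken lexicographically
#' by protein ID.
#'
#' @param selection_counts named integer vector (protein -> count).
#' @param k number of top proteins to return (capped at the total).
#' @return data.frame with columns `protein` and `count`, ordered.
#' @export
top_selected_proteins <- function(selection_counts, k = 20L) {
  if (length(selection_counts) == 0L) stop("empty selection counts", call. = FALSE)
  ord <- order(-selection_counts, names(selection_counts))
  k <- min(k, length(selection_counts))
  data.frame(protein = names(selection_counts)[ord][seq_len(k)],
             count = as.integer(selection_counts[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Subgroup Kaplan-Meier export
#'
#' Per-subgroup KM curves of the high/low risk groups, for clinical
#' covariate subsets (e.g. per stage or sex); a data export, no plotting.
#'
#' @param cohort a `cohort`.
#' @param group per-sample `"high"`/`"low"` labels (cohort order).
#' @param by clinical column to split on (`"sex"` or `"stage"`).
#' @return data.frame of KM steps with columns subgroup, group, time,
#'   survival, at_risk, n_events.
#' @export
subgroup_km <- function(cohort, group, by = c("stage", "sex")) {
  by <- match.arg(by)
  validate_cohort(cohort)
  stopifnot(length(group) == nrow(cohort$expression))
  lev <- unique(cohort$clinical[[by]])
  do.call(rbind, lapply(sort(lev), function(l) {
    sel <- cohort$clinical[[by]] == l
    if (sum(sel) == 0L) return(NULL)
    tab <- km_table(cohort$clinical$os_months[sel],
                    cohort$clinical$os_event[sel], group[sel])
    if (is.null(tab)) return(NULL)
    cbind(subgroup = l, tab)
  }))
}
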