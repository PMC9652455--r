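# The three signature-score constructions. Every model is a
# `signature_model`: a sparse named weight vector w over protein IDs plus
# the training-set normalization it must travel with; the per-sample risk
# score is the inner product  score = sum_i w_i * Y_i  of the weights with
# the normalized expression values Y.

new_signature_model <- function(method, weights, norm, lambda = NA_real_) {
  stopifnot(inherits(norm, "normalization_params"))
  if (length(weights) > 0 && !all(names(weights) %in% norm$protein_ids)) {
    stop("model weights refer to proteins absent from the normalization",
         call. = FALSE)
  }
  structure(list(method = method,
                 weights = weights,
                 norm = norm,
                 lambda_selected = lambda,
                 training_sample_ids = norm$training_ids),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("signature_model [", x$method, "]: ", length(x$weights),
      " non-zero weight(s)", sep = "")
  if (!is.na(x$lambda_selected)) cat(", lambda =", signif(x$lambda_selected, 4))
  cat("\n")
  invisible(x)
}

#' Unweighted (+1/-1) pathway signature model
#'
#' Uses the pathway's literature-assigned +1/-1 weights directly. Members
#' dropped by the training normalization are excluded with a warning; the
#' model errors only when no member survives.
#'
#' @param pathway a [pathway_definition()].
#' @param norm a [fit_normalization()] result from the training set.
#' @return a `signature_model` with method `"unweighted_pathway"`.
#' @export
make_unweighted_pathway_model <- function(pathway, norm) {
  stopifnot(inherits(pathway, "pathway_definition"))
  retained <- intersect(names(pathway$weights), norm$protein_ids)
  lost <- setdiff(names(pathway$weights), retained)
  if (length(retained) == 0L) {
    stop("no pathway member retained after normalization", call. = FALSE)
  }
  if (length(lost) > 0L) {
    warning("pathway member(s) dropped by normalization: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  new_signature_model("unweighted_pathway", pathway$weights[retained], norm)
}

# internal: multivariable Cox fit of the member proteins on normalized
# training data; returns the coefficient vector
fit_cox_weights <- function(x_train, times, events, member_ids,
                            eps = 1e-9, iter_max = 50L) {
  df <- data.frame(x_train[, member_ids, drop = FALSE], check.names = FALSE)
  df$..time <- times
  df$..event <- events
  fml <- stats::as.formula(paste(
    "survival::Surv(..time, ..event) ~",
    paste(sprintf("`%s`", member_ids), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(eps = eps,
                                                           iter.max = iter_max))
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("singular design in Cox pathway fit (collinear members); ",
         "consider dropping redundant proteins or a ridge fit", call. = FALSE)
  }
  if (fit$iter >= iter_max) {
    stop("Cox pathway fit did not converge in ", iter_max, " iterations",
         call. = FALSE)
  }
  stats::setNames(as.numeric(co), member_ids)
}

#' Cox-reweighted pathway signature model
#'
#' Replaces the pathway's +1/-1 weights by the coefficients (log hazard
#' ratios) of a multivariable Cox proportional-hazards fit of the member
#' proteins on the normalized training data (Efron tie handling).
#'
#' @param cohort a `cohort`.
#' @param pathway a [pathway_definition()].
#' @param training_ids training-set sample IDs (>= 2 events required).
#' @param missing_cap passed to [fit_normalization()].
#' @return a `signature_model` with method `"cox_weighted_pathway"`.
#' @export
fit_cox_weighted_pathway_model <- function(cohort, pathway, training_ids,
                                           missing_cap = 0.2) {
  validate_cohort(cohort)
  stopifnot(inherits(pathway, "pathway_definition"))
  idx <- match(training_ids, cohort$clinical$sample_id)
  if (anyNA(idx)) stop("training_ids not all in cohort", call. = FALSE)
  if (sum(cohort$clinical$os_event[idx]) < 2) {
    stop("training set needs >= 2 events for a Cox fit", call. = FALSE)
  }
  norm <- fit_normalization(cohort$expression, training_ids, missing_cap)
  retained <- intersect(names(pathway$weights), norm$protein_ids)
  if (length(retained) == 0L) {
    stop("no pathway member retained after normalization", call. = FALSE)
  }
  xn <- apply_normalization(cohort$expression[training_ids, , drop = FALSE], norm)
  w <- fit_cox_weights(xn, cohort$clinical$os_months[idx],
                       cohort$clinical$os_event[idx], retained)
  new_signature_model("cox_weighted_pathway", w, norm)
}

#' Configuration of the LASSO-Cox fit
#'
#' Controls the L1-penalized Cox fit and its internal cross-validation for
#' the penalty `lambda`. Defaults use a short regularization path and
#' 3-fold internal CV so the fit stays fast enough to sit inside a
#' permutation null that refits it thousands of times; see the methods
#' vignette for the rationale and for how to recover full glmnet defaults.
#'
#' @param cv_folds internal CV folds for selecting lambda.
#' @param nlambda number of points on the lambda path.
#' @param lambda_min_ratio ratio of smallest to largest lambda.
#' @param thresh coordinate-descent convergence threshold.
#' @param rule `"lambda.min"` (CV-deviance minimizer, default) or
#'   `"lambda.1se"` (sparsest model within one standard error).
#' @param lambda optional explicit lambda path (overrides
#'   `nlambda`/`lambda_min_ratio`).
#' @param maxit maximum glmnet iterations.
#' @return a `lasso_config` list.
#' @export
lasso_config <- function(cv_folds = 3L, nlambda = 10L,
                         lambda_min_ratio = 0.30, thresh = 1e-5,
                         rule = c("lambda.min", "lambda.1se"),
                         lambda = NULL, maxit = 1e5) {
  rule <- match.arg(rule)
  stopifnot(cv_folds >= 2, nlambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(cv_folds = as.integer(cv_folds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 thresh = thresh, rule = rule,
                 lambda = lambda, maxit = maxit),
            class = "lasso_config")
}

# Breslow partial-likelihood deviance of one or more linear predictors
# (columns of lp_mat): -2 * sum over events of
# (lp_i - log sum_{j: t_j >= t_i} exp(lp_j)). Vectorized over the whole
# lambda path at once.
breslow_deviance_path <- function(lp_mat, times, events) {
  ord <- order(times, decreasing = TRUE)
  lp <- lp_mat[ord, , drop = FALSE]
  ev <- events[ord]
  tt <- times[ord]
  den <- apply(exp(lp), 2L, cumsum)
  if (anyDuplicated(tt)) {
    runs <- rle(tt)$lengths  # tied samples share the full risk-set denominator
    den <- den[rep(cumsum(runs), runs), , drop = FALSE]
  }
  -2 * colSums(ev * (lp - log(den)))
}

breslow_deviance <- function(lp, times, events) {
  as.numeric(breslow_deviance_path(matrix(lp, ncol = 1L), times, events))
}

# internal: L1-penalized Cox fit on normalized training data. Returns the
# sparse non-zero weight vector and the selected lambda. The internal CV
# fold assignment comes from its own seeded stream (`seed`), decoupled
# from the outer cross-validation stream.
#
# Lambda is selected by k-fold cross-validated partial-likelihood deviance
# in the grouped (van Houwelingen) form cv.glmnet uses for Cox models:
# each fold contributes dev(all; beta_fold) - dev(train_fold; beta_fold).
# The CV loop is implemented here directly on glmnet() path fits because
# this selection sits inside the permutation null and runs tens of
# thousands of times; cv.glmnet's prediction-matrix bookkeeping dominates
# its runtime at these problem sizes. Equality of the selected lambda and
# CV curve with cv.glmnet (same folds, same path) is asserted in the tests.
fit_lasso_weights <- function(x_train, times, events, config, seed) {
  n <- nrow(x_train)
  foldid <- withr::with_seed(derive_seed(seed, 101L),
                             make_folds(n, config$cv_folds))
  y <- survival::Surv(times, events)
  args <- list(x = x_train, y = y, family = "cox", standardize = FALSE,
               thresh = config$thresh, maxit = config$maxit)
  if (is.null(config$lambda)) {
    args$nlambda <- config$nlambda
    args$lambda.min.ratio <- config$lambda_min_ratio
  } else {
    args$lambda <- config$lambda
  }
  master <- suppressWarnings(do.call(glmnet::glmnet, args))
  lambda <- master$lambda
  nl <- length(lambda)
  k <- max(foldid)
  devmat <- matrix(NA_real_, k, nl)
  wfold <- numeric(k)
  for (f in seq_len(k)) {
    inb <- foldid != f
    args_f <- args
    args_f$x <- x_train[inb, , drop = FALSE]
    args_f$y <- y[inb]
    args_f$lambda <- lambda
    args_f$nlambda <- NULL
    args_f$lambda.min.ratio <- NULL
    fit_f <- tryCatch(suppressWarnings(do.call(glmnet::glmnet, args_f)),
                      error = function(e) NULL)
    if (is.null(fit_f)) next
    b <- as.matrix(fit_f$beta)
    lp_all <- x_train %*% b
    nlf <- ncol(b)
    devmat[f, seq_len(nlf)] <-
      breslow_deviance_path(lp_all, times, events) -
      breslow_deviance_path(lp_all[inb, , drop = FALSE],
                            times[inb], events[inb])
    wfold[f] <- sum(events[foldid == f])
  }
  used <- which(wfold > 0 & rowSums(!is.na(devmat)) > 0)
  cand <- which(colSums(is.na(devmat[used, , drop = FALSE])) == 0)
  if (length(used) < 2L || length(cand) == 0L) {
    # CV not informative (e.g. almost no events): fall back to the
    # strongest penalty, i.e. the empty model -- conservative
    j <- 1L
    cvm <- cvsd <- rep(NA_real_, nl)
  } else {
    cvraw <- devmat[used, , drop = FALSE] / wfold[used]
    w <- wfold[used]
    cvm <- apply(cvraw, 2L, stats::weighted.mean, w = w)
    cvsd <- sqrt(apply((cvraw - rep(cvm, each = length(used)))^2, 2L,
                       stats::weighted.mean, w = w) / (length(used) - 1))
    jmin <- cand[which.min(cvm[cand])]
    j <- if (config$rule == "lambda.min") {
      jmin
    } else {
      min(cand[cvm[cand] <= cvm[jmin] + cvsd[jmin]])
    }
  }
  co <- master$beta[, j]
  list(weights = co[co != 0], lambda = lambda[j], fit = master,
       cvm = cvm, cvsd = cvsd, foldid = foldid)
}

#' Pathway-independent LASSO-Cox signature model
#'
#' Fits an L1-penalized Cox proportional-hazards model over all retained
#' proteins of the normalized training data; `lambda` is chosen by
#' internal k-fold cross-validation minimizing partial-likelihood deviance
#' on the training samples only. Proteins with zero coefficients are
#' excluded from the weight vector. An all-zero solution at the selected
#' `lambda` yields an empty model with a warning (scores become constant
#' and the median-cut stratification degenerates to all-low).
#'
#' @param cohort a `cohort`.
#' @param training_ids training-set sample IDs (>= 2 events required).
#' @param config a [lasso_config()].
#' @param seed integer seed for the internal CV fold stream.
#' @param missing_cap passed to [fit_normalization()].
#' @return a `signature_model` with method `"lasso"`.
#' @export
fit_lasso_model <- function(cohort, training_ids, config = lasso_config(),
                            seed = 1L, missing_cap = 0.2) {
  validate_cohort(cohort)
  stopifnot(inherits(config, "lasso_config"))
  idx <- match(training_ids, cohort$clinical$sample_id)
  if (anyNA(idx)) stop("training_ids not all in cohort", call. = FALSE)
  if (sum(cohort$clinical$os_event[idx]) < 2) {
    stop("training set needs >= 2 events for a LASSO-Cox fit", call. = FALSE)
  }
  norm <- fit_normalization(cohort$expression, training_ids, missing_cap)
  xn <- apply_normalization(cohort$expression[training_ids, , drop = FALSE], norm)
  res <- fit_lasso_weights(xn, cohort$clinical$os_months[idx],
                           cohort$clinical$os_event[idx], config, seed)
  if (length(res$weights) == 0L) {
    warning("LASSO selected the empty model at lambda = ",
            signif(res$lambda, 4), "; scores will be constant", call. = FALSE)
  }
  new_signature_model("lasso", res$weights, norm, lambda = res$lambda)
}

#' Compute per-sample signature scores
#'
#' The score of each sample is the inner product of the model weights with
#' its normalized expression values: `score = sum_i w_i * Y_i`.
#'
#' @param expr_normalized normalized expression matrix (output of
#'   [apply_normalization()] with the model's own parameters).
#' @param model a `signature_model`, or a bare named weight vector.
#' @return named numeric vector of scores, one per sample.
#' @export
compute_scores <- function(expr_normalized, model) {
  w <- if (inherits(model, "signature_model")) model$weights else model
  if (length(w) == 0L) {
    return(stats::setNames(rep(0, nrow(expr_normalized)),
                           rownames(expr_normalized)))
  }
  absent <- setdiff(names(w), colnames(expr_normalized))
  if (length(absent) > 0L) {
    stop("weighted protein(s) absent from matrix: ",
         paste(utils::head(absent, 3), collapse = ", "), call. = FALSE)
  }
  drop(expr_normalized[, names(w), drop = FALSE] %*% w)
}

#' Score a cohort with a fitted signature model
#'
#' Convenience wrapper: applies the model's own training-set normalization
#' to the cohort expression matrix and computes scores for all samples.
#'
#' @param cohort a `cohort`.
#' @param model a `signature_model`.
#' @return named numeric vector of scores.
#' @export
score_cohort <- function(cohort, model) {
  validate_cohort(cohort)
  xn <- apply_normalization(cohort$expression, model$norm)
  compute_scores(xn, model)
}

#' Median-cut risk stratification
#'
#' The stratification threshold is the median score of the training
#' samples; a sample is `"high"` risk iff its score exceeds the threshold
#' strictly (ties go to `"low"`). Constant scores yield an all-low
#' labeling with a warning.
#'
#' @param scores named numeric score vector (all samples).
#' @param training_ids sample IDs over which the median is taken.
#' @return object of class `risk_stratification`: list with `sample_ids`,
#'   `scores`, `threshold`, `group`.
#' @export
stratify_by_training_median <- function(scores, training_ids) {
  if (is.null(names(scores))) stop("scores must be named by sample ID",
                                   call. = FALSE)
  training_ids <- as.character(training_ids)
  if (length(training_ids) == 0L || !all(training_ids %in% names(scores))) {
    stop("training_ids must be a non-empty subset of the scored samples",
         call. = FALSE)
  }
  threshold <- stats::median(scores[training_ids])
  group <- ifelse(scores > threshold, "high", "low")
  if (length(unique(scores)) == 1L) {
    warning("constant scores: all samples labeled low risk", call. = FALSE)
  }
  structure(list(sample_ids = names(scores),
                 scores = scores,
                 threshold = threshold,
                 group = stats::setNames(group, names(scores))),
            class = "risk_stratification")
}

#' Serialize a signature model to JSON
#'
#' @param model a `signature_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
write_signature_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "signature_model"))
  obj <- list(
    method = model$method,
    weights = as.list(model$weights),
    lambda = if (is.na(model$lambda_selected)) NULL else model$lambda_selected,
    normalization = stats::setNames(
      lapply(seq_along(model$norm$protein_ids),
             function(i) c(model$norm$medians[[i]], model$norm$sds[[i]])),
      model$norm$protein_ids),
    training_sample_ids = model$training_sample_ids
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
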