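#' Configuration for the synthetic-cohort generator
#'
#' Defaults are sized like a TCGA-KIRC-scale RPPA cohort: 445 tumors, 233
#' proteins, 10 proteins carrying a proportional-hazards effect, and a
#' censored fraction around 65%.
#'
#' @param n_samples number of samples.
#' @param n_proteins number of proteins.
#' @param n_causal number of proteins with a non-zero log-hazard effect
#'   (`0 <= n_causal <= n_proteins`).
#' @param beta_magnitude absolute log-hazard ratio per unit expression for
#'   each causal protein (signs alternate +/-).
#' @param block_size proteins per correlated block.
#' @param block_correlation equicorrelation within a block, in `[0, 1)`.
#' @param baseline_scale Weibull scale of the baseline event-time
#'   distribution, months.
#' @param baseline_shape Weibull shape (> 1 means increasing hazard).
#' @param censor_rate target expected censored fraction, in `[0, 1)`.
#' @param admin_censor_months administrative end of follow-up, months.
#' @param prop_male,stage_probs marginal frequencies for the sex and stage
#'   covariates (independent of outcome).
#' @param seed integer RNG seed; the generator is fully reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 445L, n_proteins = 233L,
                              n_causal = 10L, beta_magnitude = 0.5,
                              block_size = 10L, block_correlation = 0.4,
                              baseline_scale = 60, baseline_shape = 1.2,
                              censor_rate = 0.65, admin_censor_months = 144,
                              prop_male = 0.65,
                              stage_probs = c(I = 0.45, II = 0.10,
                                              III = 0.20, IV = 0.20, X = 0.05),
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_proteins = as.integer(n_proteins),
              n_causal = as.integer(n_causal),
              beta_magnitude = beta_magnitude,
              block_size = as.integer(block_size),
              block_correlation = block_correlation,
              baseline_scale = baseline_scale,
              baseline_shape = baseline_shape,
              censor_rate = censor_rate,
              admin_censor_months = admin_censor_months,
              prop_male = prop_male,
              stage_probs = stage_probs,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples > 0, cfg$n_proteins > 0,
            cfg$block_size > 0,
            cfg$block_correlation >= 0, cfg$block_correlation < 1,
            cfg$beta_magnitude > 0, cfg$baseline_scale > 0,
            cfg$baseline_shape > 0,
            cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$admin_censor_months > 0)
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_proteins) {
    stop("n_causal must lie in [0, n_proteins]", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# expected censored fraction if C = min(Exp(rate), admin), given event times t
expected_censored_fraction <- function(rate, t, admin) {
  mean(ifelse(t > admin, 1, 1 - exp(-rate * pmin(t, admin))))
}

# solve for the exponential censoring rate hitting the target fraction
tune_censor_rate <- function(t, admin, target) {
  floor_frac <- mean(t > admin)  # administrative censoring alone
  if (target <= floor_frac) return(1e-12)
  lo <- 1e-12; hi <- 1
  while (expected_censored_fraction(hi, t, admin) < target && hi < 1e6) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_censored_fraction(mid, t, admin) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a protein-expression survival cohort with a planted signal
#'
#' Expression is drawn from a block-equicorrelated multivariate normal
#' (unit marginal variance). A random subset of `n_causal` proteins carries
#' a proportional-hazards effect with alternating-sign coefficients of
#' magnitude `beta_magnitude`. Event times follow a Weibull
#' proportional-hazards model: `T = scale * (-log U * exp(-x'beta))^(1/shape)`.
#' Censoring is an exponential time (rate tuned numerically so the expected
#' censored fraction matches `censor_rate`) truncated at
#' `admin_censor_months`. Sex and stage are drawn at their marginal
#' frequencies, independent of outcome.
#'
#' Two separately seeded RNG streams are used: covariates (expression, sex,
#' stage, age) and survival draws. Editing non-causal covariates therefore
#' cannot perturb the outcome draws.
#'
#' @param config a [simulation_config()].
#' @return list with elements `cohort` (a `cohort`) and `truth` (list with
#'   `causal_protein_ids` and `true_betas`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples; p <- config$n_proteins
  protein_ids <- sprintf("P%03d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))

  cov_draw <- withr::with_seed(derive_seed(config$seed, 1L), {
    rho <- config$block_correlation
    block <- rep(seq_len(ceiling(p / config$block_size)),
                 each = config$block_size)[seq_len(p)]
    f <- matrix(stats::rnorm(n * max(block)), n, max(block))
    e <- matrix(stats::rnorm(n * p), n, p)
    x <- sqrt(rho) * f[, block, drop = FALSE] + sqrt(1 - rho) * e
    dimnames(x) <- list(sample_ids, protein_ids)
    causal <- if (config$n_causal > 0) sort(sample(p, config$n_causal)) else integer(0)
    sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
    stage <- sample(names(config$stage_probs), n, replace = TRUE,
                    prob = config$stage_probs)
    age <- pmin(pmax(stats::rnorm(n, 61, 12), 18), 90)
    list(x = x, causal = causal, sex = sex, stage = stage, age = age)
  })

  beta <- rep(config$beta_magnitude * c(1, -1),
              length.out = config$n_causal)
  lp <- if (config$n_causal > 0) {
    drop(cov_draw$x[, cov_draw$causal, drop = FALSE] %*% beta)
  } else {
    rep(0, n)
  }

  surv <- withr::with_seed(derive_seed(config$seed, 2L), {
    u_t <- stats::runif(n)
    u_c <- stats::runif(n)
    t_event <- config$baseline_scale *
      (-log(u_t) * exp(-lp))^(1 / config$baseline_shape)
    rate <- tune_censor_rate(t_event, config$admin_censor_months,
                             config$censor_rate)
    t_cens <- pmin(-log(u_c) / rate, config$admin_censor_months)
    list(os_months = unname(pmin(t_event, t_cens)),
         os_event = unname(as.numeric(t_event <= t_cens)))
  })

  clin <- data.frame(sample_id = sample_ids,
                     os_months = surv$os_months,
                     os_event = surv$os_event,
                     sex = cov_draw$sex,
                     stage = cov_draw$stage,
                     age_years = cov_draw$age,
                     stringsAsFactors = FALSE)
  cohort <- suppressMessages(build_cohort(cov_draw$x, clin))
  truth <- list(causal_protein_ids = protein_ids[cov_draw$causal],
                true_betas = stats::setNames(beta, protein_ids[cov_draw$causal]))
  list(cohort = cohort, truth = truth)
}

#' Rename simulated protein columns to pathway member names
#'
#' Maps a subset of protein columns onto the member names of a pathway so
#' that pathway-score code paths can be exercised on simulated data.
#' Values are untouched; only column names change. By default the first
#' `k` columns are renamed; pass `protein_ids` to choose which columns
#' (e.g. planted causal proteins, so the pathway score carries signal).
#'
#' @param cohort a `cohort`.
#' @param pathway a [pathway_definition()].
#' @param protein_ids optional character vector of existing column names to
#'   rename, same length as the pathway membership.
#' @return the cohort with renamed columns.
#' @export
plant_pathway_proteins <- function(cohort, pathway, protein_ids = NULL) {
  validate_cohort(cohort)
  members <- names(pathway$weights)
  p <- ncol(cohort$expression)
  if (length(members) > p) {
    stop("pathway has more members than the cohort has proteins", call. = FALSE)
  }
  cols <- colnames(cohort$expression)
  if (is.null(protein_ids)) protein_ids <- cols[seq_along(members)]
  idx <- match(protein_ids, cols)
  if (anyNA(idx) || length(idx) != length(members)) {
    stop("protein_ids must name one existing column per pathway member",
         call. = FALSE)
  }
  cols[idx] <- members
  colnames(cohort$expression) <- cols
  validate_cohort(cohort)
  cohort
}
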