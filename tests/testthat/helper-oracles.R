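# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package implementation.

# product-limit estimator by direct looping over distinct event times;
# convention: events precede censorings at tied times
km_brute <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = ut, survival = surv)
}

# two-group log-rank chi-square via the O-E / hypergeometric-variance sums
logrank_brute <- function(times, events, groups) {
  g <- as.character(groups)
  lev <- sort(unique(g))
  stopifnot(length(lev) == 2)
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n1 <- sum(times >= t & g == lev[1])
    n2 <- sum(times >= t & g == lev[2])
    n <- n1 + n2
    d1 <- sum(times == t & events == 1 & g == lev[1])
    d <- sum(times == t & events == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# signature score by naive double loop
score_brute <- function(x, w) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- 0
    for (p in names(w)) s <- s + w[[p]] * x[i, p]
    out[i] <- s
  }
  out
}

# small deterministic cohort with a single strong prognostic protein
tiny_cohort <- function(n = 60, p = 8, beta = 1.2, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("P%02d", 1:p)))
    lp <- beta * x[, 1]
    t_event <- rexp(n, rate = 0.02 * exp(lp))
    t_cens <- runif(n, 20, 150)
    clin <- data.frame(sample_id = rownames(x),
                       os_months = pmin(t_event, t_cens),
                       os_event = as.numeric(t_event <= t_cens),
                       sex = sample(c("female", "male"), n, replace = TRUE),
                       stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
                       age_years = runif(n, 40, 80))
    build_cohort(x, clin)
  })
}

write_tmp <- function(lines, ext) {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
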