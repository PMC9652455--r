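#' Derive a child RNG seed from a base seed and stream labels
#'
#' Mixes a base seed with one or more integer labels (permutation index,
#' fold number, stream id) into a new seed in `[1, 2^31 - 2]`, so that
#' logically distinct random streams (fold splitting, internal lambda
#' cross-validation, survival draws, permutations) never share a state.
#'
#' @param seed integer base seed.
#' @param ... integer stream labels.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.double(abs(as.integer(seed))) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + as.double(k) + 12345) %% 2147483647
  }
  as.integer(x) + 1L
}

#' Split n samples into k random folds
#'
#' Balanced random partition: fold sizes differ by at most one. With
#' `stratify` (typically the event indicator) the partition is drawn
#' within each stratum so event counts stay balanced across folds.
#' Draws from the current RNG state; callers wrap it in
#' [withr::with_seed()] for reproducibility.
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param stratify optional vector of length `n`; folds are balanced
#'   within its levels.
#' @return integer vector of fold assignments in `1:k`.
#' @export
make_folds <- function(n, k, stratify = NULL) {
  stopifnot(k >= 2, n >= k)
  fold <- integer(n)
  if (is.null(stratify)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(stratify) == n)
    for (lev in unique(stratify)) {
      idx <- which(stratify == lev)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

# shared internals: per-column median / sd. Hot path inside the
# permutation loop, so the NA-free case avoids apply()/median() overhead.
fast_median <- function(v) {
  n <- length(v)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort(v, partial = half)[half]
  } else {
    s <- sort(v, partial = c(half, half + 1L))
    (s[half] + s[half + 1L]) / 2
  }
}

col_medians <- function(x) {
  if (anyNA(x)) return(apply(x, 2L, stats::median, na.rm = TRUE))
  apply(x, 2L, fast_median)
}

col_sds <- function(x) {
  if (anyNA(x)) return(apply(x, 2L, stats::sd, na.rm = TRUE))
  n <- nrow(x)
  m <- colMeans(x)
  v <- (colSums(x * x) - n * m * m) / (n - 1)
  sqrt(pmax(v, 0))
}

msg <- function(..., verbose = getOption("sigsurv.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
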