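#' Fit training-set normalization parameters
#'
#' Computes the per-protein median and sample standard deviation
#' (denominator n - 1) over the training samples only. Proteins with a
#' training s.d. below `sd_tol` (effectively constant) or with a training
#' missing fraction above `missing_cap` are excluded and listed in
#' `dropped_proteins`.
#'
#' @param expr expression matrix.
#' @param training_ids sample IDs of the training set (>= 2).
#' @param missing_cap maximum tolerated training missing fraction.
#' @param sd_tol minimum training s.d. for a protein to be retained.
#' @return object of class `normalization_params`: list with
#'   `protein_ids`, `medians`, `sds` (aligned to `protein_ids`),
#'   `dropped_proteins` and `training_ids`.
#' @export
fit_normalization <- function(expr, training_ids, missing_cap = 0.2,
                              sd_tol = 1e-12) {
  validate_expression_matrix(expr)
  training_ids <- as.character(training_ids)
  if (!all(training_ids %in% rownames(expr))) {
    stop("training_ids must be a subset of the expression sample IDs",
         call. = FALSE)
  }
  if (length(training_ids) < 2L) stop("need >= 2 training samples", call. = FALSE)
  sub <- expr[training_ids, , drop = FALSE]
  med <- col_medians(sub)
  sds <- col_sds(sub)
  miss <- colMeans(is.na(sub))
  keep <- !is.na(sds) & sds >= sd_tol & miss <= missing_cap
  if (!any(keep)) stop("all proteins dropped during normalization", call. = FALSE)
  structure(
    list(protein_ids = colnames(expr)[keep],
         medians = med[keep],
         sds = sds[keep],
         dropped_proteins = colnames(expr)[!keep],
         training_ids = training_ids),
    class = "normalization_params"
  )
}

#' Apply training-set normalization to an expression matrix
#'
#' Restricts the matrix to the retained proteins and maps each value to
#' `(raw - training median) / training s.d.`. Remaining missing values are
#' imputed to 0 -- i.e. to the training median -- which is neutral under
#' the linear signature score.
#'
#' @param expr expression matrix (any samples, e.g. the whole cohort).
#' @param norm a [fit_normalization()] result.
#' @return normalized expression matrix over the retained proteins.
#' @export
apply_normalization <- function(expr, norm) {
  stopifnot(inherits(norm, "normalization_params"))
  missing <- setdiff(norm$protein_ids, colnames(expr))
  if (length(missing) > 0L) {
    stop("expression matrix lacks normalized protein(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  x <- expr[, norm$protein_ids, drop = FALSE]
  x <- sweep(x, 2L, norm$medians, "-")
  x <- sweep(x, 2L, norm$sds, "/")
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0L) {
    x[is.na(x)] <- 0
    msg("apply_normalization: imputed ", n_imputed,
        " missing value(s) to the training median")
  }
  x
}
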