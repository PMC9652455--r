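#' Validate a samples-by-proteins expression matrix
#'
#' An expression matrix is an ordinary numeric matrix whose rownames are
#' unique sample identifiers and whose colnames are unique protein
#' identifiers (normalized log-intensity units, arbitrary scale). Missing
#' measurements are stored as `NA`.
#'
#' @param x numeric matrix, samples in rows, proteins in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  sid <- rownames(x)
  pid <- colnames(x)
  if (is.null(sid) || is.null(pid)) {
    stop("expression matrix must carry sample rownames and protein colnames",
         call. = FALSE)
  }
  if (anyDuplicated(sid)) stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(pid)) stop("duplicate protein IDs", call. = FALSE)
  if (any(!nzchar(sid)) || any(!nzchar(pid))) {
    stop("empty sample or protein ID", call. = FALSE)
  }
  invisible(x)
}

#' Validate a clinical table
#'
#' A clinical table is a data.frame with one row per sample and columns
#' `sample_id`, `os_months` (overall survival, months), `os_event`
#' (1 = deceased, 0 = censored), `sex` (`"female"`, `"male"`, `"unknown"`),
#' `stage` (`"I"`, `"II"`, `"III"`, `"IV"`, `"X"` for unknown) and
#' `age_years` (`NA` when unknown).
#'
#' @param x data.frame to validate.
#' @return `x`, invisibly, after validation.
#' @export
validate_clinical_table <- function(x) {
  req <- c("sample_id", "os_months", "os_event")
  if (!all(req %in% names(x))) {
    stop("clinical table requires columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) stop("duplicate sample IDs in clinical table",
                                       call. = FALSE)
  ok_months <- is.na(x$os_months) | x$os_months >= 0
  if (!all(ok_months)) stop("os_months must be non-negative", call. = FALSE)
  ok_event <- is.na(x$os_event) | x$os_event %in% c(0, 1)
  if (!all(ok_event)) stop("os_event must be 0 or 1", call. = FALSE)
  invisible(x)
}

#' Join expression and clinical data into a cohort
#'
#' Matches clinical records to expression rows by exact sample ID
#' (whitespace-trimmed; optionally truncated to the first `truncate_ids`
#' characters to cope with portal-specific barcode lengths) and returns a
#' `cohort`: the expression matrix together with the clinical table
#' restricted and reordered to its rows. Samples with missing survival
#' time or event status are never admitted.
#'
#' @param expr expression matrix (see [validate_expression_matrix()]).
#' @param clin clinical table (see [validate_clinical_table()]).
#' @param on_unmatched `"drop"` keeps the intersection and reports the
#'   number of samples dropped; `"error"` requires identical ID sets.
#' @param truncate_ids optional integer; truncate both ID sets to this many
#'   leading characters before matching.
#' @return an object of class `cohort`: list with elements `expression`
#'   (matrix) and `clinical` (data.frame, same sample order).
#' @export
build_cohort <- function(expr, clin, on_unmatched = c("drop", "error"),
                         truncate_ids = NULL) {
  on_unmatched <- match.arg(on_unmatched)
  validate_expression_matrix(expr)
  validate_clinical_table(clin)
  eid <- trimws(rownames(expr))
  cid <- trimws(as.character(clin$sample_id))
  if (!is.null(truncate_ids)) {
    eid <- substr(eid, 1L, truncate_ids)
    cid <- substr(cid, 1L, truncate_ids)
    if (anyDuplicated(eid) || anyDuplicated(cid)) {
      stop("ID truncation produced duplicate sample IDs", call. = FALSE)
    }
  }
  rownames(expr) <- eid
  clin$sample_id <- cid
  usable <- cid[!is.na(clin$os_months) & !is.na(clin$os_event)]
  shared <- intersect(eid, usable)
  if (length(shared) == 0L) {
    stop("no samples shared between expression and clinical data", call. = FALSE)
  }
  n_drop <- (length(eid) - length(shared)) + (length(cid) - length(shared))
  if (on_unmatched == "error" && n_drop > 0L) {
    stop("expression and clinical sample sets differ (", n_drop,
         " unmatched/unusable); use on_unmatched = \"drop\"", call. = FALSE)
  }
  if (n_drop > 0L) {
    msg("build_cohort: dropped ", n_drop,
        " sample(s) without a usable match in both inputs")
  }
  keep <- eid[eid %in% shared]  # order follows the expression matrix
  clin <- clin[match(keep, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  out <- structure(
    list(expression = expr[keep, , drop = FALSE], clinical = clin),
    class = "cohort"
  )
  validate_cohort(out)
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$expression), "samples x", ncol(x$expression),
      "proteins;", sum(x$clinical$os_event == 1), "events\n")
  invisible(x)
}

#' Validate a cohort object
#'
#' @param x object of class `cohort`.
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  validate_expression_matrix(x$expression)
  validate_clinical_table(x$clinical)
  if (!identical(rownames(x$expression), as.character(x$clinical$sample_id))) {
    stop("cohort: clinical rows must match expression rows one-to-one, in order",
         call. = FALSE)
  }
  if (anyNA(x$clinical$os_months) || anyNA(x$clinical$os_event)) {
    stop("cohort: every sample needs non-missing os_months and os_event",
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a pathway definition
#'
#' A pathway is a named set of member proteins with literature-assigned
#' signed weights: +1 for positive regulators, -1 for negative regulators.
#'
#' @param name pathway name.
#' @param proteins character vector of unique member protein IDs.
#' @param weights numeric vector of +1/-1, one per member.
#' @return object of class `pathway_definition` with elements `name` and
#'   `weights` (named numeric vector over proteins).
#' @export
pathway_definition <- function(name, proteins, weights) {
  proteins <- as.character(proteins)
  weights <- as.numeric(weights)
  if (length(proteins) != length(weights)) {
    stop("one weight per member protein required", call. = FALSE)
  }
  if (anyDuplicated(proteins)) {
    stop("duplicate protein in pathway '", name, "'", call. = FALSE)
  }
  if (!all(weights %in% c(1, -1))) {
    stop("pathway weights must be exactly +1 or -1", call. = FALSE)
  }
  names(weights) <- proteins
  structure(list(name = name, weights = weights), class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("pathway '", x$name, "': ", length(x$weights), " proteins (",
      sum(x$weights > 0), " up, ", sum(x$weights < 0), " down)\n", sep = "")
  invisible(x)
}
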