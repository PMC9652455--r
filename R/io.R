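# Readers/writers for the three plain-text interchange formats:
#   expression  - CSV, header "SampleID,<protein>,...", one row per sample
#                 (TCPA level-4 layout)
#   clinical    - TSV with sample_id / os_months / os_event / sex / stage /
#                 age_years
#   pathways    - TSV with pathway / protein / weight (+1 or -1)

NA_TOKENS <- c("", "na", "nan", "null")

parse_numeric_cells <- function(v, what) {
  v <- trimws(v)
  is_na <- tolower(v) %in% NA_TOKENS | is.na(v)
  num <- suppressWarnings(as.numeric(v))
  bad <- !is_na & is.na(num)
  if (any(bad)) {
    stop("non-numeric ", what, " value(s): ",
         paste(utils::head(unique(v[bad]), 3), collapse = ", "), call. = FALSE)
  }
  num[is_na] <- NA_real_
  num
}

#' Read a samples-by-proteins expression CSV
#'
#' Expects the TCPA level-4 layout: first column sample IDs, remaining
#' header fields protein IDs, one row per sample. Cells equal to `""`,
#' `"NA"`, `"NaN"` or `"null"` (case-insensitive) become missing values;
#' any other non-numeric cell is a format error, as are duplicated sample
#' or protein IDs.
#'
#' @param path path to the CSV file.
#' @return numeric matrix with sample rownames and protein colnames.
#' @export
read_expression_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression CSV needs an ID column plus >= 1 protein",
                           call. = FALSE)
  ids <- trimws(raw[[1L]])
  proteins <- trimws(colnames(raw)[-1L])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in expression CSV",
                               call. = FALSE)
  if (anyDuplicated(proteins)) stop("duplicate protein IDs in expression CSV header",
                                    call. = FALSE)
  vals <- vapply(raw[-1L], parse_numeric_cells, numeric(nrow(raw)),
                 what = "expression")
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, proteins))
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as CSV
#'
#' Inverse of [read_expression_csv()]; round-trips values to full double
#' precision.
#'
#' @param expr expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(expr, path) {
  validate_expression_matrix(expr)
  df <- data.frame(SampleID = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

recode_event <- function(v) {
  key <- tolower(trimws(as.character(v)))
  out <- rep(NA_real_, length(v))
  out[key %in% c("deceased", "dead", "1")] <- 1
  out[key %in% c("living", "alive", "0")] <- 0
  bad <- !(key %in% c("deceased", "dead", "1", "living", "alive", "0")) &
    !(key %in% NA_TOKENS)
  if (any(bad)) {
    stop("unrecognized os_event value(s): ",
         paste(utils::head(unique(v[bad]), 3), collapse = ", "), call. = FALSE)
  }
  out
}

recode_sex <- function(v) {
  key <- tolower(trimws(as.character(v)))
  out <- rep("unknown", length(v))
  out[key %in% c("female", "f")] <- "female"
  out[key %in% c("male", "m")] <- "male"
  out
}

recode_stage <- function(v) {
  key <- toupper(trimws(as.character(v)))
  key <- sub("^STAGE\\s*", "", key)
  # collapse substages (IIIA -> III); anything unrecognized is "X" (unknown)
  key <- sub("^(IV|III|II|I).*$", "\\1", key)
  out <- ifelse(key %in% c("I", "II", "III", "IV"), key, "X")
  out
}

#' Read a clinical table TSV
#'
#' Requires columns `sample_id`, `os_months`, `os_event`; optional `sex`,
#' `stage`, `age_years`. Event status may be coded 0/1 or with
#' Living/Deceased (Alive/Dead) labels, case-insensitive. Stage labels are
#' normalized to I--IV with `"X"` for unknown (substages collapse to their
#' main stage). Negative survival times and event codes outside {0, 1} are
#' validation errors.
#'
#' @param path path to the TSV file.
#' @return a validated clinical data.frame.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  req <- c("sample_id", "os_months", "os_event")
  if (!all(req %in% names(raw))) {
    stop("clinical TSV requires columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    sample_id = trimws(raw$sample_id),
    os_months = parse_numeric_cells(raw$os_months, "os_months"),
    os_event  = recode_event(raw$os_event),
    sex       = if ("sex" %in% names(raw)) recode_sex(raw$sex) else "unknown",
    stage     = if ("stage" %in% names(raw)) recode_stage(raw$stage) else "X",
    age_years = if ("age_years" %in% names(raw))
      parse_numeric_cells(raw$age_years, "age_years") else NA_real_,
    stringsAsFactors = FALSE
  )
  validate_clinical_table(out)
  out
}

#' Write a clinical table as TSV
#'
#' @param clin clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clin, path) {
  validate_clinical_table(clin)
  utils::write.table(clin, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pathway definitions from a TSV file
#'
#' Format: header `pathway  protein  weight`, one member per row, weight
#' literal `+1` or `-1`. A protein may belong to several pathways.
#'
#' @param path path to the TSV file.
#' @return named list of [pathway_definition()] objects.
#' @export
read_pathway_definitions <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  req <- c("pathway", "protein", "weight")
  if (!all(req %in% names(raw))) {
    stop("pathway TSV requires columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  w <- suppressWarnings(as.numeric(trimws(raw$weight)))
  if (anyNA(w) || !all(w %in% c(1, -1))) {
    stop("pathway weights must be +1 or -1", call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(raw)), raw$pathway), function(idx) {
    pathway_definition(raw$pathway[idx[1L]],
                       trimws(raw$protein[idx]), w[idx])
  })
  out[unique(raw$pathway)]
}

#' The packaged 7-protein RTK pathway definition
#'
#' The receptor tyrosine kinase (RTK) activity signature: an unweighted
#' (+1) sum over EGFR-pY1068, EGFR-pY1173, HER2-pY1248, HER3-pY1289,
#' SHC-pY317, SRC-pY416 and SRC-pY527.
#'
#' @return a [pathway_definition()] object.
#' @export
rtk_pathway <- function() {
  path <- system.file("extdata", "rtk.tsv", package = "sigsurv",
                      mustWork = TRUE)
  read_pathway_definitions(path)[["RTK"]]
}
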