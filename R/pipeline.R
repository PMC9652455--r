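# End-to-end orchestration: run every requested scoring method through the
# cross-validation evaluation and the permutation test, assemble a
# methods-by-cohort table of permutation p-values, and (optionally) write
# all outputs with a machine-readable run manifest.

#' Run the full method comparison on one cohort
#'
#' For each entry of `methods`, runs [run_cv()] and [run_permutation_test()]
#' and collects a comparison table of permutation p-values alongside the
#' CV medians. When `out_dir` is given, fold-level TSVs, summary JSON,
#' pooled-label TSVs, permuted-statistic TSVs, KM tables and a run
#' manifest are written there.
#'
#' @param cohort a `cohort`.
#' @param methods named list; each element is a list with `method` and
#'   optionally `pathway` (a [pathway_definition()]).
#' @param base_seed integer master seed for all sub-runs.
#' @param n_cv_iterations,n_cv_folds cross-validation shape (default 10 x 3).
#' @param n_perm_folds,n_permutations permutation-test shape (default 10
#'   folds; set `n_permutations` to 1000 for full runs, 99 for desk scale).
#' @param lasso a [lasso_config()].
#' @param horizon_months evaluation horizon.
#' @param out_dir optional output directory.
#' @return object of class `comparison_report`: list with `cv` (named
#'   `cv_summary` list), `perm` (named `permutation_result` list) and
#'   `p_table` (data.frame method / permutation_p / median_hr /
#'   median_surv_diff_5yr / observed_logrank).
#' @export
run_full_comparison <- function(cohort, methods, base_seed = 1L,
                                n_cv_iterations = 10L, n_cv_folds = 3L,
                                n_perm_folds = 10L, n_permutations = 99L,
                                lasso = lasso_config(), horizon_months = 60,
                                out_dir = NULL) {
  validate_cohort(cohort)
  stopifnot(is.list(methods), length(methods) >= 1)
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    stop("methods list must be named", call. = FALSE)
  }
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  cv_out <- list()
  perm_out <- list()
  rows <- list()
  for (nm in names(methods)) {
    spec <- methods[[nm]]
    msg("method '", nm, "': cross-validation")
    cv_out[[nm]] <- run_cv(cohort, cv_config(
      method = spec$method, n_iterations = n_cv_iterations,
      n_folds = n_cv_folds, base_seed = derive_seed(base_seed, match(nm, names(methods)), 1L),
      pathway = spec$pathway, horizon_months = horizon_months, lasso = lasso))
    msg("method '", nm, "': permutation test (M = ", n_permutations, ")")
    perm_out[[nm]] <- run_permutation_test(cohort, permutation_config(
      method = spec$method, n_folds = n_perm_folds,
      n_permutations = n_permutations,
      base_seed = derive_seed(base_seed, match(nm, names(methods)), 2L),
      pathway = spec$pathway, lasso = lasso))
    rows[[nm]] <- data.frame(
      method = nm,
      permutation_p = perm_out[[nm]]$p_value,
      observed_logrank = perm_out[[nm]]$observed_statistic,
      median_hr = cv_out[[nm]]$median_hr,
      median_surv_diff_5yr = cv_out[[nm]]$median_surv_diff,
      stringsAsFactors = FALSE)
  }
  report <- structure(list(cv = cv_out, perm = perm_out,
                           p_table = do.call(rbind, c(rows, make.row.names = FALSE))),
                      class = "comparison_report")
  if (!is.null(out_dir)) {
    write_comparison_report(report, cohort, out_dir,
                            command = "compare", base_seed = base_seed,
                            started = started)
  }
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report over", length(x$cv), "method(s):\n")
  print(x$p_table, row.names = FALSE)
  invisible(x)
}

write_comparison_report <- function(report, cohort, out_dir, command,
                                    base_seed, started) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files[[length(files) + 1L]] <<- p
    files
  }
  tsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                            row.names = FALSE, quote = FALSE)
  wr(report$p_table, "comparison_p_values.tsv", tsv)
  for (nm in names(report$cv)) {
    wr(report$cv[[nm]]$fold_results, paste0("cv_folds_", nm, ".tsv"), tsv)
    sc <- report$cv[[nm]]$selection_counts
    if (length(sc) > 0) {
      wr(data.frame(protein = names(sc), count = as.integer(sc)),
         paste0("selection_counts_", nm, ".tsv"), tsv)
    }
    pr <- report$perm[[nm]]
    wr(data.frame(permutation = seq_along(pr$permuted_statistics),
                  statistic = pr$permuted_statistics),
       paste0("permuted_statistics_", nm, ".tsv"), tsv)
    wr(data.frame(sample_id = names(pr$pooled_labels),
                  group = unname(pr$pooled_labels)),
       paste0("pooled_labels_", nm, ".tsv"), tsv)
    km <- km_table(cohort$clinical$os_months, cohort$clinical$os_event,
                   pr$pooled_labels)
    wr(km, paste0("pooled_km_", nm, ".tsv"), tsv)
  }
  write_run_manifest(out_dir, command = command, base_seed = base_seed,
                     started = started, outputs = files)
  invisible(out_dir)
}

#' Write a machine-readable run manifest
#'
#' Records the command, package version, seeds, start/finish timestamps
#' and an MD5 digest of every output file, so a run can be reproduced and
#' its outputs verified.
#'
#' @param out_dir directory the manifest describes.
#' @param command name of the command that produced the outputs.
#' @param base_seed master seed of the run.
#' @param started ISO start timestamp.
#' @param outputs character vector of produced file paths.
#' @param extra optional named list merged into the manifest.
#' @return path of the written manifest, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, base_seed, started,
                               outputs, extra = list()) {
  manifest <- c(list(
    command = command,
    software_version = as.character(utils::packageVersion("sigsurv")),
    base_seed = base_seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_digests = as.list(tools::md5sum(outputs))
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
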