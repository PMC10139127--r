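#' Write a result bundle to disk
#'
#' Serializes a fitted `nested_cv` or `stavarsel_fit` as machine-readable
#' text: per-sample prediction records as TSV, selection-frequency table
#' and step-forward curve as TSV (StaVarSel fits), and a JSON summary with
#' config provenance (seed and a config hash).  Field order is fixed and
#' numbers are written at full precision, so reruns with the same seed and
#' configuration produce byte-identical files.  Wall-clock information
#' goes to a separate `run_log.txt` that is excluded from determinism
#' comparisons.
#'
#' @param fit A `nested_cv` or `stavarsel_fit`, optionally augmented by
#'   [conservative_intervals()].
#' @param out_dir Output directory, created if needed.
#' @return Tibble manifest of the files written, invisibly.
#' @export
write_result_bundle <- function(fit, out_dir) {
  stopifnot(inherits(fit, c("nested_cv", "stavarsel_fit")))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("Cannot create output directory: ", out_dir),
          class = "stavarsel_io")
  }
  files <- character(0)
  wr <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tbl, path)
    files <<- c(files, name)
  }
  wr(fit$records, "records.tsv")
  if (inherits(fit, "stavarsel_fit")) {
    freq <- fit$frequencies %||%
      tibble(ratio_id = character(0), count = integer(0),
             fraction = numeric(0), mean_abs_coefficient = numeric(0),
             rank = integer(0))
    wr(freq, "selection_frequencies.tsv")
    curve <- if (!is.null(fit$curve)) fit$curve$curve else
      tibble(k = integer(0), error = numeric(0))
    wr(curve, "step_forward_curve.tsv")
    wr(fit$standard_records, "standard_cv_records.tsv")
  }
  summary <- list(
    model = class(fit)[1],
    summary = as.list(fit$summary),
    lambda = fit$lambda,
    seed = fit$config$seed,
    config_hash = rlang::hash(fit$config)
  )
  if (inherits(fit, "stavarsel_fit")) {
    summary$chosen_k <- fit$chosen_k
    summary$final_features <- as.list(fit$final_features)
    summary$standard_summary <- as.list(fit$standard_summary)
  }
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, "summary.json")
  writeLines(c(paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste0("seed: ", fit$config$seed)),
             file.path(out_dir, "run_log.txt"))
  files <- c(files, "run_log.txt")
  invisible(tibble(file = files,
                   path = file.path(out_dir, files)))
}
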