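#' Remove low-expression features
#'
#' Features with an average strictly below `min_avg_cpm` counts per million
#' are removed, as are features with a zero value in any sample (so every
#' retained feature can serve as a ratio denominator).  The operation is
#' idempotent.
#'
#' @param expression Wide expression tibble (`sample_id` first column).
#' @param params [qc_params()].
#' @return A list with `expression` (filtered tibble) and `report` (tibble
#'   of removed `feature_id` and `reason`).
#' @export
filter_low_expression <- function(expression, params = qc_params()) {
  m <- values_matrix(expression)
  if (ncol(m) == 0) abort("Empty expression matrix.", class = "stavarsel_qc")
  means <- colMeans(m)
  low <- means < params$min_avg_cpm
  zero <- if (params$require_nonzero_in_all_samples) {
    apply(m, 2, function(v) any(v == 0))
  } else {
    rep(FALSE, ncol(m))
  }
  drop <- low | zero
  if (all(drop)) {
    abort("All features removed by the low-expression filter.",
          class = "stavarsel_qc")
  }
  reason <- dplyr::case_when(
    low & zero ~ "low_mean_cpm;zero_count",
    low ~ "low_mean_cpm",
    zero ~ "zero_count"
  )
  report <- tibble(feature_id = colnames(m)[drop],
                   reason = reason[drop])
  list(expression = matrix_tibble(m[, !drop, drop = FALSE]),
       report = report)
}

# Per-sample score over a set of feature columns, after rescaling each
# column to mean 1.  Scale-invariant by construction.
centered_sample_scores <- function(m) {
  mu <- colMeans(m)
  if (any(mu == 0)) {
    abort(paste0("Feature(s) with zero mean: ",
                 paste(colnames(m)[mu == 0], collapse = ", "),
                 ". Run filter_low_expression() first."),
          class = "stavarsel_qc")
  }
  rowMeans(sweep(m, 2, mu, `/`))
}

#' Detect global outlier samples
#'
#' Each feature is rescaled to mean 1 across samples; a sample's score is
#' its mean rescaled value across features.  Samples whose score falls
#' outside the band mean +/- `outlier_sd_multiplier` standard deviations
#' (over per-sample scores) are flagged.  The rule is two-sided and the
#' flag direction (high/low) is recorded.
#'
#' @inheritParams filter_low_expression
#' @return A tibble with `sample_id`, `score`, `flagged`, `direction`.
#' @export
detect_outlier_samples <- function(expression, params = qc_params()) {
  m <- values_matrix(expression)
  if (nrow(m) < 3) {
    abort("Outlier detection needs at least 3 samples.",
          class = "stavarsel_qc")
  }
  score <- centered_sample_scores(m)
  mu <- mean(score)
  s <- sd(score)
  hi <- score > mu + params$outlier_sd_multiplier * s
  lo <- score < mu - params$outlier_sd_multiplier * s
  tibble(sample_id = rownames(m),
         score = unname(score),
         flagged = hi | lo,
         direction = dplyr::case_when(hi ~ "high", lo ~ "low",
                                      .default = "within"))
}

#' Detect haemolysed samples from red-blood-cell marker miRNAs
#'
#' The configured marker miRNAs (by default miR-451a, miR-16-5p and
#' miR-486-5p, which are enriched in red blood cells) are each rescaled to
#' mean 1 across samples; a sample's haemolysis score is the mean of its
#' rescaled marker values.  A sample is flagged when its score exceeds the
#' cohort mean by `haemolysis_sd_multiplier` standard deviations.  The rule
#' is one-sided: haemolysis only elevates marker levels.
#'
#' @inheritParams filter_low_expression
#' @return A tibble with `sample_id`, `score`, `flagged`.
#' @export
detect_haemolysis <- function(expression, params = qc_params()) {
  m <- values_matrix(expression)
  present <- intersect(params$haemolysis_marker_ids, colnames(m))
  if (length(present) == 0) {
    abort(paste0("No haemolysis marker found. Configured: ",
                 paste(params$haemolysis_marker_ids, collapse = ", "),
                 "; available: ",
                 paste(head(colnames(m), 10), collapse = ", "), ", ..."),
          class = "stavarsel_qc")
  }
  if (length(present) < length(params$haemolysis_marker_ids)) {
    warn(paste0("Haemolysis markers missing from the matrix: ",
                paste(setdiff(params$haemolysis_marker_ids, present),
                      collapse = ", "),
                ". Score computed over the ", length(present),
                " present marker(s)."))
  }
  score <- centered_sample_scores(m[, present, drop = FALSE])
  mu <- mean(score)
  s <- sd(score)
  tibble(sample_id = rownames(m),
         score = unname(score),
         flagged = score > mu + params$haemolysis_sd_multiplier * s)
}

#' Run the full sample/feature QC stage
#'
#' Applies the low-expression filter, then flags outlier and haemolysed
#' samples; flagged samples are excluded from the returned expression and
#' metadata unless `keep_flagged = TRUE`.
#'
#' @inheritParams filter_low_expression
#' @param metadata Tibble with `sample_id` and `group`.
#' @param keep_flagged Keep flagged samples (with a warning).
#' @return A list with `expression`, `metadata`, `feature_report`,
#'   `sample_report`.
#' @export
run_qc <- function(expression, metadata, params = qc_params(),
                   keep_flagged = FALSE) {
  filt <- filter_low_expression(expression, params)
  out <- detect_outlier_samples(filt$expression, params)
  hae <- tryCatch(detect_haemolysis(filt$expression, params),
                  stavarsel_qc = function(e) NULL)
  sample_report <- out |>
    select("sample_id", outlier_score = "score", outlier = "flagged",
           "direction")
  if (!is.null(hae)) {
    sample_report <- sample_report |>
      left_join(hae |> select("sample_id", haemolysis_score = "score",
                              haemolysed = "flagged"),
                by = "sample_id")
  } else {
    sample_report$haemolysis_score <- NA_real_
    sample_report$haemolysed <- FALSE
  }
  sample_report <- sample_report |>
    mutate(flagged = .data$outlier | .data$haemolysed)
  keep <- sample_report$sample_id[!sample_report$flagged]
  if (keep_flagged) {
    if (any(sample_report$flagged)) {
      warn(paste0("Keeping ", sum(sample_report$flagged),
                  " flagged sample(s) as requested."))
    }
    keep <- sample_report$sample_id
  }
  expr <- filt$expression |> filter(.data$sample_id %in% keep)
  meta <- metadata |> filter(.data$sample_id %in% keep)
  list(expression = expr, metadata = meta,
       feature_report = filt$report, sample_report = sample_report)
}
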