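#' Parameter objects for the biomarker pipeline
#'
#' Constructors for the parameter lists used across the pipeline.  Defaults
#' follow the published workflow the package implements: low-expression
#' removal below an average of 5 CPM, outlier samples beyond 3 standard
#' deviations of the per-sample mean of mean-centred profiles, haemolysis
#' flagged 2 standard deviations above the cohort mean of red-blood-cell
#' marker levels, ratio prefilters at a coefficient of variation of 300% and
#' a Mann-Whitney p-value of 0.2, a leave-one-out outer loop with 100
#' repeats of 10-fold inner cross-validation for the Lasso penalty, a 50%
#' selection-frequency threshold, 2000 bootstrap resamples and 1000
#' Monte-Carlo n-2 subsampling iterations with 95% confidence intervals at
#' a 0.5 classification threshold.
#'
#' @param min_avg_cpm Features with mean CPM strictly below this are removed.
#' @param require_nonzero_in_all_samples Remove features with any zero count.
#' @param outlier_sd_multiplier Half-width, in standard deviations, of the
#'   two-sided outlier band on per-sample mean centred expression.
#' @param haemolysis_sd_multiplier One-sided haemolysis threshold in standard
#'   deviations above the mean marker score.
#' @param haemolysis_marker_ids Feature IDs of red-blood-cell enriched
#'   miRNAs used to score haemolysis.
#' @return A named list of validated parameters.
#' @export
qc_params <- function(min_avg_cpm = 5,
                      require_nonzero_in_all_samples = TRUE,
                      outlier_sd_multiplier = 3,
                      haemolysis_sd_multiplier = 2,
                      haemolysis_marker_ids = c("hsa-miR-451a",
                                                "hsa-miR-16-5p",
                                                "hsa-miR-486-5p")) {
  stopifnot(min_avg_cpm >= 0,
            outlier_sd_multiplier > 0,
            haemolysis_sd_multiplier > 0,
            length(haemolysis_marker_ids) >= 1)
  list(min_avg_cpm = min_avg_cpm,
       require_nonzero_in_all_samples = isTRUE(require_nonzero_in_all_samples),
       outlier_sd_multiplier = outlier_sd_multiplier,
       haemolysis_sd_multiplier = haemolysis_sd_multiplier,
       haemolysis_marker_ids = as.character(haemolysis_marker_ids))
}

#' @rdname qc_params
#' @param cv_threshold Ratios with a coefficient of variation above this in
#'   both comparison groups are removed (3.0 = 300%).
#' @param mwu_alpha_keep Ratios with a two-sided Mann-Whitney p-value above
#'   this are removed; a p-value exactly at the threshold is retained.
#' @param log2_ratios Model ratio features on the log2 scale instead of the
#'   raw quotient scale.
#' @export
prefilter_params <- function(cv_threshold = 3.0,
                             mwu_alpha_keep = 0.2,
                             log2_ratios = FALSE) {
  stopifnot(cv_threshold > 0, mwu_alpha_keep > 0, mwu_alpha_keep < 1)
  list(cv_threshold = cv_threshold,
       mwu_alpha_keep = mwu_alpha_keep,
       log2_ratios = isTRUE(log2_ratios))
}

#' @rdname qc_params
#' @param inner_folds Folds of the inner cross-validation for the penalty.
#' @param inner_repeats Number of repeats of the inner cross-validation.
#' @param lambda_rule `"min"` for the deviance-minimizing penalty,
#'   `"one_se"` for the one-standard-error rule.
#' @param classification_threshold Probability cut-point for class calls.
#' @param lambda_grid Optional fixed penalty grid; by default a geometric
#'   grid of `lambda_grid_size` values spanning `lambda_decades` decades
#'   below the smallest penalty that zeroes every coefficient, recomputed
#'   per training set.
#' @param lambda_grid_size,lambda_decades Size and span of the default grid.
#' @param lambda_average How per-training-set penalties are combined into
#'   the shared penalty: arithmetic (default) or geometric mean.
#' @export
cv_config <- function(inner_folds = 10L,
                      inner_repeats = 100L,
                      lambda_rule = c("min", "one_se"),
                      classification_threshold = 0.5,
                      lambda_grid = NULL,
                      lambda_grid_size = 100L,
                      lambda_decades = 4,
                      lambda_average = c("arithmetic", "geometric")) {
  lambda_rule <- match.arg(lambda_rule)
  lambda_average <- match.arg(lambda_average)
  stopifnot(inner_folds >= 2, inner_repeats >= 1,
            classification_threshold > 0, classification_threshold < 1,
            lambda_grid_size >= 2, lambda_decades > 0)
  if (!is.null(lambda_grid)) stopifnot(all(lambda_grid > 0))
  list(inner_folds = as.integer(inner_folds),
       inner_repeats = as.integer(inner_repeats),
       lambda_rule = lambda_rule,
       classification_threshold = classification_threshold,
       lambda_grid = lambda_grid,
       lambda_grid_size = as.integer(lambda_grid_size),
       lambda_decades = lambda_decades,
       lambda_average = lambda_average)
}

#' @rdname qc_params
#' @param frequency_threshold Minimum fraction of outer training sets in
#'   which a ratio must be selected to enter the ranked stable list.
#' @param max_model_size Largest model size scanned by the step-forward
#'   search.
#' @param size_selection_mode `"point"` uses the inner misclassification
#'   rate; `"conservative"` uses the worst-case rate from per-sample
#'   jackknife intervals.
#' @export
stability_config <- function(frequency_threshold = 0.5,
                             max_model_size = 10L,
                             size_selection_mode = c("point", "conservative")) {
  size_selection_mode <- match.arg(size_selection_mode)
  stopifnot(frequency_threshold > 0, frequency_threshold <= 1,
            max_model_size >= 1)
  list(frequency_threshold = frequency_threshold,
       max_model_size = as.integer(max_model_size),
       size_selection_mode = size_selection_mode)
}

#' @rdname qc_params
#' @param bootstrap_B Number of stratified bootstrap resamples.
#' @param jackknife_iterations Monte-Carlo subsampling iterations; ignored
#'   when `jackknife_mode = "exhaustive"`.
#' @param jackknife_mode `"auto"` enumerates all single deletions when the
#'   cohort has at most `exhaustive_max_n` samples (exact and cheaper) and
#'   falls back to Monte-Carlo draws otherwise.
#' @param exhaustive_max_n Cohort-size ceiling for automatic exhaustive
#'   enumeration.
#' @param ci_level Confidence level of the per-sample nonparametric
#'   intervals.
#' @param threshold Classification cut-point used by the worst-case rule.
#' @param refit_scope `"final_model"` refits the fixed feature set on each
#'   subsample; `"selection_and_fit"` re-runs the ratio prefilter and Lasso
#'   selection (at the fixed averaged penalty) on each subsample.
#' @export
uncertainty_config <- function(bootstrap_B = 2000L,
                               jackknife_iterations = 1000L,
                               jackknife_mode = c("auto", "montecarlo",
                                                  "exhaustive"),
                               exhaustive_max_n = 60L,
                               ci_level = 0.95,
                               threshold = 0.5,
                               refit_scope = NULL) {
  jackknife_mode <- match.arg(jackknife_mode)
  stopifnot(bootstrap_B >= 100, jackknife_iterations >= 100,
            ci_level > 0, ci_level < 1, threshold > 0, threshold < 1)
  if (!is.null(refit_scope)) {
    refit_scope <- match.arg(refit_scope, c("final_model", "selection_and_fit"))
  }
  list(bootstrap_B = as.integer(bootstrap_B),
       jackknife_iterations = as.integer(jackknife_iterations),
       jackknife_mode = jackknife_mode,
       exhaustive_max_n = as.integer(exhaustive_max_n),
       ci_level = ci_level,
       threshold = threshold,
       refit_scope = refit_scope)
}

#' @rdname qc_params
#' @param qc,prefilter,cv,stability,uncertainty Nested parameter objects.
#' @param seed Integer seed controlling every stochastic stage.
#' @export
run_config <- function(qc = qc_params(),
                       prefilter = prefilter_params(),
                       cv = cv_config(),
                       stability = stability_config(),
                       uncertainty = uncertainty_config(),
                       seed = 1L) {
  list(qc = qc, prefilter = prefilter, cv = cv, stability = stability,
       uncertainty = uncertainty, seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()] and its nested
#' constructors; missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config()` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build <- function(ctor, values) do.call(ctor, values %||% list())
  run_config(
    qc = build(qc_params, raw$qc),
    prefilter = build(prefilter_params, raw$prefilter),
    cv = build(cv_config, raw$cv),
    stability = build(stability_config, raw$stability),
    uncertainty = build(uncertainty_config, raw$uncertainty),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
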