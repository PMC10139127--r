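# StaVarSel: stabilized 3-stage nested cross-validation.  Stage 1 and 2
# reuse the standard nested CV machinery (per-split prefilter, penalty
# optimization, Lasso selection at the averaged penalty).  Stage 3 ranks
# ratios by how often the training-set Lasso fits selected them, scans
# model sizes along the ranked list with an extra round of
# cross-validations, and refits the chosen stable set in every training
# set.

#' Selection frequencies of ratios across outer training sets
#'
#' Counts, for each ratio, the fraction of outer training-set Lasso fits
#' that selected it.  Ratios at or above `frequency_threshold` form the
#' ranked stable list.  Ties in fraction are broken by the larger mean
#' absolute relaxed coefficient across the selecting splits, then
#' lexicographically, so the ranking is deterministic.
#'
#' @param per_split_selected List of character vectors, one per outer
#'   training set.
#' @param per_split_coefficients Optional list of named coefficient
#'   vectors (from the relaxed refits) used for tie-breaking.
#' @param frequency_threshold Minimum selection fraction (default 0.5).
#' @return A tibble `ratio_id`, `count`, `fraction`, `rank`, sorted by
#'   rank; only ratios meeting the threshold.
#' @export
compute_selection_frequencies <- function(per_split_selected,
                                          per_split_coefficients = NULL,
                                          frequency_threshold = 0.5) {
  n_splits <- length(per_split_selected)
  if (n_splits == 0) {
    abort("No per-split selections given.", class = "stavarsel_frequency")
  }
  all_ids <- sort(unique(unlist(per_split_selected)))
  counts <- vapply(all_ids, function(id) {
    sum(vapply(per_split_selected, function(s) id %in% s, logical(1)))
  }, numeric(1))
  mean_abs <- vapply(all_ids, function(id) {
    if (is.null(per_split_coefficients)) return(0)
    vals <- unlist(lapply(per_split_coefficients, function(cf) {
      if (!is.null(cf) && id %in% names(cf)) abs(cf[[id]]) else NULL
    }))
    if (length(vals) == 0) 0 else mean(vals)
  }, numeric(1))
  tab <- tibble(ratio_id = all_ids,
                count = as.integer(unname(counts)),
                fraction = unname(counts) / n_splits,
                mean_abs_coefficient = unname(mean_abs)) |>
    filter(.data$fraction >= frequency_threshold) |>
    arrange(desc(.data$fraction), desc(.data$mean_abs_coefficient),
            .data$ratio_id) |>
    mutate(rank = row_number())
  if (nrow(tab) == 0) {
    abort(paste0("No ratio was selected in at least ",
                 round(100 * frequency_threshold),
                 "% of training sets; consider lowering ",
                 "`frequency_threshold`."),
          class = "stavarsel_frequency")
  }
  tab
}

# Jackknife worst-case misclassification indicator for one inner held-out
# sample inside the step-forward search: refit the top-k model on every
# single further deletion of the inner training set and ask whether the
# band of predictions (plus the point prediction) reaches the wrong side
# of the threshold.
step_forward_worst_case <- function(Xk_tr, y_tr, x_new, y_new, point_prob,
                                    uncertainty, seed) {
  probs <- jackknife_probabilities(
    Xk_tr, y_tr, x_new,
    refit = function(Xs, ys) {
      b <- fit_logistic(Xs, ys, ridge_on_separation = FALSE)$coefficients
      function(xn) predict_logistic(b, xn)
    },
    config = uncertainty, seed = seed)
  qs <- quantile_type1(probs, ci_probs(uncertainty$ci_level))
  lo <- min(qs[1], point_prob)
  hi <- max(qs[2], point_prob)
  t <- uncertainty$threshold
  if (y_new == 0) hi >= t else lo < t
}

#' Step-forward optimization of the stable model size
#'
#' For each candidate size k (1 up to `max_model_size`), runs a
#' leave-one-out cross-validation within each outer training set: each
#' inner fit is an unpenalized logistic regression on the top-k ranked
#' ratios, and the inner held-out sample is classified at the threshold.
#' The per-training-set error is the inner misclassification rate; in
#' conservative mode each inner held-out sample additionally receives a
#' jackknife band from single-deletion refits and counts as misclassified
#' whenever the band reaches the wrong side of the threshold (the
#' worst-case rate, never below the point rate).  The chosen size
#' minimizes the mean error over training sets, smallest size on ties.
#'
#' @param ratios Wide ratio tibble or numeric matrix (all analysis
#'   samples).
#' @param labels 0/1 vector or two-level factor.
#' @param ranked_ids Ranked stable ratio IDs (best first).
#' @param stability [stability_config()]; `size_selection_mode` picks the
#'   error criterion.
#' @param cv [cv_config()] (classification threshold).
#' @param uncertainty [uncertainty_config()] (jackknife settings for
#'   conservative mode).
#' @param seed Integer seed (used only by Monte-Carlo jackknife draws).
#' @return A list of class `step_forward_curve`: `curve` (tibble `k`,
#'   `error`) and `chosen_k`.
#' @export
step_forward_size_selection <- function(ratios, labels, ranked_ids,
                                        stability = stability_config(),
                                        cv = cv_config(),
                                        uncertainty = uncertainty_config(),
                                        seed = 1L) {
  X <- if (is.matrix(ratios)) ratios else values_matrix(ratios)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(ranked_ids) == 0) {
    abort("Empty ranked list.", class = "stavarsel_frequency")
  }
  n <- nrow(X)
  conservative <- stability$size_selection_mode == "conservative"
  t <- cv$classification_threshold
  ks <- seq_len(min(stability$max_model_size, length(ranked_ids)))
  # inner training sets have n - 2 samples; k must leave a residual df
  estimable <- ks < (n - 2) - 1
  if (any(!estimable)) {
    warn(paste0("Model sizes ", paste(ks[!estimable], collapse = ", "),
                " skipped: too few inner training samples."))
    ks <- ks[estimable]
  }
  if (length(ks) == 0) {
    abort("No estimable model size.", class = "stavarsel_frequency")
  }
  errors <- vapply(ks, function(k) {
    Xk <- X[, ranked_ids[seq_len(k)], drop = FALSE]
    split_errors <- vapply(seq_len(n), function(i) {
      train <- setdiff(seq_len(n), i)
      miss <- vapply(seq_along(train), function(jj) {
        j <- train[jj]
        inner <- setdiff(train, j)
        b <- fit_logistic(Xk[inner, , drop = FALSE], y[inner],
                          ridge_on_separation = FALSE)$coefficients
        pj <- predict_logistic(b, Xk[j, , drop = FALSE])
        point_wrong <- if (y[j] == 0) pj >= t else pj < t
        if (!conservative) return(point_wrong)
        point_wrong || step_forward_worst_case(
          Xk[inner, , drop = FALSE], y[inner],
          Xk[j, , drop = FALSE], y[j], pj, uncertainty,
          seed = derive_seed(seed, i * 10000L + j * 100L + k))
      }, logical(1))
      mean(miss)
    }, numeric(1))
    mean(split_errors)
  }, numeric(1))
  chosen <- ks[which.min(errors)]
  structure(list(curve = tibble(k = ks, error = errors),
                 chosen_k = chosen,
                 mode = stability$size_selection_mode),
            class = "step_forward_curve")
}

#' Run the stabilized nested cross-validation (StaVarSel)
#'
#' The full 3-stage pipeline: (1) per-training-set ratio prefilter and
#' penalty optimization with penalty averaging, (2) Lasso selection at the
#' averaged penalty in every training set with relaxed refits (the
#' standard nested CV), (3) ranking of ratios by selection frequency
#' (threshold 50%), step-forward optimization of how many top-ranked
#' ratios to keep, relaxed refit of that single stable set in every
#' training set, and prediction of each held-out sample, which was
#' excluded from its own training set's selection throughout.
#'
#' If no ratio reaches the frequency threshold the pipeline falls back to
#' intercept-only models (with a warning) rather than failing, so null
#' cohorts remain analysable.
#'
#' @inheritParams run_standard_nested_cv
#' @param stability [stability_config()].
#' @param uncertainty [uncertainty_config()] (used by conservative size
#'   selection).
#' @return An object of class `stavarsel_fit` with, in addition to the
#'   `nested_cv` fields, `frequencies`, `curve`, `chosen_k`,
#'   `final_features`, and the stage-2 (standard nested CV) records for
#'   comparison.
#' @export
run_stavarsel <- function(ratios, metadata, comparison = NULL,
                          cv = cv_config(),
                          prefilter = prefilter_params(),
                          stability = stability_config(),
                          uncertainty = uncertainty_config(),
                          seed = 1L) {
  dat <- resolve_analysis_data(ratios, metadata, comparison)
  check_cohort_size(dat$y)
  stage1 <- outer_stage1(dat$X, dat$y, cv, prefilter, seed)
  lambda_bar <- average_lambda(stage1, cv)
  splits <- outer_stage2(dat$X, dat$y, stage1, lambda_bar, prefilter)
  threshold <- cv$classification_threshold
  Xm <- modeling_matrix(dat$X, prefilter)

  standard_records <- records_from_splits(splits, dat$sample_ids, dat$y,
                                          dat$comparison, threshold)

  freq <- tryCatch(
    compute_selection_frequencies(
      lapply(splits, `[[`, "selected"),
      lapply(splits, function(s) s$fit$coefficients),
      stability$frequency_threshold),
    stavarsel_frequency = function(e) {
      warn(conditionMessage(e))
      NULL
    })

  if (is.null(freq)) {
    final_features <- character(0)
    curve <- NULL
    chosen_k <- 0L
  } else {
    curve <- step_forward_size_selection(Xm, dat$y, freq$ratio_id,
                                         stability, cv, uncertainty,
                                         seed = derive_seed(seed, 777L))
    chosen_k <- curve$chosen_k
    final_features <- freq$ratio_id[seq_len(chosen_k)]
  }

  n <- nrow(dat$X)
  final_models <- purrr::map(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    relaxed_refit(Xm[tr, , drop = FALSE], dat$y[tr], final_features)
  })
  probs <- vapply(seq_len(n), function(i) {
    unname(predict_probability(final_models[[i]],
                               Xm[i, , drop = FALSE]))
  }, numeric(1))
  records <- tibble(
    sample_id = dat$sample_ids,
    true_label = dat$comparison[dat$y + 1L],
    y = dat$y,
    point_probability = probs
  ) |>
    mutate(predicted_label =
             dat$comparison[(.data$point_probability >= threshold) + 1L])

  structure(list(
    records = records,
    summary = summarize_classification(records, threshold),
    frequencies = freq,
    curve = curve,
    chosen_k = as.integer(chosen_k),
    final_features = final_features,
    final_models = final_models,
    lambda = lambda_bar,
    per_split = splits,
    stage1 = stage1,
    standard_records = standard_records,
    standard_summary = summarize_classification(standard_records, threshold),
    data = dat,
    config = list(cv = cv, prefilter = prefilter, stability = stability,
                  uncertainty = uncertainty, seed = as.integer(seed))
  ), class = "stavarsel_fit")
}
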