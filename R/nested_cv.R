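# Standard 2-stage nested cross-validation: LOOCV outer loop, per-training-
# set ratio prefilter and penalty optimization, penalty averaging across
# training sets, Lasso selection + relaxed refit per training set,
# prediction of each held-out sample.

# Resolve ratio tibble + metadata into the matrix/label pair all engines
# consume.
resolve_analysis_data <- function(ratios, metadata, comparison = NULL) {
  stopifnot(is_tibble(ratios) || is.data.frame(ratios))
  meta <- as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("metadata needs 'sample_id' and 'group' columns.",
          class = "stavarsel_io")
  }
  comparison <- comparison %||% (
    if (is.factor(meta$group)) levels(meta$group) else
      unique(as.character(meta$group)))
  meta <- meta |>
    mutate(group = as.character(.data$group)) |>
    filter(.data$group %in% comparison)
  ratios <- align_samples(as_tibble(ratios), meta)
  X <- values_matrix(ratios)
  y <- encode_labels(meta$group[match(rownames(X), meta$sample_id)],
                     comparison)
  list(X = X, y = y, sample_ids = rownames(X), comparison = comparison)
}

# Modeling-scale view of the ratio matrix.  The coefficient-of-variation
# prefilter always sees the raw quotients; the penalized and relaxed fits
# see log2 quotients when `log2_ratios` is on (the Mann-Whitney filter is
# rank-based and indifferent).
modeling_matrix <- function(X, prefilter) {
  if (isTRUE(prefilter$log2_ratios)) log2(X) else X
}

# Stage 1, shared between the standard nested CV and StaVarSel: for every
# leave-one-out split, prefilter ratios and optimize lambda on the
# training samples only.
outer_stage1 <- function(X, y, cv, prefilter, seed) {
  n <- nrow(X)
  Xm <- modeling_matrix(X, prefilter)
  purrr::map(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    retained <- prefilter_ratios(X[tr, , drop = FALSE], y[tr], prefilter)
    if (length(retained) == 0) {
      warn(paste0("Split ", i, ": no ratio survived the prefilter; ",
                  "intercept-only model recorded."))
      return(list(held_out = i, retained = character(0),
                  lambda_min = NA_real_, lambda_one_se = NA_real_))
    }
    lam <- optimize_lambda(Xm[tr, retained, drop = FALSE], y[tr], cv,
                           seed = derive_seed(seed, i))
    list(held_out = i, retained = retained,
         lambda_min = lam$lambda_min, lambda_one_se = lam$lambda_one_se)
  })
}

average_lambda <- function(stage1, cv) {
  lam <- vapply(stage1, function(s) {
    if (cv$lambda_rule == "min") s$lambda_min else s$lambda_one_se
  }, numeric(1))
  lam <- lam[is.finite(lam)]
  if (length(lam) == 0) {
    abort("No training set produced a lambda estimate.",
          class = "stavarsel_lasso")
  }
  if (cv$lambda_average == "geometric") exp(mean(log(lam))) else mean(lam)
}

# Stage 2: Lasso at the shared averaged penalty + relaxed refit per split.
outer_stage2 <- function(X, y, stage1, lambda_bar, prefilter) {
  Xm <- modeling_matrix(X, prefilter)
  purrr::map(stage1, function(s) {
    tr <- setdiff(seq_len(nrow(Xm)), s$held_out)
    if (length(s$retained) == 0) {
      fit <- relaxed_refit(Xm[tr, , drop = FALSE], y[tr], character(0))
      sel <- character(0)
    } else {
      lf <- fit_lasso(Xm[tr, s$retained, drop = FALSE], y[tr], lambda_bar)
      sel <- lf$selected
      fit <- relaxed_refit(Xm[tr, , drop = FALSE], y[tr], sel)
    }
    prob <- predict_probability(fit, Xm[s$held_out, , drop = FALSE])
    list(held_out = s$held_out, retained = s$retained, selected = sel,
         fit = fit, probability = unname(prob))
  })
}

records_from_splits <- function(splits, sample_ids, y, comparison,
                                threshold) {
  tibble(
    sample_id = sample_ids,
    true_label = comparison[y + 1L],
    y = y,
    point_probability = vapply(splits, `[[`, numeric(1), "probability"),
  ) |>
    mutate(predicted_label =
             comparison[(.data$point_probability >= threshold) + 1L])
}

#' Run the standard 2-stage nested cross-validation
#'
#' Outer leave-one-out loop; within each training set the ratio prefilter
#' is applied and the Lasso penalty optimized by repeated stratified
#' inner cross-validation; the per-training-set penalties (under the
#' configured rule) are then averaged, Lasso is refit at the shared
#' averaged penalty in every training set, its selection is refit
#' unpenalized (relaxed Lasso), and the held-out sample is scored.
#'
#' @param ratios Wide ratio tibble from [build_ratios()].
#' @param metadata Tibble with `sample_id` and `group`.
#' @param comparison Two group labels (negative first); defaults to the
#'   factor levels / unique values of `group`.
#' @param cv [cv_config()].
#' @param prefilter [prefilter_params()].
#' @param seed Integer seed.
#' @return An object of class `nested_cv`: a list with `records` (one row
#'   per held-out sample), `summary` (point-estimate classification
#'   summary), `lambda` (the shared averaged penalty), `per_split`
#'   bookkeeping, and the data needed for resampling-based uncertainty
#'   estimation.
#' @export
run_standard_nested_cv <- function(ratios, metadata, comparison = NULL,
                                   cv = cv_config(),
                                   prefilter = prefilter_params(),
                                   seed = 1L) {
  dat <- resolve_analysis_data(ratios, metadata, comparison)
  check_cohort_size(dat$y)
  stage1 <- outer_stage1(dat$X, dat$y, cv, prefilter, seed)
  lambda_bar <- average_lambda(stage1, cv)
  splits <- outer_stage2(dat$X, dat$y, stage1, lambda_bar, prefilter)
  records <- records_from_splits(splits, dat$sample_ids, dat$y,
                                 dat$comparison,
                                 cv$classification_threshold)
  structure(list(
    records = records,
    summary = summarize_classification(records,
                                       cv$classification_threshold),
    lambda = lambda_bar,
    per_split = splits,
    stage1 = stage1,
    data = dat,
    config = list(cv = cv, prefilter = prefilter, seed = as.integer(seed))
  ), class = "nested_cv")
}

check_cohort_size <- function(y) {
  if (length(y) < 8 || min(table(y)) < 3) {
    abort("Need at least 8 samples with at least 3 per class.",
          class = "stavarsel_design")
  }
}

#' Summarize held-out classification performance
#'
#' Specificity is the fraction of negative-class samples with probability
#' strictly below the threshold; sensitivity the fraction of
#' positive-class samples at or above it (a tie at the threshold is called
#' positive); balanced accuracy is their mean.
#'
#' @param records Tibble with `y` (0/1) and `point_probability` columns, as
#'   produced by the nested CV engines.
#' @param threshold Probability cut-point.
#' @return One-row tibble with `specificity`, `sensitivity`,
#'   `balanced_accuracy`, and class counts.
#' @export
summarize_classification <- function(records, threshold = 0.5) {
  if (nrow(records) == 0) {
    abort("No prediction records.", class = "stavarsel_summary")
  }
  y <- records$y
  p <- records$point_probability
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "stavarsel_summary")
  }
  spec <- mean(p[y == 0] < threshold)
  sens <- mean(p[y == 1] >= threshold)
  tibble(specificity = spec, sensitivity = sens,
         balanced_accuracy = (spec + sens) / 2,
         n_negative = sum(y == 0), n_positive = sum(y == 1))
}
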