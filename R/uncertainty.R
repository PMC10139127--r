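# Three estimators of the variance of cross-validation prediction error:
# naive normal (Wald on the per-class proportions), nonparametric
# bootstrap over the held-out prediction probabilities, and the
# conservative Monte-Carlo n-2 subsampling (general jackknife) estimator
# with simultaneous worst-case specificity/sensitivity bounds.

# Per-deletion prediction probabilities for one held-out sample.  Each
# jackknife subsample is the cohort minus the held-out sample minus one
# training sample, i.e. size n - 2; the refit is deterministic given the
# subsample, so the support has at most n - 1 points and Monte-Carlo
# iterations resample that support.
jackknife_probabilities <- function(X_tr, y_tr, x_new, refit, config, seed) {
  n_tr <- nrow(X_tr)
  if (n_tr < 5) {
    abort("Training set too small for n-2 subsampling.",
          class = "stavarsel_jackknife")
  }
  support <- rep(NA_real_, n_tr)
  for (d in seq_len(n_tr)) {
    ys <- y_tr[-d]
    if (length(unique(ys)) < 2) next  # class lost: this deletion is redrawn
    support[d] <- tryCatch({
      pred <- refit(X_tr[-d, , drop = FALSE], ys)
      unname(pred(x_new))
    }, error = function(e) NA_real_)
  }
  valid <- which(!is.na(support))
  if (length(valid) < n_tr / 2) {
    abort(paste0("More than half of the jackknife refits failed (",
                 n_tr - length(valid), " of ", n_tr, ")."),
          class = "stavarsel_jackknife")
  }
  mode <- config$jackknife_mode
  if (mode == "auto") {
    mode <- if (n_tr + 1 <= config$exhaustive_max_n) "exhaustive" else
      "montecarlo"
  }
  if (mode == "exhaustive") {
    support[valid]
  } else {
    withr::local_seed(seed)
    support[sample(valid, config$jackknife_iterations, replace = TRUE)]
  }
}

#' Jackknife distribution of the prediction probability for one sample
#'
#' Implements the conservative n-2 subsampling estimator for a single
#' held-out sample: the training set (the cohort minus the held-out
#' sample) is repeatedly reduced by one more uniformly chosen sample, the
#' model is re-derived on the size n-2 subsample, and the held-out sample
#' is rescored.  The nonparametric confidence interval is formed from
#' order statistics of the resulting probabilities.  By default all
#' single deletions are enumerated exactly when the cohort is small
#' enough; otherwise `jackknife_iterations` Monte-Carlo draws are used.
#' Deletions that would remove the last sample of a class are redrawn.
#'
#' @param training_values Matrix or wide tibble of training samples.
#' @param training_labels 0/1 vector or two-level factor.
#' @param held_out_sample Named numeric vector or one-row matrix/tibble.
#' @param model_spec How to re-derive the model on each subsample:
#'   `list(type = "final_model", feature_ids = ...)` refits the fixed
#'   feature set unpenalized; `list(type = "selection_and_fit", lambda =
#'   ..., prefilter = prefilter_params())` re-runs the ratio prefilter and
#'   Lasso selection at the fixed penalty before the relaxed refit;
#'   `list(type = "fixed", fit = <relaxed_fit>)` never refits (zero-width
#'   intervals).
#' @param config [uncertainty_config()].
#' @param seed Integer seed (Monte-Carlo draws only).
#' @return A list of class `jackknife_distribution`: `probabilities`,
#'   `mean`, `ci_low`, `ci_high`, `n_iterations`.
#' @export
jackknife_prediction_distribution <- function(training_values,
                                              training_labels,
                                              held_out_sample,
                                              model_spec,
                                              config = uncertainty_config(),
                                              seed = 1L) {
  X <- if (is.matrix(training_values)) training_values else
    values_matrix(training_values)
  y <- if (is.factor(training_labels)) as.integer(training_labels) - 1L else
    as.integer(training_labels)
  if (is_tibble(held_out_sample) || is.data.frame(held_out_sample)) {
    held_out_sample <- values_matrix(as_tibble(held_out_sample))
  }
  if (is.null(dim(held_out_sample))) {
    held_out_sample <- matrix(held_out_sample, nrow = 1,
                              dimnames = list(NULL,
                                              names(held_out_sample)))
  }
  refit <- refit_closure(model_spec)
  probs <- jackknife_probabilities(X, y, held_out_sample, refit, config,
                                   seed)
  qs <- quantile_type1(probs, ci_probs(config$ci_level))
  structure(list(probabilities = probs,
                 mean = mean(probs),
                 ci_low = qs[1],
                 ci_high = qs[2],
                 n_iterations = length(probs)),
            class = "jackknife_distribution")
}

refit_closure <- function(model_spec) {
  type <- model_spec$type %||% "final_model"
  # fits happen on the modeling scale; the CV prefilter always sees the
  # raw quotients it is defined on
  to_model <- if (isTRUE(model_spec$log2_ratios)) {
    function(m) log2(m)
  } else {
    identity
  }
  switch(
    type,
    final_model = function(Xs, ys) {
      fit <- relaxed_refit(to_model(Xs), ys, model_spec$feature_ids)
      function(xn) predict_probability(fit, to_model(xn))
    },
    selection_and_fit = function(Xs, ys) {
      pf <- model_spec$prefilter %||% prefilter_params()
      retained <- prefilter_ratios(Xs, ys, pf)
      Xm <- to_model(Xs)
      sel <- if (length(retained) == 0) character(0) else
        fit_lasso(Xm[, retained, drop = FALSE], ys,
                  model_spec$lambda)$selected
      fit <- relaxed_refit(Xm, ys, sel)
      function(xn) predict_probability(fit, to_model(xn))
    },
    fixed = function(Xs, ys) {
      function(xn) predict_probability(model_spec$fit, xn)
    },
    abort(paste0("Unknown model_spec type: ", type),
          class = "stavarsel_jackknife")
  )
}

#' Attach conservative jackknife intervals to a fitted nested CV
#'
#' Computes the n-2 subsampling distribution for every held-out sample of
#' a [run_standard_nested_cv()] or [run_stavarsel()] result and adds
#' `jk_mean`, `ci_low`, `ci_high`, `jk_n` columns to its `records`.  The
#' refit scope defaults to the model class: StaVarSel results refit the
#' fixed stable feature set; standard nested CV results re-run prefilter
#' and Lasso selection at the fit's averaged penalty.
#'
#' @param fit A `nested_cv` or `stavarsel_fit` object.
#' @param config [uncertainty_config()]; `refit_scope = NULL` picks the
#'   class default.
#' @param seed Integer seed.
#' @return The fit with augmented `records` and a `distributions` element.
#' @export
conservative_intervals <- function(fit, config = uncertainty_config(),
                                   seed = 1L) {
  stopifnot(inherits(fit, c("nested_cv", "stavarsel_fit")))
  scope <- config$refit_scope %||%
    if (inherits(fit, "stavarsel_fit")) "final_model" else
      "selection_and_fit"
  dat <- fit$data
  n <- nrow(dat$X)
  pf <- fit$config$prefilter
  model_spec_for <- function(i) {
    if (scope == "final_model") {
      feats <- if (inherits(fit, "stavarsel_fit")) fit$final_features else
        fit$per_split[[i]]$selected
      list(type = "final_model", feature_ids = feats,
           log2_ratios = pf$log2_ratios)
    } else {
      list(type = "selection_and_fit", lambda = fit$lambda,
           prefilter = pf, log2_ratios = pf$log2_ratios)
    }
  }
  dists <- purrr::map(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    jackknife_prediction_distribution(
      dat$X[tr, , drop = FALSE], dat$y[tr],
      dat$X[i, , drop = FALSE],
      model_spec_for(i), config, seed = derive_seed(seed, i))
  })
  fit$records <- fit$records |>
    mutate(jk_mean = vapply(dists, `[[`, numeric(1), "mean"),
           ci_low = vapply(dists, `[[`, numeric(1), "ci_low"),
           ci_high = vapply(dists, `[[`, numeric(1), "ci_high"),
           jk_n = vapply(dists, function(d) as.numeric(d$n_iterations),
                         numeric(1)))
  fit$distributions <- dists
  fit$uncertainty <- config
  fit
}

#' Naive normal (Wald) bounds on specificity and sensitivity
#'
#' The classical biased estimator: the per-class correct-classification
#' proportion receives a Wald interval p +/- z * sqrt(p(1-p)/n),
#' truncated to `[0, 1]`.  Degenerate at proportions of 0 or 1, where the
#' interval collapses -- a documented limitation of the naive method.
#'
#' @param records Records tibble with `y` and `point_probability`.
#' @param config [uncertainty_config()] (`ci_level`, `threshold`).
#' @return One-row summary tibble.
#' @export
naive_normal_bounds <- function(records, config = uncertainty_config()) {
  t <- config$threshold
  y <- records$y
  p <- records$point_probability
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "stavarsel_summary")
  }
  z <- qnorm(1 - (1 - config$ci_level) / 2)
  wald_lower <- function(phat, n) max(0, phat - z * sqrt(phat * (1 - phat) / n))
  spec <- mean(p[y == 0] < t)
  sens <- mean(p[y == 1] >= t)
  spec_lo <- wald_lower(spec, sum(y == 0))
  sens_lo <- wald_lower(sens, sum(y == 1))
  tibble(estimator = "naive",
         specificity = spec, sensitivity = sens,
         balanced_accuracy = (spec + sens) / 2,
         specificity_lower = spec_lo, sensitivity_lower = sens_lo,
         balanced_accuracy_lower = (spec_lo + sens_lo) / 2)
}

#' Bootstrap bounds on specificity and sensitivity
#'
#' `bootstrap_B` class-stratified resamples (with replacement, within each
#' class) of the held-out (probability, label) pairs; specificity,
#' sensitivity and balanced accuracy are recomputed per resample and the
#' lower bounds are the lower percentile order statistics.  When every
#' probability of a class lies on one side of the threshold the resampled
#' metric is constant and the interval has zero width; this non-
#' conservative estimator is uninformative under perfect separation, and
#' a warning says so.
#'
#' @inheritParams naive_normal_bounds
#' @param seed Integer seed.
#' @return One-row summary tibble.
#' @export
bootstrap_bounds <- function(records, config = uncertainty_config(),
                             seed = 1L) {
  t <- config$threshold
  y <- records$y
  p <- records$point_probability
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "stavarsel_summary")
  }
  neg <- p[y == 0]
  pos <- p[y == 1]
  if (all(neg < t) || all(neg >= t) || all(pos >= t) || all(pos < t)) {
    warn(paste0("A class's probabilities all lie on one side of the ",
                "threshold; bootstrap intervals are uninformative under ",
                "(near-)perfect separation."))
  }
  withr::local_seed(seed)
  B <- config$bootstrap_B
  spec_b <- numeric(B)
  sens_b <- numeric(B)
  for (b in seq_len(B)) {
    spec_b[b] <- mean(sample(neg, length(neg), replace = TRUE) < t)
    sens_b[b] <- mean(sample(pos, length(pos), replace = TRUE) >= t)
  }
  alpha <- (1 - config$ci_level) / 2
  tibble(estimator = "bootstrap",
         specificity = mean(neg < t), sensitivity = mean(pos >= t),
         balanced_accuracy = (mean(neg < t) + mean(pos >= t)) / 2,
         specificity_lower = quantile_type1(spec_b, alpha),
         sensitivity_lower = quantile_type1(sens_b, alpha),
         balanced_accuracy_lower =
           quantile_type1((spec_b + sens_b) / 2, alpha))
}

#' Conservative worst-case bounds from per-sample jackknife intervals
#'
#' The bounds of all per-sample confidence intervals are used
#' simultaneously: a negative-class sample counts as misclassified in the
#' worst case whenever the upper end of its band (or its point
#' probability) reaches the threshold, and a positive-class sample
#' whenever the lower end (or its point probability) falls below it.
#' Worst-case specificity and sensitivity are the complements of these
#' per-class worst-case misclassification rates, so they can never exceed
#' the point estimates.
#'
#' @param records Records tibble carrying `ci_low`, `ci_high` (and
#'   `jk_mean`) columns from [conservative_intervals()].
#' @inheritParams naive_normal_bounds
#' @return One-row summary tibble; the `*_lower` columns hold the
#'   worst-case bounds.
#' @export
conservative_bounds <- function(records, config = uncertainty_config()) {
  if (!all(c("ci_low", "ci_high") %in% names(records)) ||
      anyNA(records$ci_low)) {
    abort(paste0("Records lack jackknife intervals; run ",
                 "conservative_intervals() first."),
          class = "stavarsel_jackknife")
  }
  t <- config$threshold
  y <- records$y
  p <- records$point_probability
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "stavarsel_summary")
  }
  hi <- pmax(records$ci_high, records$jk_mean %||% records$ci_high, p)
  lo <- pmin(records$ci_low, records$jk_mean %||% records$ci_low, p)
  spec_wc <- mean(hi[y == 0] < t)
  sens_wc <- mean(lo[y == 1] >= t)
  spec <- mean(p[y == 0] < t)
  sens <- mean(p[y == 1] >= t)
  tibble(estimator = "conservative",
         specificity = spec, sensitivity = sens,
         balanced_accuracy = (spec + sens) / 2,
         specificity_lower = spec_wc, sensitivity_lower = sens_wc,
         balanced_accuracy_lower = (spec_wc + sens_wc) / 2)
}

#' Compare the point, naive, bootstrap and conservative estimators
#'
#' Collates the classification summary under all estimators into one
#' table.  Jackknife intervals are computed first if the fit does not
#' carry them yet.
#'
#' @param fit A `nested_cv` or `stavarsel_fit`.
#' @param config [uncertainty_config()].
#' @param seed Integer seed (bootstrap and Monte-Carlo jackknife).
#' @return A tibble with one row per estimator.
#' @export
estimator_report <- function(fit, config = uncertainty_config(),
                             seed = 1L) {
  if (is.null(fit$distributions)) {
    fit <- conservative_intervals(fit, config, seed = derive_seed(seed, 1L))
  }
  point <- fit$summary |>
    mutate(estimator = "point",
           specificity_lower = NA_real_, sensitivity_lower = NA_real_,
           balanced_accuracy_lower = NA_real_) |>
    select("estimator", "specificity", "sensitivity", "balanced_accuracy",
           "specificity_lower", "sensitivity_lower",
           "balanced_accuracy_lower")
  bind_rows(
    point,
    naive_normal_bounds(fit$records, config),
    bootstrap_bounds(fit$records, config, seed = derive_seed(seed, 2L)),
    conservative_bounds(fit$records, config)
  )
}
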