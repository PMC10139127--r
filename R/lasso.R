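# Penalized logistic machinery: inner-loop lambda optimization, Lasso
# selection at a fixed lambda, relaxed (unpenalized) refit, prediction.

# Geometric penalty grid: from the smallest lambda that zeroes every
# coefficient (the usual max |x_s' (y - ybar)| / n on standardized
# columns) down `decades` orders of magnitude.
lambda_grid_for <- function(X, y, size = 100L, decades = 4) {
  n <- nrow(X)
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu, `-`)^2))
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, s, `/`)
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = size))
}

#' Optimize the Lasso penalty by repeated inner cross-validation
#'
#' Runs `inner_repeats` rounds of class-stratified `inner_folds`-fold
#' cross-validation of an L1-penalized logistic regression over a shared
#' geometric penalty grid, averaging the binomial-deviance curves over
#' repeats.  `lambda_min` minimizes the averaged curve; `lambda_one_se` is
#' the largest penalty whose averaged deviance is within one standard
#' error (at the minimum) of the minimum.
#'
#' @param train_values Numeric matrix or wide tibble of training features.
#' @param labels 0/1 vector or two-level factor.
#' @param config [cv_config()].
#' @param seed Integer seed for fold draws.
#' @return A list with `lambda_min`, `lambda_one_se`, `grid`, `cvm`, `cvse`.
#' @export
optimize_lambda <- function(train_values, labels, config = cv_config(),
                            seed = 1L) {
  X <- if (is.matrix(train_values)) train_values else
    values_matrix(train_values)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "stavarsel_lasso")
  }
  if (nrow(X) < config$inner_folds) {
    abort("Fewer training samples than inner folds.",
          class = "stavarsel_lasso")
  }
  grid <- config$lambda_grid %||%
    lambda_grid_for(X, y, config$lambda_grid_size, config$lambda_decades)
  grid <- sort(grid, decreasing = TRUE)
  nl <- length(grid)
  withr::local_seed(seed)
  cvm_rep <- matrix(NA_real_, config$inner_repeats, nl)
  se_rep <- matrix(NA_real_, config$inner_repeats, nl)
  for (r in seq_len(config$inner_repeats)) {
    folds <- draw_valid_folds(y, config$inner_folds)
    fold_means <- matrix(NA_real_, config$inner_folds, nl)
    for (f in seq_len(config$inner_folds)) {
      tr <- folds != f
      # small-cohort class-size and path-truncation warnings are expected
      fit <- suppressWarnings(
        glmnet::glmnet(pad_for_glmnet(X[tr, , drop = FALSE]), y[tr],
                       family = "binomial", lambda = grid,
                       standardize = TRUE))
      pr <- predict(fit, pad_for_glmnet(X[!tr, , drop = FALSE]),
                    type = "response")
      # pad if glmnet returned a truncated path
      dev <- matrix(NA_real_, sum(!tr), nl)
      got <- match(signif(fit$lambda, 10), signif(grid, 10))
      dev[, got] <- binomial_deviance(y[!tr], pr)
      if (anyNA(dev)) {
        last <- max(got)
        for (j in seq_len(nl)[-seq_len(last)]) dev[, j] <- dev[, last]
      }
      fold_means[f, ] <- colMeans(dev)
    }
    cvm_rep[r, ] <- colMeans(fold_means)
    se_rep[r, ] <- apply(fold_means, 2, sd) / sqrt(config$inner_folds)
  }
  cvm <- colMeans(cvm_rep)
  cvse <- colMeans(se_rep)
  i_min <- which.min(cvm)
  lambda_min <- grid[i_min]
  ok <- cvm <= cvm[i_min] + cvse[i_min]
  lambda_one_se <- max(grid[ok])
  list(lambda_min = lambda_min, lambda_one_se = lambda_one_se,
       grid = grid, cvm = cvm, cvse = cvse)
}

# Stratified folds where every fold's training part keeps both classes;
# redraws up to 100 times (only degenerate class counts ever need it).
draw_valid_folds <- function(y, nfolds) {
  for (attempt in 1:100) {
    folds <- stratified_folds(y, nfolds)
    ok <- all(vapply(seq_len(nfolds), function(f) {
      length(unique(y[folds != f])) == 2
    }, logical(1)))
    if (ok) return(folds)
  }
  abort("Could not draw folds with both classes in every training part.",
        class = "stavarsel_lasso")
}

#' Fit an L1-penalized logistic regression at a fixed penalty
#'
#' @inheritParams optimize_lambda
#' @param lambda Positive penalty.
#' @return A list of class `lasso_fit`: `lambda`, `selected` (feature IDs
#'   with non-zero coefficient), `coefficients` (named, selected only),
#'   `intercept`.
#' @export
fit_lasso <- function(train_values, labels, lambda) {
  X <- if (is.matrix(train_values)) train_values else
    values_matrix(train_values)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(lambda > 0)
  # warm-started path ending exactly at the requested lambda
  path <- sort(unique(c(lambda * c(32, 16, 8, 4, 2), lambda)),
               decreasing = TRUE)
  fit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(pad_for_glmnet(X), y, family = "binomial",
                     lambda = path, standardize = TRUE)),
    error = function(e) {
      abort(paste0("Lasso did not converge at lambda = ", signif(lambda, 4),
                   " with ", ncol(X), " features: ", conditionMessage(e)),
            class = "stavarsel_lasso")
    })
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))[, 1]
  beta <- cf[-1]
  beta <- beta[names(beta) != ".stavarsel_dummy"]
  sel <- names(beta)[beta != 0]
  structure(list(lambda = lambda, selected = sel,
                 coefficients = beta[beta != 0],
                 intercept = unname(cf[1])),
            class = "lasso_fit")
}

#' Unpenalized (relaxed) logistic refit on a fixed feature set
#'
#' The relaxed-Lasso refit with relaxation parameter 0: a
#' maximum-likelihood logistic regression on exactly the given features.
#' With an empty feature set an intercept-only model at the class
#' prevalence is returned.  Complete or quasi-complete separation is
#' detected and recorded; the reported coefficients then come from a
#' weakly ridge-stabilized fit (penalty 1e-6) so downstream refits never
#' abort and predictions stay strictly inside (0, 1).
#'
#' @inheritParams optimize_lambda
#' @param feature_ids Character vector of columns to refit on (possibly
#'   empty).
#' @return A list of class `relaxed_fit`: `feature_ids`, `coefficients`
#'   (named, including `(Intercept)`), `separation`.
#' @export
relaxed_refit <- function(train_values, labels, feature_ids) {
  X <- if (is.matrix(train_values)) train_values else
    values_matrix(train_values)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) == 0) {
    prev <- mean(y)
    prev <- min(max(prev, 1e-10), 1 - 1e-10)
    return(structure(list(feature_ids = character(0),
                          coefficients = c(`(Intercept)` =
                                             stats::qlogis(prev)),
                          separation = FALSE),
                     class = "relaxed_fit"))
  }
  missing <- setdiff(feature_ids, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("Features absent from training data: ",
                 paste(missing, collapse = ", ")),
          class = "stavarsel_lasso")
  }
  if (nrow(X) < length(feature_ids) + 1) {
    abort(paste0("Cannot refit ", length(feature_ids), " features on ",
                 nrow(X), " samples."),
          class = "stavarsel_lasso")
  }
  Xf <- X[, feature_ids, drop = FALSE]
  fit <- fit_logistic(Xf, y)
  structure(list(feature_ids = feature_ids,
                 coefficients = fit$coefficients,
                 separation = fit$separation),
            class = "relaxed_fit")
}

#' Predict a class probability from a relaxed fit
#'
#' @param fit A `relaxed_fit`.
#' @param sample_values Named numeric vector, one-row matrix, or wide
#'   tibble row providing every fitted feature.
#' @return Probability (or vector of probabilities) strictly in (0, 1).
#' @export
predict_probability <- function(fit, sample_values) {
  stopifnot(inherits(fit, "relaxed_fit"))
  if (is_tibble(sample_values) || is.data.frame(sample_values)) {
    sample_values <- values_matrix(as_tibble(sample_values))
  }
  if (is.null(dim(sample_values))) {
    sample_values <- matrix(sample_values, nrow = 1,
                            dimnames = list(NULL, names(sample_values)))
  }
  if (length(fit$feature_ids) > 0) {
    missing <- setdiff(fit$feature_ids, colnames(sample_values))
    if (length(missing) > 0) {
      abort(paste0("Sample lacks feature(s): ",
                   paste(missing, collapse = ", ")),
            class = "stavarsel_lasso")
    }
    Xf <- sample_values[, fit$feature_ids, drop = FALSE]
  } else {
    Xf <- matrix(0, nrow(sample_values), 0)
  }
  p <- predict_logistic(fit$coefficients, Xf)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
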