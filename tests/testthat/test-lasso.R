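test_that("lambda optimization recovers a separating feature and orders rules", {
  fx <- signal_ratio_fixture(n_per_group = 10, n_noise = 6, shift = 8)
  cvc <- cv_config(inner_folds = 5, inner_repeats = 5)
  lam <- optimize_lambda(fx$X, fx$y, cvc, seed = 1)
  expect_gte(lam$lambda_one_se, lam$lambda_min)
  fit <- fit_lasso(fx$X, fx$y, lam$lambda_min)
  expect_true("sig" %in% fit$selected)
  # determinism given (data, config, seed)
  lam2 <- optimize_lambda(fx$X, fx$y, cvc, seed = 1)
  expect_identical(lam, lam2)
  lam3 <- optimize_lambda(fx$X, fx$y, cvc, seed = 2)
  expect_false(identical(lam$cvm, lam3$cvm))
})

test_that("repeated-CV deviance curve agrees with cv.glmnet on one repeat", {
  fx <- signal_ratio_fixture(n_per_group = 10, n_noise = 6, shift = 3)
  cvc <- cv_config(inner_folds = 5, inner_repeats = 1)
  lam <- optimize_lambda(fx$X, fx$y, cvc, seed = 31)
  # reproduce the same folds and feed them to cv.glmnet
  y <- fx$y
  folds <- withr::with_seed(31, stavarsel:::draw_valid_folds(y, 5))
  cvg <- glmnet::cv.glmnet(fx$X, y, family = "binomial", foldid = folds,
                           lambda = lam$grid, type.measure = "deviance",
                           standardize = TRUE)
  shared <- match(cvg$lambda, lam$grid)
  expect_equal(lam$cvm[shared], unname(cvg$cvm), tolerance = 1e-6)
})

test_that("null-label lambda selection matches cv.glmnet and stays sparse", {
  # With permuted labels the penalty choice should agree with the cited
  # cv.glmnet workflow on identical folds, and chance models stay small.
  sizes <- integer(0)
  agree <- 0L
  runs <- 10L
  for (s in seq_len(runs)) {
    withr::with_seed(1000 + s, {
      X <- matrix(exp(rnorm(20 * 15)), 20, 15)
      colnames(X) <- sprintf("r%02d", 1:15)
      y <- sample(rep(0:1, each = 10))
    })
    cvc <- cv_config(inner_folds = 5, inner_repeats = 1)
    lam <- optimize_lambda(X, y, cvc, seed = s)
    folds <- withr::with_seed(s, stavarsel:::draw_valid_folds(y, 5))
    cvg <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = folds,
                             lambda = lam$grid)
    if (abs(log(lam$lambda_min) - log(cvg$lambda.min)) < 1e-8) {
      agree <- agree + 1L
    }
    sizes <- c(sizes, length(fit_lasso(X, y, lam$lambda_min)$selected))
  }
  expect_equal(agree, runs)
  expect_lte(stats::median(sizes), 4)
})

test_that("lasso selection shrinks to empty at large lambda and handles collinearity", {
  fx <- signal_ratio_fixture()
  fit <- fit_lasso(fx$X, fx$y, 1e4)
  expect_length(fit$selected, 0)
  # duplicated column: coordinate descent splits the coefficient mass
  # between the copies; the total equals the single-copy solution
  Xd <- cbind(fx$X, sig_copy = fx$X[, "sig"])
  fit_single <- fit_lasso(fx$X, fx$y, 0.05)
  fit2 <- fit_lasso(Xd, fx$y, 0.05)
  total_dup <- sum(fit2$coefficients[names(fit2$coefficients) %in%
                                       c("sig", "sig_copy")])
  expect_equal(total_dup, unname(fit_single$coefficients["sig"]),
               tolerance = 1e-3)
  # one-SE selection is never larger than lambda_min selection (usually)
  cvc <- cv_config(inner_folds = 5, inner_repeats = 3)
  smaller <- 0L
  for (s in 1:10) {
    fxs <- signal_ratio_fixture(seed = 100 + s, shift = 3)
    lam <- optimize_lambda(fxs$X, fxs$y, cvc, seed = s)
    n_min <- length(fit_lasso(fxs$X, fxs$y, lam$lambda_min)$selected)
    n_1se <- length(fit_lasso(fxs$X, fxs$y, lam$lambda_one_se)$selected)
    if (n_1se <= n_min) smaller <- smaller + 1L
  }
  expect_gte(smaller / 10, 0.95)
})

test_that("relaxed refit reproduces the maximum-likelihood solution", {
  withr::with_seed(21, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    colnames(X) <- c("a", "b", "c")
    eta <- 0.5 + X[, 1] - 0.8 * X[, 2]
    y <- rbinom(40, 1, plogis(eta))
  })
  fit <- relaxed_refit(X, y, c("a", "b"))
  oracle <- irls_logistic(X[, c("a", "b")], y)
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
  # removing the penalty can only improve training deviance
  lfit <- fit_lasso(X, y, 0.05)
  if (length(lfit$selected) > 0) {
    rfit <- relaxed_refit(X, y, lfit$selected)
    dev_of <- function(int, beta, cols) {
      p <- plogis(int + X[, cols, drop = FALSE] %*% beta)
      -2 * sum(y * log(p) + (1 - y) * log(1 - p))
    }
    d_lasso <- dev_of(lfit$intercept, lfit$coefficients, lfit$selected)
    d_relax <- dev_of(rfit$coefficients[1], rfit$coefficients[-1],
                      rfit$feature_ids)
    expect_lte(d_relax, d_lasso + 1e-8)
  }
})

test_that("empty feature sets give prevalence fits and separation is flagged", {
  y <- c(rep(0, 13), rep(1, 7))
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "a"))
  fit <- relaxed_refit(X, y, character(0))
  expect_equal(unname(predict_probability(fit, c(a = 3))), 0.35,
               tolerance = 1e-12)
  # perfectly separating feature
  Xs <- matrix(c(rnorm(10, -3), rnorm(10, 3)), 20, 1,
               dimnames = list(NULL, "s"))
  ys <- rep(0:1, each = 10)
  sf <- relaxed_refit(Xs, ys, "s")
  expect_true(sf$separation)
  p <- predict_probability(sf, Xs)
  expect_true(all(p > 0 & p < 1))
  # more features than samples is a hard error
  Xw <- matrix(rnorm(4 * 6), 4, 6,
               dimnames = list(NULL, sprintf("f%d", 1:6)))
  expect_error(relaxed_refit(Xw, c(0, 1, 0, 1), colnames(Xw)),
               class = "stavarsel_lasso")
})

test_that("probability predictions honour the logistic link and contracts", {
  fit <- structure(list(feature_ids = character(0),
                        coefficients = c(`(Intercept)` = 0),
                        separation = FALSE), class = "relaxed_fit")
  expect_equal(unname(predict_probability(fit, c(x = 1))), 0.5)
  fit2 <- structure(list(feature_ids = c("a", "b"),
                         coefficients = c(`(Intercept)` = 1, a = 2, b = -1),
                         separation = FALSE), class = "relaxed_fit")
  expect_equal(unname(predict_probability(fit2, c(a = 0.5, b = 2))),
               plogis(1 + 1 - 2))
  expect_error(predict_probability(fit2, c(a = 1)), "b",
               class = "stavarsel_lasso")
})
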