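test_that("naive Wald bounds match the closed form and degenerate at 1", {
  cfg <- uncertainty_config()
  # 16 of 20 negatives correct (spec 0.8), all 13 positives correct
  rec <- records_tbl(c(rep(0, 20), rep(1, 13)),
                     c(rep(0.1, 16), rep(0.9, 4), rep(0.9, 13)))
  out <- naive_normal_bounds(rec, cfg)
  z <- qnorm(0.975)
  expect_equal(z, 1.959964, tolerance = 1e-6)
  expect_equal(out$specificity, 0.8)
  expect_equal(out$specificity_lower, 0.8 - z * sqrt(0.8 * 0.2 / 20),
               tolerance = 1e-12)
  # p-hat = 1 collapses the Wald interval (documented naive limitation)
  expect_equal(out$sensitivity_lower, 1)
  expect_equal(out$balanced_accuracy_lower,
               (out$specificity_lower + 1) / 2)
})

test_that("bootstrap bounds are seeded, on the resample grid, and warn under separation", {
  cfg <- uncertainty_config(bootstrap_B = 500)
  # one of ten negatives misclassified
  rec <- records_tbl(c(rep(0, 10), rep(1, 10)),
                     c(rep(0.1, 9), 0.9, rep(0.8, 9), 0.3))
  b1 <- bootstrap_bounds(rec, cfg, seed = 4)
  b2 <- bootstrap_bounds(rec, cfg, seed = 4)
  expect_identical(b1, b2)
  # resampled specificities live on the tenths grid, bound cannot exceed point
  expect_true(b1$specificity_lower %in% ((0:10) / 10))
  expect_lte(b1$specificity_lower, 0.9)
  # perfect separation: zero-width, warning
  sep <- records_tbl(rep(0:1, each = 8),
                     c(rep(0.1, 8), rep(0.9, 8)))
  expect_warning(bs <- bootstrap_bounds(sep, cfg, seed = 1), "separation")
  expect_equal(bs$specificity_lower, 1)
  expect_equal(bs$sensitivity_lower, 1)
})

test_that("bootstrap lower bound matches binomial enumeration at small n", {
  # with 10 negatives, 1 misclassified, resampled specificity is
  # Binomial(10, 0.9)/10; the 2.5% order statistic over B draws converges
  # to the distribution's 2.5% quantile (type-1 on the exact distribution)
  cfg <- uncertainty_config(bootstrap_B = 20000)
  rec <- records_tbl(c(rep(0, 10), rep(1, 10)),
                     c(rep(0.1, 9), 0.9, rep(0.8, 10)))
  b <- suppressWarnings(bootstrap_bounds(rec, cfg, seed = 10))
  exact_q <- qbinom(0.025, 10, 0.9) / 10
  expect_equal(b$specificity_lower, exact_q)
})

test_that("intercept-only jackknife support is the exact two-point enumeration", {
  # cohort n = 21: held-out 1, training 20 with 7 positives
  y_tr <- c(rep(0, 13), rep(1, 7))
  X_tr <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "r"))
  d <- jackknife_prediction_distribution(
    X_tr, y_tr, c(r = 0),
    model_spec = list(type = "final_model", feature_ids = character(0)),
    config = uncertainty_config(jackknife_mode = "exhaustive"))
  expect_setequal(round(unique(d$probabilities), 12),
                  round(c(7 / 19, 6 / 19), 12))
  expect_equal(d$ci_low, 6 / 19, tolerance = 1e-12)
  expect_equal(d$ci_high, 7 / 19, tolerance = 1e-12)
  expect_equal(d$n_iterations, 20)
})

test_that("fixed-coefficient models give zero-width intervals", {
  fit <- structure(list(feature_ids = "r",
                        coefficients = c(`(Intercept)` = 0.3, r = 0),
                        separation = FALSE), class = "relaxed_fit")
  X_tr <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "r"))
  d <- jackknife_prediction_distribution(
    X_tr, rep(0:1, 6), c(r = 1),
    model_spec = list(type = "fixed", fit = fit),
    config = uncertainty_config(jackknife_mode = "exhaustive"))
  expect_equal(d$ci_low, d$ci_high)
  expect_equal(d$ci_low, plogis(0.3), tolerance = 1e-12)
})

test_that("Monte-Carlo and exhaustive jackknife give identical CI bounds", {
  withr::with_seed(8, {
    X_tr <- matrix(rnorm(12 * 2), 12, 2,
                   dimnames = list(NULL, c("a", "b")))
    y_tr <- rep(0:1, each = 6)
    x_new <- c(a = 0.2, b = -0.4)
  })
  spec <- list(type = "final_model", feature_ids = c("a", "b"))
  ex <- jackknife_prediction_distribution(
    X_tr, y_tr, x_new, spec,
    uncertainty_config(jackknife_mode = "exhaustive"))
  mc <- jackknife_prediction_distribution(
    X_tr, y_tr, x_new, spec,
    uncertainty_config(jackknife_mode = "montecarlo",
                       jackknife_iterations = 5000), seed = 3)
  expect_equal(mc$ci_low, ex$ci_low, tolerance = 1e-12)
  expect_equal(mc$ci_high, ex$ci_high, tolerance = 1e-12)
  expect_setequal(round(unique(mc$probabilities), 12),
                  round(unique(ex$probabilities), 12))
})

test_that("worst-case rule counts boundary intervals as errors", {
  cfg <- uncertainty_config()
  # negative with CI [0.10, 0.60]: misclassified in the worst case
  # positive with CI [0.55, 0.90]: correct in the worst case
  rec <- records_tbl(c(0, 1), c(0.2, 0.7),
                     ci_low = c(0.10, 0.55), ci_high = c(0.60, 0.90),
                     jk_mean = c(0.2, 0.7))
  out <- conservative_bounds(rec, cfg)
  expect_equal(out$specificity_lower, 0)   # sole negative counted wrong
  expect_equal(out$sensitivity_lower, 1)
  # zero-width CIs: conservative equals point exactly
  rec2 <- records_tbl(rep(0:1, each = 5),
                      c(rep(0.2, 4), 0.8, rep(0.9, 4), 0.1),
                      ci_low = c(rep(0.2, 4), 0.8, rep(0.9, 4), 0.1),
                      ci_high = c(rep(0.2, 4), 0.8, rep(0.9, 4), 0.1))
  out2 <- conservative_bounds(rec2, cfg)
  expect_equal(out2$specificity_lower, out2$specificity)
  expect_equal(out2$sensitivity_lower, out2$sensitivity)
  # missing intervals are a hard error
  rec3 <- records_tbl(0:1, c(0.2, 0.8))
  expect_error(conservative_bounds(rec3, cfg),
               class = "stavarsel_jackknife")
})

test_that("conservative bounds never exceed point estimates (dominance)", {
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- sample(6:20, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      p <- runif(n)
      lo <- pmax(p - runif(n, 0, 0.4), 0)
      hi <- pmin(p + runif(n, 0, 0.4), 1)
      rec <- records_tbl(y, p, ci_low = lo, ci_high = hi, jk_mean = p)
      out <- conservative_bounds(rec, uncertainty_config())
      expect_lte(out$specificity_lower, out$specificity)
      expect_lte(out$sensitivity_lower, out$sensitivity)
    }
  })
})

test_that("raising the confidence level never narrows intervals or raises bounds", {
  withr::with_seed(9, {
    X_tr <- matrix(rnorm(14 * 2), 14, 2,
                   dimnames = list(NULL, c("a", "b")))
    y_tr <- rep(0:1, 7)
    x_new <- c(a = 0.1, b = 0.5)
  })
  spec <- list(type = "final_model", feature_ids = c("a", "b"))
  d95 <- jackknife_prediction_distribution(
    X_tr, y_tr, x_new, spec,
    uncertainty_config(jackknife_mode = "exhaustive", ci_level = 0.95))
  d99 <- jackknife_prediction_distribution(
    X_tr, y_tr, x_new, spec,
    uncertainty_config(jackknife_mode = "exhaustive", ci_level = 0.99))
  expect_lte(d99$ci_low, d95$ci_low)
  expect_gte(d99$ci_high, d95$ci_high)
})

test_that("jackknife intervals have positive width when refits differ", {
  fx <- signal_ratio_fixture(n_per_group = 8, n_noise = 2, shift = 2)
  spec <- list(type = "final_model", feature_ids = "sig")
  d <- jackknife_prediction_distribution(
    fx$X[-1, ], fx$y[-1], fx$X[1, ], spec,
    uncertainty_config(jackknife_mode = "exhaustive"))
  expect_gt(d$ci_high - d$ci_low, 0)
})
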