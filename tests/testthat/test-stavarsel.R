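test_that("selection frequencies count, threshold and tie-break deterministically", {
  sel <- c(rep(list(c("a", "b")), 20), rep(list(c("a", "c"))
           , 15))
  # a: 35/35, b: 20/35 (0.571), c: 15/35 (0.429)
  tab <- compute_selection_frequencies(sel, frequency_threshold = 0.5)
  expect_equal(tab$ratio_id, c("a", "b"))
  expect_equal(tab$fraction[tab$ratio_id == "b"], 20 / 35, tolerance = 1e-12)
  expect_false("c" %in% tab$ratio_id)
  # 17/35 = 0.486 misses the "at least 50%" rule
  sel2 <- c(rep(list("a"), 18), rep(list(c("a", "b")), 17))
  tab2 <- compute_selection_frequencies(sel2, frequency_threshold = 0.5)
  expect_false("b" %in% tab2$ratio_id)
  # ties resolved by mean |coefficient| then lexically, reproducibly
  sel3 <- rep(list(c("x", "y")), 10)
  coefs <- rep(list(c(x = 0.5, y = 2)), 10)
  tab3 <- compute_selection_frequencies(sel3, coefs)
  expect_equal(tab3$ratio_id, c("y", "x"))
  tab3b <- compute_selection_frequencies(rev(sel3), rev(coefs))
  expect_equal(tab3$ratio_id, tab3b$ratio_id)
  # lexical fallback when coefficients tie too
  tab4 <- compute_selection_frequencies(sel3)
  expect_equal(tab4$ratio_id, c("x", "y"))
  # nothing reaches the threshold: hard error with guidance
  expect_error(compute_selection_frequencies(list("a", "b", "c", "d")),
               "threshold", class = "stavarsel_frequency")
})

test_that("step-forward search prefers the informative prefix and breaks ties small", {
  # two informative ratios, several pure-noise ratios ranked after them
  withr::with_seed(33, {
    n <- 24
    y <- rep(0:1, each = 12)
    sig1 <- exp(rnorm(n, 0, 0.4) + y * 1.6)
    sig2 <- exp(rnorm(n, 0, 0.4) + y * 1.6)
    noise <- matrix(exp(rnorm(n * 5, 0, 0.6)), n, 5)
  })
  X <- cbind(s1 = sig1, s2 = sig2, noise)
  colnames(X)[3:7] <- sprintf("n%d", 1:5)
  curve <- step_forward_size_selection(
    X, y, colnames(X),
    stability = stability_config(max_model_size = 5),
    cv = cv_config(), uncertainty = uncertainty_config(), seed = 1)
  expect_s3_class(curve, "step_forward_curve")
  expect_lte(curve$chosen_k, 3)
  expect_equal(curve$curve$k, 1:5)
  # minimum is attained at the chosen k, smallest on ties
  mins <- which(curve$curve$error == min(curve$curve$error))
  expect_equal(curve$chosen_k, curve$curve$k[min(mins)])
})

test_that("conservative step-forward errors dominate point errors", {
  withr::with_seed(41, {
    n <- 14
    y <- rep(0:1, each = 7)
    X <- cbind(s = exp(rnorm(n, 0, 0.5) + y * 1.2),
               n1 = exp(rnorm(n, 0, 0.5)),
               n2 = exp(rnorm(n, 0, 0.5)))
  })
  args <- list(X, y, colnames(X), cv = cv_config(),
               uncertainty = uncertainty_config(jackknife_mode =
                                                  "exhaustive"))
  pt <- do.call(step_forward_size_selection,
                c(args, list(stability = stability_config(
                  max_model_size = 3, size_selection_mode = "point"),
                  seed = 2)))
  cons <- do.call(step_forward_size_selection,
                  c(args, list(stability = stability_config(
                    max_model_size = 3, size_selection_mode =
                      "conservative"), seed = 2)))
  expect_true(all(cons$curve$error >= pt$curve$error - 1e-12))
})

test_that("model sizes too large for the inner training sets are skipped", {
  withr::with_seed(5, {
    X <- matrix(exp(rnorm(10 * 9)), 10, 9)
    colnames(X) <- sprintf("r%d", 1:9)
    y <- rep(0:1, each = 5)
  })
  expect_warning(
    curve <- step_forward_size_selection(
      X, y, colnames(X), stability = stability_config(max_model_size = 9),
      cv = cv_config(), uncertainty = uncertainty_config(), seed = 1),
    "skipped")
  expect_lt(max(curve$curve$k), 9)
})

test_that("the full StaVarSel pipeline recovers a planted pair and books k", {
  ch <- generate_cohort(cohort_design(
    n_per_group = c(10L, 10L), n_features = 12L,
    informative_pairs = tibble::tibble(numerator = 3L, denominator = 8L,
                                       log2fc = 2.5),
    seed = 71))
  r <- build_ratios(ch$expression)
  sv <- suppressWarnings(run_stavarsel(
    r, ch$metadata, cv = cv_config(inner_folds = 4, inner_repeats = 3),
    prefilter = prefilter_params(log2_ratios = TRUE), seed = 7))
  expect_s3_class(sv, "stavarsel_fit")
  expect_equal(length(sv$final_features), sv$chosen_k)
  expect_equal(nrow(sv$records), 20)
  expect_true(ch$truth$informative_ratios %in% sv$final_features)
  expect_gte(sv$summary$balanced_accuracy, 0.7)
  # glance reports the chosen size
  expect_equal(glance(sv)$chosen_k, sv$chosen_k)
})

test_that("null cohorts fall back to intercept-only models with a warning", {
  ch <- generate_cohort(cohort_design(
    n_per_group = c(8L, 8L), n_features = 8L, seed = 90))
  r <- build_ratios(ch$expression)
  w <- testthat::capture_warnings(
    sv <- run_stavarsel(r, ch$metadata,
                        cv = cv_config(inner_folds = 4, inner_repeats = 2),
                        seed = 9))
  expect_true(any(grepl("threshold|prefilter", w)))
  if (sv$chosen_k == 0) {
    expect_length(sv$final_features, 0)
    expect_null(sv$curve)
  }
  expect_equal(nrow(sv$records), 16)
})

test_that("held-out samples never enter their split's training stages", {
  ch <- generate_cohort(cohort_design(
    n_per_group = c(8L, 8L), n_features = 10L,
    informative_pairs = tibble::tibble(numerator = 1L, denominator = 5L,
                                       log2fc = 2.5),
    seed = 15))
  r <- build_ratios(ch$expression)
  cvc <- cv_config(inner_folds = 4, inner_repeats = 2)
  f1 <- suppressWarnings(run_stavarsel(r, ch$metadata, cv = cvc, seed = 3))
  mutated <- r
  mutated[5, -1] <- mutated[5, -1] * 40
  f2 <- suppressWarnings(run_stavarsel(mutated, ch$metadata, cv = cvc,
                                       seed = 3))
  expect_identical(f1$per_split[[5]]$retained, f2$per_split[[5]]$retained)
  expect_identical(f1$stage1[[5]]$lambda_min, f2$stage1[[5]]$lambda_min)
})

test_that("stable selections are more reproducible across seeds than raw Lasso", {
  # Jaccard similarity of StaVarSel final sets across reruns with
  # different CV seeds vs similarity of the per-split Lasso selections
  # from the standard stage (the stabilization claim, as a tendency).
  ch <- generate_cohort(cohort_design(
    n_per_group = c(10L, 10L), n_features = 12L,
    informative_pairs = tibble::tibble(numerator = c(3L, 7L),
                                       denominator = c(8L, 2L),
                                       log2fc = c(2, 2)),
    seed = 55))
  r <- build_ratios(ch$expression)
  cvc <- cv_config(inner_folds = 4, inner_repeats = 3)
  pf <- prefilter_params(log2_ratios = TRUE)
  fits <- lapply(1:3, function(s) {
    suppressWarnings(run_stavarsel(r, ch$metadata, cv = cvc,
                                   prefilter = pf, seed = s))
  })
  jacc <- function(a, b) {
    if (length(a) == 0 && length(b) == 0) return(1)
    length(intersect(a, b)) / length(union(a, b))
  }
  pairs <- combn(3, 2)
  stable_sim <- mean(apply(pairs, 2, function(ij) {
    jacc(fits[[ij[1]]]$final_features, fits[[ij[2]]]$final_features)
  }))
  lasso_sim <- mean(vapply(fits, function(f) {
    sels <- lapply(f$per_split, `[[`, "selected")
    ij <- utils::combn(length(sels), 2)
    mean(apply(ij, 2, function(kk) jacc(sels[[kk[1]]], sels[[kk[2]]])))
  }, numeric(1)))
  expect_gte(stable_sim, lasso_sim - 0.05)
})
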