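# Internal numerical helpers shared across the pipeline.

# Deterministic child seed derived from a user seed and a stage offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629L)
}

# Nearest-order-statistic (inverse-ECDF, quantile type 1) quantiles.
# Every returned bound is an element of `x`, which is what makes
# Monte-Carlo and exhaustive jackknife intervals comparable: both are
# order statistics over the same support.
quantile_type1 <- function(x, probs) {
  xs <- sort(x)
  n <- length(xs)
  idx <- pmin(pmax(ceiling(probs * n), 1L), n)
  xs[idx]
}

ci_probs <- function(ci_level) {
  alpha <- (1 - ci_level) / 2
  c(alpha, 1 - alpha)
}

# Class-stratified fold assignment for k-fold cross-validation.
# Within each class, samples are randomly permuted and dealt round-robin,
# so fold class counts differ by at most one.
stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

# Binomial deviance contributions, clamped away from 0/1 at 1e-5 (the
# cv.glmnet convention for binomial CV curves).
binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-5), 1 - 1e-5)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

# Ridge-stabilized logistic regression by Newton iterations.  Used as the
# fallback when the unpenalized fit separates; the intercept is never
# penalized.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 50L, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1, 1] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# Fast unpenalized logistic fit with separation detection.  `X` excludes the
# intercept column; returns coefficients as c(intercept, slopes).
fit_logistic <- function(X, y, ridge_on_separation = TRUE) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(glm.fit(Xd, y, family = binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # scale-free separation symptom: a fitted log-odds beyond +/-30 means a
  # probability numerically at 0/1, i.e. (quasi-)complete separation
  separated <- !fit$converged ||
    max(abs(fit$linear.predictors)) > 30
  if (separated && ridge_on_separation) {
    beta <- ridge_logistic(Xd, y, lambda = 1e-6)
    names(beta) <- colnames(Xd)
  }
  list(coefficients = beta, separation = separated)
}

predict_logistic <- function(beta, X) {
  plogis(drop(cbind(1, X) %*% beta))
}

# glmnet refuses single-column matrices; pad with an all-zero dummy whose
# coefficient is necessarily zero and strip it from results.
pad_for_glmnet <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `.stavarsel_dummy` = 0)
}

# Vectorised two-sided Mann-Whitney U p-values across the columns of `X`.
# Exact null distribution when there are no ties in a column and both
# groups have fewer than 50 samples (the stats::wilcox.test convention);
# otherwise a tie-corrected normal approximation with continuity
# correction.  Verified against stats::wilcox.test in the test suite.
mwu_pvalues <- function(X, in_group_a) {
  XA <- X[in_group_a, , drop = FALSE]
  XB <- X[!in_group_a, , drop = FALSE]
  nA <- nrow(XA)
  nB <- nrow(XB)
  p <- ncol(X)
  U <- numeric(p)
  # U = #{(a, b) : x_a > x_b} + 0.5 * #{ties}; accumulate one group-A row
  # at a time so each pass is vectorised over all columns.
  for (a in seq_len(nA)) {
    xa_m <- matrix(XA[a, ], nB, p, byrow = TRUE)
    U <- U + colSums(xa_m > XB) + 0.5 * colSums(xa_m == XB)
  }
  any_tie <- apply(X, 2, function(v) anyDuplicated(v) > 0L)
  tie_term <- numeric(p)
  for (j in which(any_tie)) {
    tt <- table(X[, j])
    tie_term[j] <- sum(tt^3 - tt)
  }
  pvals <- numeric(p)
  exact_ok <- !any_tie & nA < 50 & nB < 50
  if (any(exact_ok)) {
    u <- U[exact_ok]
    lower <- pwilcox(u, nA, nB)
    upper <- 1 - pwilcox(u - 1, nA, nB)
    pvals[exact_ok] <- pmin(1, 2 * pmin(lower, upper))
  }
  if (any(!exact_ok)) {
    u <- U[!exact_ok]
    nn <- nA + nB
    mu <- nA * nB / 2
    sigma2 <- nA * nB / 12 * ((nn + 1) - tie_term[!exact_ok] / (nn * (nn - 1)))
    z <- u - mu
    z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(pmax(sigma2, 1e-300))
    pvals[!exact_ok] <- pmin(1, 2 * pnorm(-abs(z)))
  }
  pvals
}

# --- tabular <-> matrix plumbing -------------------------------------------

# Wide sample table (first column sample_id) -> numeric matrix with
# sample_id rownames.
values_matrix <- function(tbl, id_col = "sample_id") {
  stopifnot(id_col %in% names(tbl))
  ids <- as.character(tbl[[id_col]])
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_tibble <- function(m, id_col = "sample_id") {
  out <- as_tibble(m)
  out <- tibble(!!id_col := rownames(m)) |> dplyr::bind_cols(out)
  out
}

# Encode a two-level group vector as 0/1 with the first comparison label
# as the negative class.
encode_labels <- function(group, comparison) {
  if (length(comparison) != 2 || comparison[1] == comparison[2]) {
    abort("`comparison` must be two distinct group labels.",
          class = "stavarsel_bad_comparison")
  }
  bad <- setdiff(unique(group), comparison)
  if (length(bad) > 0) {
    abort(paste0("Group labels outside the comparison: ",
                 paste(bad, collapse = ", ")),
          class = "stavarsel_bad_comparison")
  }
  as.integer(group == comparison[2])
}
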