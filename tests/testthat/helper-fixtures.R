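# Shared fixtures, built in code.

# tiny wide expression tibble from a plain matrix
expr_tbl <- function(m, sample_ids = NULL, feature_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(feature_ids)) feature_ids <- sprintf("f%02d", seq_len(ncol(m)))
  rownames(m) <- sample_ids
  colnames(m) <- feature_ids
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                   tibble::as_tibble(m))
}

# records tibble in the format the summary/uncertainty functions expect
records_tbl <- function(y, p, ci_low = NULL, ci_high = NULL,
                        jk_mean = NULL) {
  out <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_along(y)),
    true_label = c("neg", "pos")[y + 1L],
    y = y,
    point_probability = p
  )
  if (!is.null(ci_low)) {
    out$jk_mean <- jk_mean %||% p
    out$ci_low <- ci_low
    out$ci_high <- ci_high
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent IRLS oracle for unpenalized logistic regression (used to
# validate relaxed refits without going through glm.fit)
irls_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  Xd <- cbind(1, X)
  beta <- rep(0, ncol(Xd))
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(t(Xd * w) %*% Xd, t(Xd * w) %*% z))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# small two-group ratio cohort with one clean signal column
signal_ratio_fixture <- function(n_per_group = 10, n_noise = 8, seed = 42,
                                 shift = 2) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    y <- rep(0:1, each = n_per_group)
    m <- matrix(exp(rnorm(n * (n_noise + 1), 0, 0.5)), n, n_noise + 1)
    m[y == 1, 1] <- m[y == 1, 1] * shift
    colnames(m) <- c("sig", sprintf("noise%02d", seq_len(n_noise)))
    rownames(m) <- sprintf("S%02d", seq_len(n))
    list(X = m, y = y)
  })
}
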