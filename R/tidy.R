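# broom-style accessors and print methods.

#' Tidy a nested cross-validation fit
#'
#' Returns the per-sample held-out prediction records.
#'
#' @param x A `nested_cv` or `stavarsel_fit`.
#' @param ... Unused.
#' @return A tibble, one row per held-out sample.
#' @method tidy nested_cv
#' @export
tidy.nested_cv <- function(x, ...) x$records

#' @rdname tidy.nested_cv
#' @method tidy stavarsel_fit
#' @export
tidy.stavarsel_fit <- function(x, ...) x$records

#' One-row summary of a nested cross-validation fit
#'
#' @inheritParams tidy.nested_cv
#' @return A one-row tibble with the point classification summary, the
#'   averaged penalty and (for StaVarSel) the chosen model size.
#' @method glance nested_cv
#' @export
glance.nested_cv <- function(x, ...) {
  x$summary |> mutate(lambda = x$lambda, n_splits = nrow(x$records))
}

#' @rdname glance.nested_cv
#' @method glance stavarsel_fit
#' @export
glance.stavarsel_fit <- function(x, ...) {
  x$summary |>
    mutate(lambda = x$lambda, n_splits = nrow(x$records),
           chosen_k = x$chosen_k,
           final_features = paste(x$final_features, collapse = ","))
}

#' @export
print.nested_cv <- function(x, ...) {
  s <- x$summary
  cat("Standard nested cross-validation (LOOCV outer loop)\n")
  cat(sprintf("  samples: %d (neg %d / pos %d), averaged lambda: %.4g\n",
              nrow(x$records), s$n_negative, s$n_positive, x$lambda))
  cat(sprintf("  specificity %.3f, sensitivity %.3f, balanced accuracy %.3f\n",
              s$specificity, s$sensitivity, s$balanced_accuracy))
  invisible(x)
}

#' @export
print.stavarsel_fit <- function(x, ...) {
  s <- x$summary
  cat("StaVarSel stabilized nested cross-validation\n")
  cat(sprintf("  samples: %d, stable model size: %d\n",
              nrow(x$records), x$chosen_k))
  if (length(x$final_features) > 0) {
    cat("  stable ratios:", paste(x$final_features, collapse = ", "), "\n")
  }
  cat(sprintf("  specificity %.3f, sensitivity %.3f, balanced accuracy %.3f\n",
              s$specificity, s$sensitivity, s$balanced_accuracy))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d features\n",
              nrow(x$expression), ncol(x$expression) - 1))
  if (length(x$truth$informative_ratios) > 0) {
    cat("  informative ratios:",
        paste(x$truth$informative_ratios, collapse = ", "), "\n")
  }
  invisible(x)
}
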