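#' Build all pairwise expression-ratio features
#'
#' For every unordered pair of features (i, j) with i before j in column
#' order, the ratio feature `"i/j"` holds value_i / value_j per sample.
#' With p features this yields p(p-1)/2 ratio columns, all strictly
#' positive.
#'
#' @param expression Wide expression tibble with strictly positive values
#'   (run the QC zero-count filter first).
#' @return A wide tibble: `sample_id` plus one column per ratio.
#' @export
build_ratios <- function(expression) {
  m <- values_matrix(expression)
  zero_feat <- colnames(m)[apply(m, 2, function(v) any(v == 0))]
  if (length(zero_feat) > 0) {
    abort(paste0("Zero values in feature(s): ",
                 paste(zero_feat, collapse = ", "),
                 ". Remove them with filter_low_expression() before ",
                 "building ratios."),
          class = "stavarsel_ratio")
  }
  p <- ncol(m)
  if (p < 2) abort("Need at least two features.", class = "stavarsel_ratio")
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  r <- m[, pairs[, "row"], drop = FALSE] / m[, pairs[, "col"], drop = FALSE]
  colnames(r) <- paste0(colnames(m)[pairs[, "row"]], "/",
                        colnames(m)[pairs[, "col"]])
  matrix_tibble(r)
}

# Coefficient of variation (sample sd / mean) per column.
column_cv <- function(m) {
  apply(m, 2, sd) / colMeans(m)
}

#' Prefilter ratio features on a training set
#'
#' Two sequential filters computed on training samples only.  First, a
#' ratio is removed if its coefficient of variation (sd/mean) exceeds
#' `cv_threshold` within *both* comparison groups (high variation in only
#' one group is informative, not noise).  Second, a surviving ratio is
#' removed if its two-sided Mann-Whitney U p-value between the groups
#' exceeds `mwu_alpha_keep`.  Both removals use strict inequalities: a CV
#' exactly at the threshold or a p-value exactly at the threshold is
#' retained.
#'
#' @param ratio_values Numeric matrix (training samples x ratios) or a wide
#'   ratio tibble from [build_ratios()] restricted to training samples.
#' @param labels 0/1 vector (or two-level factor) of group membership.
#' @param params [prefilter_params()].
#' @return Character vector of retained ratio IDs, in input column order.
#' @export
prefilter_ratios <- function(ratio_values, labels,
                             params = prefilter_params()) {
  m <- if (is.matrix(ratio_values)) ratio_values else
    values_matrix(ratio_values)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(y) != nrow(m)) {
    abort("labels length must match the number of rows.",
          class = "stavarsel_ratio")
  }
  if (min(table(y)) < 2 || length(unique(y)) != 2) {
    abort("Each comparison group needs at least 2 training samples.",
          class = "stavarsel_ratio")
  }
  cv_a <- column_cv(m[y == 0, , drop = FALSE])
  cv_b <- column_cv(m[y == 1, , drop = FALSE])
  keep_cv <- !(cv_a > params$cv_threshold & cv_b > params$cv_threshold)
  survivors <- which(keep_cv)
  if (length(survivors) == 0) return(character(0))
  pvals <- mwu_pvalues(m[, survivors, drop = FALSE], y == 0)
  keep <- survivors[pvals <= params$mwu_alpha_keep]
  colnames(m)[keep]
}
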