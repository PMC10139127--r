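#' Read a normalized expression matrix
#'
#' Reads a delimited (TSV or CSV, chosen by file extension) expression table
#' of counts-per-million values into the wide sample-by-feature layout used
#' throughout the package: a tibble whose first column is `sample_id` and
#' whose remaining columns are features.  Expression tables are commonly
#' published with features in rows and samples in columns, so that is the
#' default orientation; it is a flag, not an inference, because source
#' layouts vary.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file with one
#'   header row and IDs in the first column.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @return A tibble with a `sample_id` column and one numeric column per
#'   feature, all values finite and non-negative.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  tbl <- read_delimited(path)
  if (nrow(tbl) == 0 || ncol(tbl) < 2) {
    abort(paste0("No expression values in ", path), class = "stavarsel_io")
  }
  ids <- as.character(tbl[[1]])
  m <- as.matrix(tbl[-1])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tbl[-1], is.numeric, logical(1)))[1]
    abort(paste0("Non-numeric expression column: ", names(tbl[-1])[bad]),
          class = "stavarsel_io")
  }
  rownames(m) <- ids
  if (orientation == "features_in_rows") m <- t(m)
  validate_expression_values(m)
  matrix_tibble(m)
}

read_delimited <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "stavarsel_io")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, name_repair = "minimal")
  if (anyDuplicated(names(tbl))) {
    abort(paste0("Duplicate column IDs in ", path, ": ",
                 paste(unique(names(tbl)[duplicated(names(tbl))]),
                       collapse = ", ")),
          class = "stavarsel_io")
  }
  tbl
}

validate_expression_values <- function(m) {
  if (anyDuplicated(rownames(m))) {
    abort(paste0("Duplicate sample IDs: ",
                 paste(unique(rownames(m)[duplicated(rownames(m))]),
                       collapse = ", ")),
          class = "stavarsel_io")
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("Duplicate feature IDs: ",
                 paste(unique(colnames(m)[duplicated(colnames(m))]),
                       collapse = ", ")),
          class = "stavarsel_io")
  }
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("Negative or non-finite expression value at sample '",
                 rownames(m)[bad[1, 1]], "', feature '",
                 colnames(m)[bad[1, 2]], "'."),
          class = "stavarsel_io")
  }
  invisible(m)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression_matrix()]; writes full-precision values so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param expression Wide expression tibble (`sample_id` first column).
#' @inheritParams read_expression_matrix
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(expression, path,
                                    orientation = c("features_in_rows",
                                                    "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- values_matrix(expression)
  if (orientation == "features_in_rows") {
    out <- tibble(feature_id = colnames(m)) |>
      dplyr::bind_cols(as_tibble(t(m)))
  } else {
    out <- matrix_tibble(m)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read sample metadata for a two-group comparison
#'
#' @param path Delimited file with `sample_id` and `group` columns.
#' @param comparison Character vector of the two group labels to analyse;
#'   the first is treated as the negative class, the second as the
#'   positive class.  Samples with other labels are dropped.
#' @return A tibble with `sample_id` and `group` (factor with the
#'   comparison labels as levels), input order preserved.
#' @export
read_sample_metadata <- function(path, comparison) {
  tbl <- read_delimited(path)
  if (!all(c("sample_id", "group") %in% names(tbl))) {
    abort("Metadata must have 'sample_id' and 'group' columns.",
          class = "stavarsel_io")
  }
  if (length(comparison) != 2 || comparison[1] == comparison[2]) {
    abort("`comparison` must name two distinct group labels.",
          class = "stavarsel_bad_comparison")
  }
  out <- tbl |>
    mutate(sample_id = as.character(.data$sample_id),
           group = as.character(.data$group)) |>
    filter(.data$group %in% comparison) |>
    mutate(group = factor(.data$group, levels = comparison)) |>
    select("sample_id", "group")
  if (anyDuplicated(out$sample_id)) {
    abort("Duplicate sample IDs in metadata.", class = "stavarsel_io")
  }
  as_tibble(out)
}

#' Check that every expression sample is annotated
#'
#' @param expression Wide expression tibble.
#' @param metadata Tibble from [read_sample_metadata()].
#' @return The expression tibble restricted (and reordered) to the metadata
#'   samples.
#' @export
align_samples <- function(expression, metadata) {
  missing <- setdiff(expression$sample_id, metadata$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples missing from metadata: ",
                 paste(missing, collapse = ", ")),
          class = "stavarsel_io")
  }
  keep <- metadata$sample_id[metadata$sample_id %in% expression$sample_id]
  expression[match(keep, expression$sample_id), , drop = FALSE]
}
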