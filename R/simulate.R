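#' Design a synthetic serum miRNA cohort
#'
#' Describes a two-group cohort of log-normal CPM profiles with a small
#' number of truly group-informative ratio pairs among noise features,
#' optional haemolysis-marker spiking and optional global outlier samples.
#' The generator emulates the statistical structure of TMM-normalized
#' small-RNA sequencing data after normalization: strictly positive CPM
#' values, feature abundances spread over orders of magnitude, group
#' effects expressible as expression ratios, and red-blood-cell marker
#' elevation under haemolysis.
#'
#' Defaults: per-feature baseline abundances are drawn once per feature
#' from a log-normal with median 100 CPM and log-sd 1.2 (abundances from a
#' few CPM to a few thousand), and per-sample noise has log-sd 0.6, i.e. a
#' per-feature coefficient of variation of about 66%, typical of circulating
#' miRNA cohorts.
#'
#' @param n_per_group Integer pair: samples in the negative and positive
#'   group.
#' @param n_features Number of miRNA-like features.
#' @param informative_pairs Data frame with columns `numerator`,
#'   `denominator` (feature indices) and `log2fc`: in the positive group the
#'   pair's ratio is shifted by a log2 fold-change of `log2fc`, split
#'   evenly between the numerator (up) and denominator (down), so the
#'   planted ratio itself is the most informative ratio.
#' @param base_log_mean,base_log_sd Mean and sd of per-feature baseline
#'   log-CPM.
#' @param noise_log_sd Within-feature, between-sample log-sd.
#' @param pair_coupling_log_sd Log-sd of the per-sample latent factor
#'   shared by the two members of each informative pair (co-regulation).
#'   The factor cancels in the pair's ratio but inflates the variance of
#'   every ratio pairing one member with an unrelated feature, which is
#'   what makes the *pair* -- rather than its individual members -- the
#'   truly informative unit.
#' @param haemolysis Optional list with `samples` (indices into the cohort),
#'   `factor` (multiplier, > 1) and optionally `markers` (feature indices,
#'   default the first three features).  Marker features are renamed to the
#'   canonical red-blood-cell miRNA IDs so the default QC marker list finds
#'   them.
#' @param outliers Optional list with `samples` and `factor`; multiplies a
#'   whole sample's profile.
#' @param seed Integer seed; the same design yields byte-identical cohorts.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(20L, 20L),
                          n_features = 30L,
                          informative_pairs = NULL,
                          base_log_mean = log(100),
                          base_log_sd = 1.2,
                          noise_log_sd = 0.6,
                          pair_coupling_log_sd = 1.0,
                          haemolysis = NULL,
                          outliers = NULL,
                          seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1),
            n_features >= 2, base_log_sd >= 0, noise_log_sd > 0,
            pair_coupling_log_sd >= 0)
  n <- sum(n_per_group)
  if (!is.null(informative_pairs)) {
    informative_pairs <- as_tibble(informative_pairs)
    stopifnot(all(c("numerator", "denominator", "log2fc") %in%
                    names(informative_pairs)))
    idx <- c(informative_pairs$numerator, informative_pairs$denominator)
    if (any(idx < 1 | idx > n_features)) {
      abort("Informative pair index out of range.", class = "stavarsel_design")
    }
    if (any(informative_pairs$numerator == informative_pairs$denominator)) {
      abort("A ratio pair must use two distinct features.",
            class = "stavarsel_design")
    }
    if (!all(is.finite(informative_pairs$log2fc))) {
      abort("Fold-changes must be finite.", class = "stavarsel_design")
    }
  }
  check_spike <- function(x, name, markers_ok = FALSE) {
    if (is.null(x)) return(NULL)
    stopifnot(is.list(x), all(c("samples", "factor") %in% names(x)))
    if (any(x$samples < 1 | x$samples > n)) {
      abort(paste0(name, " sample index out of range."),
            class = "stavarsel_design")
    }
    if (x$factor <= 0) {
      abort(paste0(name, " factor must be positive."),
            class = "stavarsel_design")
    }
    x
  }
  haemolysis <- check_spike(haemolysis, "haemolysis")
  outliers <- check_spike(outliers, "outliers")
  if (!is.null(haemolysis)) {
    haemolysis$markers <- haemolysis$markers %||% seq_len(min(3L, n_features))
    if (any(haemolysis$markers < 1 | haemolysis$markers > n_features)) {
      abort("Haemolysis marker index out of range.",
            class = "stavarsel_design")
    }
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_features = as.integer(n_features),
                 informative_pairs = informative_pairs,
                 base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd,
                 noise_log_sd = noise_log_sd,
                 pair_coupling_log_sd = pair_coupling_log_sd,
                 haemolysis = haemolysis,
                 outliers = outliers,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a synthetic cohort from a design
#'
#' @param design A [cohort_design()].
#' @return A list of class `cohort` with elements `expression` (wide tibble,
#'   `sample_id` first), `metadata` (`sample_id`, `group` with levels
#'   `"control"` then `"case"`), and `truth` (informative ratio IDs and the
#'   indices of spiked/outlier samples).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  withr::local_seed(design$seed)
  n <- sum(design$n_per_group)
  p <- design$n_features
  group <- factor(rep(c("control", "case"), design$n_per_group),
                  levels = c("control", "case"))
  feature_ids <- sprintf("mir-%03d", seq_len(p))
  markers <- design$haemolysis$markers
  if (!is.null(markers)) {
    canonical <- c("hsa-miR-451a", "hsa-miR-16-5p", "hsa-miR-486-5p")
    feature_ids[markers] <- canonical[seq_along(markers)]
  }
  base_mu <- rnorm(p, design$base_log_mean, design$base_log_sd)
  log_cpm <- matrix(rnorm(n * p, 0, design$noise_log_sd), n, p)
  log_cpm <- sweep(log_cpm, 2, base_mu, `+`)
  truth_ratios <- character(0)
  if (!is.null(design$informative_pairs)) {
    for (k in seq_len(nrow(design$informative_pairs))) {
      num <- design$informative_pairs$numerator[k]
      den <- design$informative_pairs$denominator[k]
      fc <- design$informative_pairs$log2fc[k]
      # the declared log2 fold-change applies to the pair's ratio and is
      # split evenly: numerator up, denominator down.  A per-sample
      # latent factor shared by both members (co-regulation) cancels in
      # the pair's ratio but adds variance to every other ratio touching
      # either member, so the planted pair is the truly informative
      # ratio, not a proxy of informative single features.
      u <- rnorm(n, 0, design$pair_coupling_log_sd)
      log_cpm[, num] <- log_cpm[, num] + u
      log_cpm[, den] <- log_cpm[, den] + u
      log_cpm[group == "case", num] <-
        log_cpm[group == "case", num] + fc / 2 * log(2)
      log_cpm[group == "case", den] <-
        log_cpm[group == "case", den] - fc / 2 * log(2)
      pair <- if (num < den) c(num, den) else c(den, num)
      truth_ratios <- c(truth_ratios,
                        paste0(feature_ids[pair[1]], "/", feature_ids[pair[2]]))
    }
  }
  cpm <- exp(log_cpm)
  if (!is.null(design$haemolysis)) {
    cpm[design$haemolysis$samples, markers] <-
      cpm[design$haemolysis$samples, markers] * design$haemolysis$factor
  }
  if (!is.null(design$outliers)) {
    cpm[design$outliers$samples, ] <-
      cpm[design$outliers$samples, ] * design$outliers$factor
  }
  sample_ids <- sprintf("S%03d", seq_len(n))
  rownames(cpm) <- sample_ids
  colnames(cpm) <- feature_ids
  structure(list(
    expression = matrix_tibble(cpm),
    metadata = tibble(sample_id = sample_ids, group = group),
    truth = list(informative_ratios = unique(truth_ratios),
                 haemolysed = design$haemolysis$samples,
                 outliers = design$outliers$samples,
                 design = design)
  ), class = "cohort")
}

#' The package's small worked-example cohort
#'
#' A fixed tiny cohort (12 + 12 samples, 15 features, two planted
#' informative ratio pairs with a log2 fold-change of 2) used by the
#' documentation and as a regression fixture.  Regenerating it always
#' yields the same values.
#'
#' @return A `cohort` list, see [generate_cohort()].
#' @export
worked_example_cohort <- function() {
  generate_cohort(cohort_design(
    n_per_group = c(12L, 12L),
    n_features = 15L,
    informative_pairs = tibble(numerator = c(4L, 9L),
                               denominator = c(5L, 11L),
                               log2fc = c(2, 2)),
    seed = 20230411L
  ))
}

#' A small, deliberately unstable cohort design
#'
#' The "unstable scenario" used when studying variance estimators: a small
#' cohort (8 + 8), many candidate features (50, i.e. 1225 candidate ratios)
#' and one weakly informative pair (log2 fold-change 1) under elevated
#' noise (log-sd 0.8).  Model selection on such cohorts is unstable, which
#' is the regime the conservative jackknife estimator targets.
#'
#' @param seed Integer seed.
#' @return A `cohort_design`.
#' @export
unstable_design <- function(seed = 1L) {
  cohort_design(
    n_per_group = c(8L, 8L),
    n_features = 50L,
    informative_pairs = tibble(numerator = 1L, denominator = 2L, log2fc = 1),
    noise_log_sd = 0.8,
    seed = seed
  )
}
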