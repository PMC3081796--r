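#' Candidate filter-cascade configuration
#'
#' Thresholds of the post-statistics filter cascade that turns a per-protein
#' comparison table into a candidate biomarker panel: the raw-p elevation
#' pre-filter, the significance level for Holm-Sidak adjusted p-values, the
#' minimum fold increase, and the minimum fraction of treated samples with
#' positive detection.
#'
#' @param alpha_prefilter Raw p-value cutoff for the elevation pre-filter.
#' @param alpha_adjusted Significance level on adjusted p-values.
#' @param min_fold Minimum normalized scan-count ratio (fold increase).
#' @param min_detection_fraction Minimum fraction of treated samples in which
#'   a candidate must be detected (inclusive: with six treated samples, 0.5
#'   means at least three).
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(alpha_prefilter = 0.05,
                           alpha_adjusted = 0.05,
                           min_fold = 2,
                           min_detection_fraction = 0.5) {
  for (f in c("alpha_prefilter", "alpha_adjusted", "min_detection_fraction")) {
    v <- get(f)
    if (!isTRUE(v > 0 && v <= 1)) abort_field(f, "must be in (0, 1]")
  }
  if (!isTRUE(min_fold >= 1)) abort_field("min_fold", "must be >= 1")
  structure(
    list(alpha_prefilter = alpha_prefilter, alpha_adjusted = alpha_adjusted,
         min_fold = min_fold, min_detection_fraction = min_detection_fraction),
    class = "cascade_config"
  )
}

#' Pre-filter comparisons to elevated proteins
#'
#' Retains proteins with raw p-value below `alpha_prefilter` that are either
#' detected in treated samples only (undefined ratio with a positive treated
#' count) or more abundant in the treated group (ratio > 1). The number of
#' retained rows is the family size for the subsequent Holm-Sidak adjustment
#' and is recorded as attribute `family_size`.
#'
#' @param comparisons Comparison tibble from [compare_groups()], one time
#'   point only.
#' @param config A [cascade_config()].
#' @return The retained comparison rows, with attribute `family_size`.
#' @export
prefilter_elevated <- function(comparisons, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  if (length(unique(comparisons$timepoint)) > 1) {
    stop("comparisons mix time points; pre-filter one time point at a time",
         call. = FALSE)
  }
  elevated <- (is.na(comparisons$ratio) & comparisons$x_t > 0) |
    (!is.na(comparisons$ratio) & comparisons$ratio > 1)
  keep <- comparisons$p_raw < config$alpha_prefilter & elevated
  out <- comparisons[keep, ]
  attr(out, "family_size") <- nrow(out)
  out
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down multiple-testing correction: p-values are ranked ascending; the
#' rank-i candidate (of m) is `1 - (1 - p_(i))^(m - i + 1)`; running maxima
#' enforce monotonicity; results are capped at 1 and returned in the input
#' order. A single p-value is returned unchanged.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.02, 0.03))
holm_sidak <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  # stable form of 1 - (1 - p)^k: keeps tiny p from collapsing to exact 0
  candidate <- -expm1((m - seq_len(m) + 1) * log1p(-p_sorted))
  adjusted_sorted <- pmin(cummax(candidate), 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adjusted_sorted
  adjusted
}

#' Apply the full candidate filter cascade
#'
#' Pipeline for one time point: elevation pre-filter on raw p-values,
#' Holm-Sidak adjustment over the retained family, then three final filters —
#' adjusted p below `alpha_adjusted`; normalized ratio at least `min_fold`
#' (proteins detected in treated samples only have no ratio and bypass the
#' fold rule); detection in at least `min_detection_fraction` of the treated
#' samples (inclusive). Output rows are sorted by descending ratio with
#' undefined-ratio rows last, ties broken by ascending adjusted p.
#'
#' @inheritParams prefilter_elevated
#' @param n_treated Number of treated samples at this time point.
#' @return Candidate tibble: `timepoint`, `protein_accession`, `detect_c`,
#'   `detect_t`, `ratio`, `p_adjusted` plus the pooled counts; attribute
#'   `family_size` carries the Holm-Sidak family size m.
#' @export
apply_cascade <- function(comparisons, config = cascade_config(), n_treated) {
  stopifnot(n_treated >= 1)
  family <- prefilter_elevated(comparisons, config)
  m <- attr(family, "family_size")
  if (nrow(family) == 0) {
    out <- dplyr::mutate(family, p_adjusted = numeric(0))
  } else {
    out <- dplyr::mutate(family, p_adjusted = holm_sidak(.data$p_raw))
  }
  out <- filter_candidates(out, config, n_treated)
  out <- out[order(-ifelse(is.na(out$ratio), -Inf, out$ratio), out$p_adjusted), ]
  out <- out[, c("timepoint", "protein_accession", "x_c", "x_t",
                 "detect_c", "detect_t", "ratio", "p_adjusted")]
  attr(out, "family_size") <- m
  out
}

#' Final three cascade filters on adjusted candidate rows
#'
#' The post-adjustment part of [apply_cascade()]: significance of the
#' adjusted p-value, the fold rule (bypassed for treated-only rows with
#' undefined ratio), and the treated-detection-frequency rule. Exposed
#' separately so panels that already carry adjusted p-values (published or
#' externally adjusted tables) can be checked against the same criteria.
#'
#' @param rows Tibble with columns `p_adjusted`, `ratio` (NA for
#'   treated-only rows) and `detect_t`.
#' @inheritParams apply_cascade
#' @return The rows passing all three filters.
#' @export
filter_candidates <- function(rows, config = cascade_config(), n_treated) {
  stopifnot(inherits(config, "cascade_config"), n_treated >= 1)
  min_detect <- ceiling(config$min_detection_fraction * n_treated)
  keep <- rows$p_adjusted < config$alpha_adjusted &
    (is.na(rows$ratio) | rows$ratio >= config$min_fold) &
    rows$detect_t >= min_detect
  rows[keep, ]
}

#' Cross time-point overlap of candidate panels
#'
#' Reports, for every pair of time points, the set of proteins present in
#' both candidate panels, plus the union of distinct proteins over all time
#' points.
#'
#' @param candidates Named list mapping time point to its candidate tibble
#'   (must contain `protein_accession`).
#' @return List with `pairs` (tibble: `timepoint_a`, `timepoint_b`,
#'   `n_common`, `proteins` list-column), `n_distinct` and `all_proteins`.
#' @export
cross_timepoint_overlap <- function(candidates) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  sets <- lapply(candidates, function(x) unique(x$protein_accession))
  tps <- names(sets)
  pairs <- if (length(tps) >= 2) utils::combn(tps, 2, simplify = FALSE) else list()
  pair_rows <- lapply(pairs, function(pr) {
    common <- sort(intersect(sets[[pr[1]]], sets[[pr[2]]]))
    tibble::tibble(timepoint_a = pr[1], timepoint_b = pr[2],
                   n_common = length(common), proteins = list(common))
  })
  all_proteins <- sort(unique(unlist(sets)))
  list(
    pairs = dplyr::bind_rows(pair_rows),
    n_distinct = length(all_proteins),
    all_proteins = all_proteins
  )
}
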