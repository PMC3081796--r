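#' Pool spectral counts by group at one time point
#'
#' For every protein in the matrix, sums counts over the control and treated
#' samples at the given time point (`x_c`, `x_t`), records the corresponding
#' grand total scan counts over all proteins (`T_c`, `T_t`), and counts the
#' samples in which the protein was detected (count > 0).
#'
#' @param matrix A `count_matrix` from [build_count_matrix()].
#' @param timepoint One of the design's time points.
#' @return Tibble with one row per protein: `protein_accession`, `x_c`,
#'   `x_t`, `T_c`, `T_t`, `detect_c`, `detect_t`.
#' @export
pooled_group_counts <- function(matrix, timepoint) {
  stopifnot(inherits(matrix, "count_matrix"))
  at_tp <- matrix$design$timepoint == timepoint
  if (!any(at_tp)) {
    stop("time point not present in design: ", timepoint, call. = FALSE)
  }
  ctrl <- at_tp & matrix$design$group == "control"
  trt <- at_tp & matrix$design$group == "treated"
  if (!any(ctrl) || !any(trt)) {
    stop("need at least one control and one treated sample at ", timepoint,
         call. = FALSE)
  }
  m <- matrix$counts
  tibble::tibble(
    protein_accession = rownames(m),
    x_c = as.integer(rowSums(m[, ctrl, drop = FALSE])),
    x_t = as.integer(rowSums(m[, trt, drop = FALSE])),
    T_c = sum(matrix$totals[ctrl]),
    T_t = sum(matrix$totals[trt]),
    detect_c = as.integer(rowSums(m[, ctrl, drop = FALSE] > 0)),
    detect_t = as.integer(rowSums(m[, trt, drop = FALSE] > 0))
  )
}

#' Normalized scan-count ratio (treated/control)
#'
#' Each group's pooled protein count is scaled by that group's total scan
#' count before taking the ratio: `(x_t / T_t) / (x_c / T_c)`. When the
#' pooled control count is zero the ratio is undefined (the protein was
#' detected in treated samples only) and `NA` is returned; report writers
#' render it as `"-"`.
#'
#' @param x_c,x_t Pooled control/treated spectral counts (non-negative).
#' @param T_c,T_t Total scan counts per group (positive).
#' @return Numeric vector of ratios, `NA` where `x_c == 0`.
#' @export
#' @examples
#' normalized_ratio(2, 8, 2000, 1000) # 8
normalized_ratio <- function(x_c, x_t, T_c, T_t) {
  if (any(c(x_c, x_t) < 0)) stop("negative counts", call. = FALSE)
  if (any(c(T_c, T_t) <= 0)) stop("group totals must be positive", call. = FALSE)
  ifelse(x_c > 0, (x_t / T_t) / (x_c / T_c), NA_real_)
}

#' G-test for a pooled two-group spectral-count comparison
#'
#' Likelihood-ratio goodness-of-fit test of a protein's pooled counts
#' against the expectation that the protein occupies the same proportion of
#' each group's total scans:
#' \deqn{G = 2\left[x_c \ln(x_c/\hat e_c) + x_t \ln(x_t/\hat e_t)\right],}
#' with \eqn{\hat e_c = T_c (x_c + x_t)/(T_c + T_t)} and \eqn{\hat e_t}
#' analogous — the total-scan-normalized expected counts. The p-value is the
#' upper chi-square tail with one degree of freedom.
#'
#' When either observed count is zero, 0.5 is added to both counts and to
#' both totals for the G computation only (the reported ratio keeps its
#' undefined marker), so the log terms stay finite. Reported p-values are
#' floored at 1e-300: a printed zero would be floating-point underflow, not
#' an exact zero.
#'
#' @inheritParams normalized_ratio
#' @return Tibble with columns `G` and `p_raw` (vectorized over inputs).
#' @export
g_test <- function(x_c, x_t, T_c, T_t) {
  n <- max(length(x_c), length(x_t), length(T_c), length(T_t))
  x_c <- rep_len(x_c, n); x_t <- rep_len(x_t, n)
  T_c <- rep_len(T_c, n); T_t <- rep_len(T_t, n)
  if (any(c(x_c, x_t) < 0)) stop("negative counts", call. = FALSE)
  if (any(c(T_c, T_t) <= 0)) stop("group totals must be positive", call. = FALSE)
  if (any(x_c + x_t == 0)) {
    stop("protein absent from both groups: G-test undefined", call. = FALSE)
  }
  zero <- x_c == 0 | x_t == 0
  xc <- x_c + 0.5 * zero
  xt <- x_t + 0.5 * zero
  Tc <- T_c + 0.5 * zero
  Tt <- T_t + 0.5 * zero
  e_c <- Tc * (xc + xt) / (Tc + Tt)
  e_t <- Tt * (xc + xt) / (Tc + Tt)
  G <- 2 * (xc * log(xc / e_c) + xt * log(xt / e_t))
  G <- pmax(G, 0) # guard tiny negative rounding at the null
  p <- pmax(pchisq(G, df = 1, lower.tail = FALSE), 1e-300)
  tibble::tibble(G = G, p_raw = p)
}

#' Compare treated vs control spectral counts at one time point
#'
#' Full per-protein comparison table: pooled counts, normalized scan-count
#' ratio, G statistic, raw chi-square p-value and per-sample detection
#' counts. Proteins absent from every sample at the time point are dropped.
#'
#' @inheritParams pooled_group_counts
#' @return Tibble of per-protein comparisons with columns
#'   `protein_accession`, `timepoint`, `x_c`, `x_t`, `T_c`, `T_t`, `ratio`,
#'   `G`, `p_raw`, `detect_c`, `detect_t`.
#' @export
compare_groups <- function(matrix, timepoint) {
  pooled <- pooled_group_counts(matrix, timepoint)
  pooled <- pooled[pooled$x_c + pooled$x_t > 0, ]
  if (nrow(pooled) == 0) {
    stop("no protein detected at time point ", timepoint, call. = FALSE)
  }
  gt <- g_test(pooled$x_c, pooled$x_t, pooled$T_c, pooled$T_t)
  dplyr::mutate(
    pooled,
    timepoint = timepoint,
    ratio = normalized_ratio(.data$x_c, .data$x_t, .data$T_c, .data$T_t),
    G = gt$G,
    p_raw = gt$p_raw,
    .after = "protein_accession"
  )[, c("protein_accession", "timepoint", "x_c", "x_t", "T_c", "T_t",
        "ratio", "G", "p_raw", "detect_c", "detect_t")]
}

#' Write a comparison table as TSV
#'
#' Ratios are printed to four decimals with undefined ratios rendered `"-"`;
#' G to four decimals; p-values in scientific notation.
#'
#' @param comparisons Tibble from [compare_groups()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparisons, path) {
  out <- dplyr::mutate(
    comparisons,
    ratio = ifelse(is.na(.data$ratio), "-", sprintf("%.4f", .data$ratio)),
    G = sprintf("%.4f", .data$G),
    p_raw = sprintf("%.4e", .data$p_raw)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  readr::read_tsv(path, na = c("", "NA", "-"), col_types = readr::cols(
    protein_accession = "c", timepoint = "c", x_c = "i", x_t = "i",
    T_c = "d", T_t = "d", ratio = "d", G = "d", p_raw = "d",
    detect_c = "i", detect_t = "i"
  ))
}
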