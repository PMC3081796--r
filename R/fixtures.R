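#' Packaged reference data from a primate retinal-laser-injury serum study
#'
#' Plain-text transcriptions of the published result tables of a
#' paired-control primate study of serum biomarkers after mild retinal laser
#' injury, shipped so the filter cascade, overlap and GO-tally stages can be
#' checked against known output:
#'
#' * `retinal_panel()` — the final candidate biomarker panel (23 rows over
#'   the 4 h, 1 day and 3 day time points; 19 distinct proteins), with
#'   detection counts, normalized scan-count ratios (`NA` for proteins
#'   detected in treated samples only) and Holm-Sidak adjusted p-values.
#' * `retinal_go_map()` — the GO annotation of the 19 panel proteins: one
#'   biological-process and one cellular-component term each.
#' * `retinal_timepoint_totals()` — total proteins identified per time
#'   point (818, 928, 978).
#'
#' @return Tibbles; see the individual descriptions.
#' @name retinal_fixtures
NULL

seromark_extdata <- function(file) {
  path <- system.file("extdata", file, package = "seromark")
  if (path == "") stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' @rdname retinal_fixtures
#' @export
retinal_panel <- function() {
  read_candidate_panel(seromark_extdata("retinal_injury_panel.tsv"))
}

#' @rdname retinal_fixtures
#' @export
retinal_go_map <- function() {
  read_go_map(seromark_extdata("retinal_injury_go_terms.tsv"))
}

#' @rdname retinal_fixtures
#' @export
retinal_timepoint_totals <- function() {
  readr::read_tsv(seromark_extdata("timepoint_protein_totals.tsv"),
                  col_types = readr::cols(timepoint = "c", n_proteins = "i"))
}

#' Read or write a candidate panel TSV
#'
#' Candidate panels are TSV with an undefined-ratio marker `"-"` (treated-only
#' proteins) parsed to `NA`; adjusted p-values may be in scientific notation.
#'
#' @param path File path.
#' @param panel Candidate tibble with at least `timepoint`,
#'   `protein_accession`, `detect_c`, `detect_t`, `ratio`, `p_adjusted`.
#' @return `read_candidate_panel()` returns the panel tibble;
#'   `write_candidate_panel()` returns `path` invisibly.
#' @export
read_candidate_panel <- function(path) {
  readr::read_tsv(path, na = c("", "NA", "-"),
                  col_types = readr::cols(
                    timepoint = "c", protein_accession = "c",
                    detect_c = "i", detect_t = "i",
                    ratio = "d", p_adjusted = "d",
                    .default = "c"
                  ))
}

#' @rdname read_candidate_panel
#' @export
write_candidate_panel <- function(panel, path) {
  out <- dplyr::mutate(
    panel,
    ratio = ifelse(is.na(.data$ratio), "-", sprintf("%.4f", .data$ratio)),
    p_adjusted = sprintf("%.6g", .data$p_adjusted)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
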