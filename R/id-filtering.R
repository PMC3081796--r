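#' Identification filter thresholds
#'
#' Probability and peptide-count thresholds applied to PSM-level
#' identifications before quantification. Defaults are the conventional
#' stringent settings for probability-scored serum identifications: spectrum
#' probability >= 0.85, protein probability >= 0.60, and the two-peptide rule
#' (a protein is accepted in a sample only if identified by at least two
#' distinct peptide sequences there). Comparisons are inclusive, so the
#' stated thresholds are themselves attainable values.
#'
#' @param spectrum_probability_min Minimum spectrum-level probability.
#' @param protein_probability_min Minimum protein-level probability.
#' @param min_unique_peptides Minimum distinct peptide sequences per protein
#'   per sample (after fraction merging).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(spectrum_probability_min = 0.85,
                              protein_probability_min = 0.60,
                              min_unique_peptides = 2L) {
  if (!isTRUE(spectrum_probability_min >= 0 && spectrum_probability_min <= 1))
    abort_field("spectrum_probability_min", "must be in [0, 1]")
  if (!isTRUE(protein_probability_min >= 0 && protein_probability_min <= 1))
    abort_field("protein_probability_min", "must be in [0, 1]")
  if (!isTRUE(min_unique_peptides >= 1))
    abort_field("min_unique_peptides", "must be >= 1")
  structure(
    list(
      spectrum_probability_min = spectrum_probability_min,
      protein_probability_min = protein_probability_min,
      min_unique_peptides = as.integer(min_unique_peptides)
    ),
    class = "filter_thresholds"
  )
}

#' Filter PSMs on identification probability scores
#'
#' Retains records whose spectrum and protein probabilities are both at or
#' above their thresholds (inclusive). Row order is preserved. Filtering is
#' idempotent.
#'
#' @param psms PSM tibble (see [generate_study()] for the columns).
#' @param thresholds A [filter_thresholds()].
#' @return The retained PSM rows.
#' @export
filter_psms <- function(psms, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  for (col in c("spectrum_probability", "protein_probability")) {
    if (!col %in% names(psms)) abort_field(col, "column missing from PSM table")
    bad <- which(is.na(psms[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("missing %s for record(s): %s", col,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  keep <- psms$spectrum_probability >= thresholds$spectrum_probability_min &
    psms$protein_probability >= thresholds$protein_probability_min
  psms[keep, ]
}

#' Merge IEF fractions and apply the two-peptide rule
#'
#' Pools a sample's PSMs over all of its IEF fractions, then summarises each
#' (sample, protein) pair: `spectral_count` is the number of PSMs and
#' `unique_peptide_count` the number of distinct peptide sequences, both over
#' the merged fractions. Proteins identified by fewer than
#' `min_unique_peptides` distinct peptides within a sample are dropped from
#' that sample. Input is expected to be probability-filtered already
#' ([filter_psms()]); this function does not re-apply those thresholds.
#'
#' @inheritParams filter_psms
#' @return Tibble of protein hits: `sample_id`, `protein_accession`,
#'   `unique_peptide_count`, `spectral_count`.
#' @export
assemble_protein_hits <- function(psms, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  hits <- psms |>
    dplyr::group_by(.data$sample_id, .data$protein_accession) |>
    dplyr::summarise(
      unique_peptide_count = dplyr::n_distinct(.data$peptide_sequence),
      spectral_count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$unique_peptide_count >= thresholds$min_unique_peptides)
  hits
}

new_count_matrix <- function(counts, design) {
  stopifnot(is.matrix(counts), is.data.frame(design),
            identical(colnames(counts), design$sample_id))
  structure(
    list(
      counts = counts,
      design = tibble::as_tibble(design),
      totals = colSums(counts)
    ),
    class = "count_matrix"
  )
}

#' Build a per-sample protein spectral-count matrix
#'
#' Assembles filtered protein hits into a proteins x samples count matrix
#' with the study design attached. Proteins absent from a sample are encoded
#' as zero counts; per-sample totals are the column sums.
#'
#' @param hits Protein-hit tibble from [assemble_protein_hits()].
#' @param design Sample metadata tibble with columns `sample_id`,
#'   `animal_id`, `group` (`control`/`treated`), `timepoint`. Every
#'   `sample_id` in `hits` must appear here; design samples with no hits
#'   become all-zero columns.
#' @return A `count_matrix`: list with `counts` (integer matrix), `design`
#'   and `totals`.
#' @export
build_count_matrix <- function(hits, design) {
  stopifnot(all(c("sample_id", "group", "timepoint") %in% names(design)))
  unknown <- setdiff(unique(hits$sample_id), design$sample_id)
  if (length(unknown) > 0) {
    stop("unknown sample_id in hits: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(hits[, c("sample_id", "protein_accession")]) > 0) {
    stop("duplicate (sample, protein) rows in hits; merge fractions upstream",
         call. = FALSE)
  }
  proteins <- sort(unique(hits$protein_accession))
  counts <- matrix(0L, nrow = length(proteins), ncol = nrow(design),
                   dimnames = list(proteins, design$sample_id))
  if (nrow(hits) > 0) {
    counts[cbind(match(hits$protein_accession, proteins),
                 match(hits$sample_id, design$sample_id))] <-
      as.integer(hits$spectral_count)
  }
  new_count_matrix(counts, design)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d proteins x %d samples (%d control, %d treated)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$design$group == "control"), sum(x$design$group == "treated")))
  cat("time points:", paste(unique(x$design$timepoint), collapse = ", "), "\n")
  invisible(x)
}

#' Write or read a count matrix as TSV
#'
#' Writes two files: `<path>` with proteins as rows and samples as columns
#' (first column `protein_accession`), and `<path>.design.tsv` with the
#' sample metadata.
#'
#' @param x A `count_matrix`.
#' @param path Counts file path.
#' @return `read_count_matrix()` returns the `count_matrix`;
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  wide <- tibble::as_tibble(x$counts, rownames = "protein_accession")
  readr::write_tsv(wide, path)
  readr::write_tsv(x$design, paste0(path, ".design.tsv"))
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    protein_accession = "c", .default = "i"))
  design <- readr::read_tsv(paste0(path, ".design.tsv"), col_types = readr::cols(
    .default = "c"))
  counts <- as.matrix(wide[-1])
  rownames(counts) <- wide$protein_accession
  new_count_matrix(counts, design)
}
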