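#' Read a protein-to-GO annotation mapping
#'
#' The mapping is flat, one row per protein: the protein's accession, its
#' human homolog gene identifier, one biological-process GO term and one
#' cellular-component GO term (identifier plus label). No ontology-graph
#' propagation is performed; tallies count these terms as given.
#'
#' @param path TSV file with columns `protein_accession`,
#'   `human_homolog_gene_id`, `process_go`, `process_label`, `component_go`,
#'   `component_label`.
#' @return Tibble of annotation rows.
#' @export
read_go_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("protein_accession", "human_homolog_gene_id",
            "process_go", "process_label", "component_go", "component_label")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols) > 0) {
    stop("GO map missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !grepl("^GO:[0-9]{7}$", map$process_go) |
    !grepl("^GO:[0-9]{7}$", map$component_go)
  if (any(bad)) {
    stop("malformed GO identifier(s) in rows: ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  map[, need]
}

#' Annotate a candidate panel with GO terms
#'
#' Joins each distinct panel protein to its GO annotation row. Proteins
#' absent from the mapping are kept with empty terms, flagged in the
#' `mapped` column, and reported in a warning.
#'
#' @param panel Candidate tibble (needs `protein_accession`).
#' @param go_map Annotation tibble from [read_go_map()].
#' @return Annotated tibble, one row per distinct panel protein.
#' @export
annotate_panel <- function(panel, go_map) {
  dup <- unique(go_map$protein_accession[duplicated(go_map$protein_accession)])
  if (length(dup) > 0) {
    stop("duplicate GO mapping rows for: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  proteins <- tibble::tibble(protein_accession = unique(panel$protein_accession))
  out <- dplyr::left_join(proteins, go_map, by = "protein_accession")
  out$mapped <- !is.na(out$process_go)
  if (any(!out$mapped)) {
    warning("unmapped panel protein(s): ",
            paste(out$protein_accession[!out$mapped], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' GO term frequencies over an annotated panel
#'
#' Counts, over distinct mapped proteins, how many carry each term in the
#' requested category. Rows are ordered by descending count, ties by GO
#' identifier.
#'
#' @param annotated Tibble from [annotate_panel()].
#' @param category `"component"` or `"process"`.
#' @return Tibble with `go_id`, `label`, `count`.
#' @export
term_frequencies <- function(annotated, category = c("component", "process")) {
  category <- match.arg(category)
  id_col <- paste0(category, "_go")
  label_col <- paste0(category, "_label")
  mapped <- annotated[annotated$mapped, ]
  if (nrow(mapped) == 0) {
    return(tibble::tibble(go_id = character(0), label = character(0),
                          count = integer(0)))
  }
  freq <- mapped |>
    dplyr::count(go_id = .data[[id_col]], label = .data[[label_col]],
                 name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$go_id)
  freq
}

#' Defining GO terms of a panel
#'
#' The term(s) shared by the greatest number of panel proteins, per category;
#' all tied maxima are returned.
#'
#' @inheritParams term_frequencies
#' @return List with `component` and `process`, each a tibble of the
#'   maximal-count terms.
#' @export
defining_terms <- function(annotated) {
  pick_max <- function(freq) {
    if (nrow(freq) == 0) return(freq)
    freq[freq$count == max(freq$count), ]
  }
  list(
    component = pick_max(term_frequencies(annotated, "component")),
    process = pick_max(term_frequencies(annotated, "process"))
  )
}
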