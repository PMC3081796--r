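#' Mean and spread of per-time-point identification totals
#'
#' Summarises how many proteins were identified at each time point as
#' `mean ± sd`, using the sample (n-1) standard deviation, each rounded
#' half-up to an integer.
#'
#' @param totals Integer vector of per-time-point protein totals (>= 2
#'   values, or the standard deviation is undefined).
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
#' @examples
#' summarize_totals(c(818, 928, 978)) # 908, 82
summarize_totals <- function(totals) {
  if (length(totals) < 2) {
    stop("need at least two totals; sd is undefined for fewer", call. = FALSE)
  }
  c(mean = round_half_up(mean(totals)), sd = round_half_up(sd(totals)))
}

default_pipeline_config <- function() {
  list(
    simulate = list(
      n_animals = 6L, n_timepoints = 3L, n_fractions = 10L,
      n_proteins = 900L, mean_total_scans_per_sample = 5000,
      abundance_dispersion = 2.5, decoy_fraction = 0.05,
      spike_set = NULL, seed = 1L
    ),
    psm_table = NULL,
    go_map = NULL,
    thresholds = list(
      spectrum_probability_min = 0.85,
      protein_probability_min = 0.60,
      min_unique_peptides = 2L
    ),
    cascade = list(
      alpha_prefilter = 0.05, alpha_adjusted = 0.05,
      min_fold = 2, min_detection_fraction = 0.5
    )
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("stage config: file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  utils::modifyList(default_pipeline_config(), config)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

spike_set_from_config <- function(spikes) {
  if (is.null(spikes) || length(spikes) == 0) return(NULL)
  if (is.data.frame(spikes)) return(spikes)
  dplyr::bind_rows(lapply(spikes, tibble::as_tibble))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate (unless a PSM table is supplied) -> probability filter
#' and fraction merge -> per-time-point group comparison -> candidate
#' cascade -> cross-time-point overlap -> optional GO tally, writing every
#' stage's table plus a run manifest to `out_dir`. Identical config and seed
#' give byte-identical outputs (the manifest carries no timestamps).
#'
#' @param config Path to a YAML config, or an equivalent nested list. Keys
#'   (all optional, with stringent defaults): `simulate` (arguments of
#'   [study_config()]), `psm_table` (path to an existing PSM TSV; skips
#'   simulation), `go_map` (path to a GO annotation TSV), `thresholds`
#'   (arguments of [filter_thresholds()]), `cascade` (arguments of
#'   [cascade_config()]).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional integer overriding the config's simulation seed.
#' @param timepoints Time points to analyse, or `"all"`.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, timepoints = "all") {
  cfg <- stage_try("config", read_pipeline_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_digests <- list()

  psms <- if (!is.null(cfg$psm_table)) {
    stage_try("input", {
      if (!file.exists(cfg$psm_table)) {
        stop("PSM table not found: ", cfg$psm_table)
      }
      read_psm_table(cfg$psm_table)
    })
  } else {
    stage_try("simulate", {
      sim <- cfg$simulate
      if (!is.null(seed)) sim$seed <- as.integer(seed)
      sim$spike_set <- spike_set_from_config(sim$spike_set)
      scfg <- do.call(study_config, sim)
      psms <- generate_study(scfg)
      write_psm_table(psms, file.path(out_dir, "psms.tsv"), seed = scfg$seed)
      psms
    })
  }
  if (!is.null(cfg$psm_table)) {
    input_digests[[cfg$psm_table]] <- unname(tools::md5sum(cfg$psm_table))
  }

  design <- dplyr::distinct(psms[, c("sample_id", "animal_id", "group", "timepoint")])
  thresholds <- stage_try("filter", do.call(filter_thresholds, cfg$thresholds))
  matrix <- stage_try("filter", {
    kept <- filter_psms(psms, thresholds)
    hits <- assemble_protein_hits(kept, thresholds)
    m <- build_count_matrix(hits, design)
    write_count_matrix(m, file.path(out_dir, "count_matrix.tsv"))
    m
  })

  tps <- unique(design$timepoint)
  if (!identical(timepoints, "all")) tps <- intersect(tps, timepoints)
  if (length(tps) == 0) stop("stage compare: no requested time point in design",
                             call. = FALSE)

  cascade <- stage_try("cascade", do.call(cascade_config, cfg$cascade))
  comparisons <- list()
  candidates <- list()
  family_sizes <- integer()
  for (tp in tps) {
    comp <- stage_try("compare", compare_groups(matrix, tp))
    write_comparison(comp, file.path(out_dir, sprintf("comparison_%s.tsv", tp)))
    n_treated <- sum(design$group == "treated" & design$timepoint == tp)
    cand <- stage_try("cascade", apply_cascade(comp, cascade, n_treated))
    write_candidate_panel(cand, file.path(out_dir, sprintf("candidates_%s.tsv", tp)))
    comparisons[[tp]] <- comp
    candidates[[tp]] <- cand
    family_sizes[[tp]] <- attr(cand, "family_size")
  }

  overlap <- stage_try("overlap", cross_timepoint_overlap(candidates))
  if (nrow(overlap$pairs) > 0) {
    readr::write_tsv(
      dplyr::mutate(overlap$pairs,
                    proteins = vapply(.data$proteins, paste, "", collapse = ",")),
      file.path(out_dir, "overlap.tsv"))
  }

  go <- NULL
  if (!is.null(cfg$go_map)) {
    go <- stage_try("go", {
      if (!file.exists(cfg$go_map)) stop("GO map not found: ", cfg$go_map)
      input_digests[[cfg$go_map]] <- unname(tools::md5sum(cfg$go_map))
      go_map <- read_go_map(cfg$go_map)
      all_cand <- dplyr::bind_rows(candidates)
      annotated <- annotate_panel(all_cand, go_map)
      readr::write_tsv(annotated, file.path(out_dir, "go_annotation.tsv"))
      readr::write_tsv(term_frequencies(annotated, "component"),
                       file.path(out_dir, "go_component_frequencies.tsv"))
      readr::write_tsv(term_frequencies(annotated, "process"),
                       file.path(out_dir, "go_process_frequencies.tsv"))
      annotated
    })
  }

  detected <- vapply(comparisons, nrow, integer(1))
  manifest <- list(
    config = cfg,
    seed = if (!is.null(seed)) as.integer(seed) else cfg$simulate$seed,
    input_digests = input_digests,
    proteins_detected = as.list(detected),
    detection_summary = if (length(detected) >= 2) {
      as.list(summarize_totals(detected))
    } else NULL,
    family_sizes = as.list(family_sizes),
    candidates_retained = lapply(candidates, nrow),
    distinct_candidate_proteins = overlap$n_distinct,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Bar chart of group mean normalized scan counts for selected proteins
#'
#' Mean per-sample spectral count (scaled per 1000 total scans of its
#' sample) with standard-error bars, by group and time point — the usual
#' way candidate panels are displayed.
#'
#' @param matrix A `count_matrix`.
#' @param proteins Accessions to plot.
#' @return A ggplot object.
#' @export
plot_group_counts <- function(matrix, proteins) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_group_counts() needs the ggplot2 package", call. = FALSE)
  }
  stopifnot(inherits(matrix, "count_matrix"))
  proteins <- intersect(proteins, rownames(matrix$counts))
  long <- tibble::as_tibble(matrix$counts[proteins, , drop = FALSE],
                            rownames = "protein_accession") |>
    tidyr::pivot_longer(-"protein_accession", names_to = "sample_id",
                        values_to = "count") |>
    dplyr::left_join(matrix$design, by = "sample_id") |>
    dplyr::mutate(norm = .data$count / matrix$totals[.data$sample_id] * 1000) |>
    dplyr::group_by(.data$protein_accession, .data$group, .data$timepoint) |>
    dplyr::summarise(mean = mean(.data$norm),
                     sem = sd(.data$norm) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~protein_accession, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized scans per 1000 (mean ± SEM)")
}
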