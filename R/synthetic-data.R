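#' Configure a synthetic paired-control serum study
#'
#' Builds the parameter set for the peptide-spectrum-match (PSM) simulator.
#' The defaults emulate the design of a paired-control primate serum study:
#' six animals, each serving as its own control, sampled at three time points
#' (4 h, 1 day, 3 days) after a mock and a treatment procedure, with each
#' serum sample pre-fractionated into ten isoelectric-focusing (IEF)
#' fractions before LC-MS/MS.
#'
#' Protein abundances are drawn log-normal so that relative concentrations
#' span several orders of magnitude, as serum proteomes do. Per-sample
#' spectral counts for each protein are Poisson with rate proportional to
#' abundance times the protein's peptide count, scaled to the sample's mean
#' total scan count. Treatment effects are injected through `spike_set`:
#' a spiked protein has its treated-group Poisson rate multiplied by
#' `fold` at the spiked time point; a `treated_only` spike additionally
#' zeroes the control rate, producing proteins detected in treated samples
#' only (undefined abundance ratio downstream).
#'
#' @param n_animals Number of animals; each contributes one control and one
#'   treated sample per time point.
#' @param n_timepoints Number of time points used (a prefix of `4h`, `1d`,
#'   `3d`).
#' @param n_fractions Number of IEF fractions per sample.
#' @param n_proteins Number of true serum proteins simulated.
#' @param mean_total_scans_per_sample Expected number of true PSMs per sample.
#' @param abundance_dispersion Standard deviation of log protein abundance
#'   (natural log scale); 2.5 spans roughly 4-5 orders of magnitude across
#'   the central 95% of proteins.
#' @param spike_set Data frame of treatment effects with columns `protein`
#'   (integer index in `1:n_proteins`), `timepoint` (one of the study time
#'   points), `fold` (rate multiplier, >= 1), `treated_only` (logical).
#'   `NULL` means a null study.
#' @param peptides_per_protein List with `min` and `lambda`: a protein's
#'   unique-peptide count is `min + Poisson(lambda)`.
#' @param probability_noise List of Beta shape pairs for the identification
#'   probability scores: `spectrum_true`, `spectrum_decoy`, `protein_true`,
#'   `protein_decoy`. True identifications draw from the high modes, decoys
#'   from the low modes, so probability thresholds separate them imperfectly.
#' @param decoy_fraction Expected fraction of PSMs that are decoy (false)
#'   identifications, in `[0, 1)`.
#' @param seed Integer seed; a fixed seed makes [generate_study()] output
#'   byte-identical.
#'
#' @return A `study_config` list, validated.
#' @export
#' @examples
#' cfg <- study_config(n_proteins = 50, mean_total_scans_per_sample = 500)
#' psms <- generate_study(cfg)
#' dplyr::count(psms, sample_id)
study_config <- function(n_animals = 6L,
                         n_timepoints = 3L,
                         n_fractions = 10L,
                         n_proteins = 900L,
                         mean_total_scans_per_sample = 5000,
                         abundance_dispersion = 2.5,
                         spike_set = NULL,
                         peptides_per_protein = list(min = 2L, lambda = 4),
                         probability_noise = list(
                           spectrum_true = c(18, 2),
                           spectrum_decoy = c(4, 6),
                           protein_true = c(12, 3),
                           protein_decoy = c(3, 5)
                         ),
                         decoy_fraction = 0.05,
                         seed = 1L) {
  cfg <- structure(
    list(
      n_animals = as.integer(n_animals),
      n_timepoints = as.integer(n_timepoints),
      n_fractions = as.integer(n_fractions),
      n_proteins = as.integer(n_proteins),
      mean_total_scans_per_sample = as.numeric(mean_total_scans_per_sample),
      abundance_dispersion = as.numeric(abundance_dispersion),
      spike_set = spike_set,
      peptides_per_protein = peptides_per_protein,
      probability_noise = probability_noise,
      decoy_fraction = as.numeric(decoy_fraction),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  for (f in c("n_animals", "n_timepoints", "n_fractions")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      abort_field(f, "must be a count >= 1")
  }
  if (cfg$n_timepoints > length(TIMEPOINT_LEVELS))
    abort_field("n_timepoints", sprintf("at most %d supported", length(TIMEPOINT_LEVELS)))
  if (is.na(cfg$n_proteins) || cfg$n_proteins < 0L)
    abort_field("n_proteins", "must be a count >= 0")
  if (!isTRUE(cfg$mean_total_scans_per_sample > 0))
    abort_field("mean_total_scans_per_sample", "must be > 0")
  if (!isTRUE(cfg$abundance_dispersion > 0))
    abort_field("abundance_dispersion", "must be > 0")
  if (!isTRUE(cfg$decoy_fraction >= 0 && cfg$decoy_fraction < 1))
    abort_field("decoy_fraction", "must be in [0, 1)")
  pp <- cfg$peptides_per_protein
  if (!is.list(pp) || is.null(pp$min) || is.null(pp$lambda) ||
      pp$min < 1 || pp$lambda < 0)
    abort_field("peptides_per_protein", "needs `min` >= 1 and `lambda` >= 0")
  pn <- cfg$probability_noise
  need <- c("spectrum_true", "spectrum_decoy", "protein_true", "protein_decoy")
  if (!is.list(pn) || !all(need %in% names(pn)) ||
      !all(vapply(pn[need], function(x) length(x) == 2L && all(x > 0), logical(1))))
    abort_field("probability_noise", "needs four positive Beta shape pairs")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    abort_field("seed", "must be a single integer")
  if (!is.null(cfg$spike_set)) {
    ss <- cfg$spike_set
    need <- c("protein", "timepoint", "fold", "treated_only")
    if (!is.data.frame(ss) || !all(need %in% names(ss)))
      abort_field("spike_set", "needs columns protein, timepoint, fold, treated_only")
    if (nrow(ss) > 0) {
      if (any(ss$protein < 1 | ss$protein > cfg$n_proteins))
        abort_field("spike_set", "protein index out of range")
      if (!all(ss$timepoint %in% TIMEPOINT_LEVELS[seq_len(cfg$n_timepoints)]))
        abort_field("spike_set", "unknown timepoint")
      if (any(ss$fold < 1))
        abort_field("spike_set", "every fold change must be >= 1")
    }
  }
  invisible(cfg)
}

#' Deterministic per-protein profile implied by a study configuration
#'
#' Reproduces the latent protein-level draws of the simulator (relative
#' abundance, unique-peptide count, isoelectric point) without generating
#' PSMs. Useful for choosing spike targets at a known abundance quantile,
#' as a spike-in experiment would.
#'
#' @param config A [study_config()].
#' @return Tibble with `protein` (index), `accession`, `abundance` (relative),
#'   `n_peptides`, `pI`.
#' @export
protein_profile <- function(config) {
  validate_study_config(config)
  n <- config$n_proteins
  out <- local_seed(config$seed, {
    abundance <- rlnorm(n, meanlog = 0, sdlog = config$abundance_dispersion)
    n_pep <- config$peptides_per_protein$min +
      rpois(n, config$peptides_per_protein$lambda)
    pI <- runif(n, 3, 10)
    list(abundance = abundance, n_pep = n_pep, pI = pI)
  })
  tibble::tibble(
    protein = seq_len(n),
    accession = protein_accession_ids(n),
    abundance = out$abundance,
    n_peptides = as.integer(out$n_pep),
    pI = out$pI
  )
}

protein_accession_ids <- function(n) {
  if (n == 0) character(0) else sprintf("P%05d", seq_len(n))
}

# Evaluate `expr` under a fixed RNG stream, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Synthetic tryptic-like peptide: a deterministic base-18 encoding of a
# global peptide index over a fixed amino-acid alphabet, so sequences are
# unique per (protein, peptide slot) and never shared between proteins.
peptide_sequences_for <- function(global_index) {
  alphabet <- strsplit("ACDEFGHIKLMNPQSTVW", "")[[1]] # 18 residues
  k <- length(alphabet)
  idx <- as.integer(global_index)
  width <- 7L
  chars <- matrix("", nrow = length(idx), ncol = width)
  rem <- idx
  for (j in seq_len(width)) {
    chars[, width - j + 1L] <- alphabet[rem %% k + 1L]
    rem <- rem %/% k
  }
  paste0(apply(chars, 1L, paste0, collapse = ""), "K")
}

study_design_tibble <- function(config) {
  tps <- TIMEPOINT_LEVELS[seq_len(config$n_timepoints)]
  design <- expand.grid(
    animal_id = sprintf("A%d", seq_len(config$n_animals)),
    group = GROUP_LEVELS,
    timepoint = tps,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  design$sample_id <- paste(design$animal_id, design$group, design$timepoint, sep = "_")
  tibble::as_tibble(design[, c("sample_id", "animal_id", "group", "timepoint")])
}

# Per-sample Poisson rate matrix (proteins x samples) before count draws.
# Spikes multiply the treated-group rate at their time point; treated-only
# spikes zero the control rate there.
protein_rate_matrix <- function(config, profile, design) {
  share <- profile$abundance * profile$n_peptides
  share <- share / sum(share)
  lambda <- matrix(
    share * config$mean_total_scans_per_sample,
    nrow = config$n_proteins, ncol = nrow(design),
    dimnames = list(profile$accession, design$sample_id)
  )
  ss <- config$spike_set
  if (!is.null(ss) && nrow(ss) > 0) {
    for (i in seq_len(nrow(ss))) {
      treated <- design$group == "treated" & design$timepoint == ss$timepoint[i]
      control <- design$group == "control" & design$timepoint == ss$timepoint[i]
      lambda[ss$protein[i], treated] <- lambda[ss$protein[i], treated] * ss$fold[i]
      if (isTRUE(ss$treated_only[i])) lambda[ss$protein[i], control] <- 0
    }
  }
  lambda
}

#' Generate a synthetic PSM table for a paired-control study
#'
#' Simulates one full study: every animal x group x time point sample, each
#' split over IEF fractions, down to individual peptide-spectrum matches with
#' identification probability scores. Decoy (false) identifications are mixed
#' in at `decoy_fraction` with probability scores from the low Beta modes, so
#' downstream probability thresholds genuinely discriminate.
#'
#' For a spiked protein at its spiked time point the expected pooled
#' treated/control count ratio equals its fold change; unspiked proteins have
#' identical expected rates in both groups. A fixed seed gives identical
#' output.
#'
#' @param config A [study_config()].
#' @return Tibble of PSMs with columns `sample_id`, `animal_id`, `group`,
#'   `timepoint`, `fraction`, `protein_accession`, `peptide_sequence`,
#'   `spectrum_probability`, `protein_probability`.
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  design <- study_design_tibble(config)
  profile <- protein_profile(config)
  empty <- tibble::tibble(
    sample_id = character(0), animal_id = character(0), group = character(0),
    timepoint = character(0), fraction = integer(0),
    protein_accession = character(0), peptide_sequence = character(0),
    spectrum_probability = numeric(0), protein_probability = numeric(0)
  )
  if (config$n_proteins == 0L) return(empty)

  local_seed(config$seed + 1L, {
    lambda <- protein_rate_matrix(config, profile, design)
    counts <- matrix(rpois(length(lambda), lambda),
                     nrow = nrow(lambda), dimnames = dimnames(lambda))

    # Expand counts to one row per true PSM.
    per_sample <- colSums(counts)
    prot_idx <- rep(rep(profile$protein, ncol(counts)), as.vector(counts))
    samp_idx <- rep(rep(seq_len(ncol(counts)), each = nrow(counts)), as.vector(counts))
    n_true <- length(prot_idx)

    max_pep <- max(profile$n_peptides)
    pep_slot <- 1L + floor(runif(n_true) * profile$n_peptides[prot_idx])
    frac_centre <- 1 + (profile$pI[prot_idx] - 3) / 7 * (config$n_fractions - 1)
    fraction <- pmin(pmax(round(rnorm(n_true, frac_centre, 0.7)), 1L),
                     config$n_fractions)

    pn <- config$probability_noise
    true_psms <- tibble::tibble(
      sample = samp_idx,
      fraction = as.integer(fraction),
      protein_accession = profile$accession[prot_idx],
      peptide_sequence = peptide_sequences_for((prot_idx - 1L) * max_pep + pep_slot),
      spectrum_probability = rbeta(n_true, pn$spectrum_true[1], pn$spectrum_true[2]),
      protein_probability = rbeta(n_true, pn$protein_true[1], pn$protein_true[2])
    )

    # Decoy PSMs: spurious accessions with one-off peptides, low scores.
    df <- config$decoy_fraction
    n_decoy_per_sample <- if (df > 0) {
      rpois(nrow(design), config$mean_total_scans_per_sample * df / (1 - df))
    } else rep(0L, nrow(design))
    n_decoy <- sum(n_decoy_per_sample)
    psms <- if (n_decoy > 0) {
      decoy_idx <- 1L + floor(runif(n_decoy) * max(config$n_proteins, 1L))
      decoys <- tibble::tibble(
        sample = rep(seq_len(nrow(design)), n_decoy_per_sample),
        fraction = 1L + as.integer(floor(runif(n_decoy) * config$n_fractions)),
        protein_accession = sprintf("DECOY%05d", decoy_idx),
        peptide_sequence = peptide_sequences_for(
          config$n_proteins * max_pep + seq_len(n_decoy)),
        spectrum_probability = rbeta(n_decoy, pn$spectrum_decoy[1], pn$spectrum_decoy[2]),
        protein_probability = rbeta(n_decoy, pn$protein_decoy[1], pn$protein_decoy[2])
      )
      dplyr::bind_rows(true_psms, decoys)
    } else true_psms

    psms <- psms[order(psms$sample, psms$fraction, psms$protein_accession,
                       psms$peptide_sequence), ]
    out <- dplyr::bind_cols(design[psms$sample, ], psms[-1])
    out[, PSM_COLUMNS]
  })
}

#' Simulate a per-sample protein count matrix directly
#'
#' Draws the same protein-level Poisson count model as [generate_study()]
#' but skips the PSM layer (peptides, fractions, probability scores), so that
#' replicate simulation studies of the pooled G-test run quickly. The counts
#' are what [assemble_protein_hits()] + [build_count_matrix()] would recover
#' from a noiseless PSM table.
#'
#' @inheritParams generate_study
#' @return A `count_matrix` (see [build_count_matrix()]).
#' @export
simulate_count_matrix <- function(config) {
  validate_study_config(config)
  design <- study_design_tibble(config)
  profile <- protein_profile(config)
  counts <- local_seed(config$seed + 1L, {
    lambda <- protein_rate_matrix(config, profile, design)
    matrix(rpois(length(lambda), lambda), nrow = nrow(lambda),
           dimnames = dimnames(lambda))
  })
  new_count_matrix(counts, design)
}

#' Observed pooled treated/control ratios for spiked proteins
#'
#' Test harness for generator calibration: for every spiked protein, pools
#' raw PSM counts over the treated and control samples at its spiked time
#' point and reports the normalized count ratio, which should concentrate
#' near the nominal fold change over replicates. Note that because the spike
#' itself inflates the treated group's total scan count, the expected
#' normalized ratio is `fold / (1 + sum(share * (fold - 1)))` over the
#' spiked proteins' abundance shares; the raw pooled count ratio is `fold`
#' exactly. The distinction only matters when spikes are a non-negligible
#' fraction of all scans.
#'
#' @param psms PSM tibble from [generate_study()].
#' @param spike_set Spike table as in [study_config()]; `protein` may be an
#'   integer index or an accession string.
#' @return Tibble with `protein_accession`, `timepoint`, `fold`,
#'   `observed_ratio` (NA when the pooled control count is zero).
#' @export
empirical_spike_check <- function(psms, spike_set) {
  if (is.null(spike_set) || nrow(spike_set) == 0) {
    return(tibble::tibble(protein_accession = character(0),
                          timepoint = character(0),
                          fold = numeric(0), observed_ratio = numeric(0)))
  }
  acc <- if (is.numeric(spike_set$protein)) {
    sprintf("P%05d", spike_set$protein)
  } else as.character(spike_set$protein)
  unknown <- setdiff(acc, unique(psms$protein_accession))
  if (length(unknown) > 0) {
    stop("spike references unknown protein(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(acc))
  for (i in seq_along(acc)) {
    tp <- spike_set$timepoint[i]
    at_tp <- psms[psms$timepoint == tp, ]
    T_t <- sum(at_tp$group == "treated")
    T_c <- sum(at_tp$group == "control")
    x_t <- sum(at_tp$group == "treated" & at_tp$protein_accession == acc[i])
    x_c <- sum(at_tp$group == "control" & at_tp$protein_accession == acc[i])
    ratio <- if (x_c > 0) (x_t / T_t) / (x_c / T_c) else NA_real_
    out[[i]] <- tibble::tibble(protein_accession = acc[i], timepoint = tp,
                               fold = spike_set$fold[i], observed_ratio = ratio)
  }
  dplyr::bind_rows(out)
}

#' Read or write a PSM table as tab-separated text
#'
#' The on-disk dialect is plain TSV with a fixed header holding exactly the
#' PSM columns, in order. `write_psm_table()` also writes a `<path>.meta.json`
#' sidecar recording the generator seed when one is supplied.
#'
#' @param psms PSM tibble.
#' @param path File path.
#' @param seed Optional integer recorded in the sidecar metadata.
#' @return `read_psm_table()` returns the PSM tibble; `write_psm_table()`
#'   returns `path` invisibly.
#' @export
write_psm_table <- function(psms, path, seed = NULL) {
  stopifnot(all(PSM_COLUMNS %in% names(psms)))
  readr::write_tsv(psms[, PSM_COLUMNS], path)
  if (!is.null(seed)) {
    jsonlite::write_json(list(seed = seed, n_psms = nrow(psms)),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", animal_id = "c", group = "c", timepoint = "c",
    fraction = "i", protein_accession = "c", peptide_sequence = "c",
    spectrum_probability = "d", protein_probability = "d"
  ))
}
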