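test_that("generator is deterministic under a fixed seed and empty at n_proteins = 0", {
  cfg <- study_config(n_proteins = 40, mean_total_scans_per_sample = 400, seed = 11L)
  expect_identical(generate_study(cfg), generate_study(cfg))

  empty <- generate_study(study_config(n_proteins = 0, seed = 1L))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("sample_id", "animal_id", "group", "timepoint",
                        "fraction", "protein_accession", "peptide_sequence",
                        "spectrum_probability", "protein_probability"))

  cfg2 <- study_config(n_proteins = 40, mean_total_scans_per_sample = 400, seed = 12L)
  expect_false(identical(generate_study(cfg), generate_study(cfg2)))
})

test_that("invalid configuration fields are reported by name", {
  expect_error(study_config(n_animals = 0), "n_animals")
  expect_error(study_config(mean_total_scans_per_sample = 0),
               "mean_total_scans_per_sample")
  expect_error(study_config(decoy_fraction = 1), "decoy_fraction")
  expect_error(study_config(
    spike_set = data.frame(protein = 1, timepoint = "4h", fold = 0.5,
                           treated_only = FALSE)), "fold")
  expect_error(study_config(
    spike_set = data.frame(protein = 99, timepoint = "4h", fold = 2,
                           treated_only = FALSE), n_proteins = 10), "out of range")
})

test_that("PSM tables respect the study design invariants", {
  cfg <- study_config(n_animals = 3, n_timepoints = 2, n_proteins = 50,
                      mean_total_scans_per_sample = 600, seed = 5L)
  psms <- generate_study(cfg)
  expect_true(all(psms$fraction >= 1 & psms$fraction <= cfg$n_fractions))
  expect_true(all(psms$spectrum_probability >= 0 & psms$spectrum_probability <= 1))
  expect_true(all(psms$protein_probability >= 0 & psms$protein_probability <= 1))
  # sample_id <-> (animal, group, timepoint) is a bijection
  key <- dplyr::distinct(psms[, c("sample_id", "animal_id", "group", "timepoint")])
  expect_equal(nrow(key), dplyr::n_distinct(psms$sample_id))
  expect_equal(nrow(key), 3 * 2 * 2)
  # peptides never shared between proteins (two-peptide rule unambiguous)
  pep_owner <- dplyr::distinct(psms[, c("peptide_sequence", "protein_accession")])
  expect_equal(anyDuplicated(pep_owner$peptide_sequence), 0L)
})

test_that("per-sample grand totals match the Poisson closed form over replicates", {
  reps <- 200
  mean_total <- 300
  totals <- unlist(lapply(seq_len(reps), function(i) {
    cfg <- study_config(n_animals = 1, n_timepoints = 1, n_proteins = 30,
                        mean_total_scans_per_sample = mean_total,
                        decoy_fraction = 0, seed = 1000L + i)
    psms <- generate_study(cfg)
    table(factor(psms$sample_id, levels = unique(psms$sample_id)))
  }))
  # grand total per sample ~ Poisson(mean_total): mean = var = mean_total
  se <- sqrt(mean_total / length(totals))
  expect_lt(abs(mean(totals) - mean_total), 3 * se)
})

test_that("per-protein counts conserve the per-sample totals", {
  cfg <- study_config(n_proteins = 40, mean_total_scans_per_sample = 500,
                      n_timepoints = 1, seed = 9L)
  psms <- generate_study(cfg)
  per_sample_rows <- dplyr::count(psms, sample_id)
  per_sample_protein <- psms |>
    dplyr::count(sample_id, protein_accession) |>
    dplyr::count(sample_id, wt = n)
  expect_equal(per_sample_protein, per_sample_rows)

  m <- simulate_count_matrix(cfg)
  expect_equal(m$totals, colSums(m$counts))
})

test_that("spiked fold changes are recovered as pooled ratios over replicates", {
  # Closed-form oracle for the count model: the normalized ratio of a spiked
  # protein is fold / infl, where infl = 1 + sum(share_i * (fold_i - 1)) is
  # the inflation of the treated total caused by the spikes themselves.
  reps <- 200
  ss <- data.frame(protein = c(5L, 6L), timepoint = "4h",
                   fold = c(16, 1), treated_only = FALSE)
  obs <- sapply(seq_len(reps), function(i) {
    cfg <- study_config(n_proteins = 40, n_timepoints = 1,
                        mean_total_scans_per_sample = 1500,
                        abundance_dispersion = 0.5, decoy_fraction = 0,
                        spike_set = ss, seed = 2000L + i)
    prof <- protein_profile(cfg)
    share <- prof$abundance * prof$n_peptides
    share <- share / sum(share)
    infl <- 1 + sum(share[ss$protein] * (ss$fold - 1))
    psms <- generate_study(cfg)
    empirical_spike_check(psms, ss)$observed_ratio / (ss$fold / infl)
  })
  # both ratios concentrate on their nominal expectation
  expect_lt(abs(mean(obs[1, ]) - 1), 3 * sd(obs[1, ]) / sqrt(reps) + 0.02)
  expect_lt(abs(mean(obs[2, ]) - 1), 3 * sd(obs[2, ]) / sqrt(reps) + 0.02)
})

test_that("spike check rejects unknown proteins and passes empty sets through", {
  cfg <- study_config(n_proteins = 10, mean_total_scans_per_sample = 200,
                      n_timepoints = 1, seed = 3L)
  psms <- generate_study(cfg)
  bad <- data.frame(protein = "P99999", timepoint = "4h", fold = 2,
                    treated_only = FALSE)
  expect_error(empirical_spike_check(psms, bad), "P99999")
  expect_equal(nrow(empirical_spike_check(psms, NULL)), 0L)
})

test_that("null studies are exchangeable between groups", {
  # standardized pooled differences should centre on zero without spikes
  reps <- 100
  zbar <- sapply(seq_len(reps), function(i) {
    cfg <- study_config(n_proteins = 100, n_timepoints = 1,
                        mean_total_scans_per_sample = 3000,
                        abundance_dispersion = 1, seed = 4000L + i)
    m <- simulate_count_matrix(cfg)
    p <- pooled_group_counts(m, "4h")
    p <- p[p$x_c + p$x_t > 0, ]
    mean((p$x_t - p$x_c) / sqrt(p$x_t + p$x_c))
  })
  expect_lt(abs(mean(zbar)), 3 * sd(zbar) / sqrt(reps))
})

test_that("PSM tables round-trip through the TSV dialect with a seed sidecar", {
  cfg <- study_config(n_proteins = 20, mean_total_scans_per_sample = 200,
                      n_timepoints = 1, seed = 8L)
  psms <- generate_study(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path, seed = 8L)
  back <- read_psm_table(path)
  expect_equal(as.data.frame(back), as.data.frame(psms))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 8L)
  expect_equal(meta$n_psms, nrow(psms))
})
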