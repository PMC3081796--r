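comparison_row <- function(protein, p_raw, ratio, x_c = 5L, x_t = 20L,
                           detect_c = 5L, detect_t = 6L, timepoint = "4h") {
  tibble::tibble(
    protein_accession = protein, timepoint = timepoint,
    x_c = x_c, x_t = x_t, T_c = 10000, T_t = 10000,
    ratio = ratio, G = 1, p_raw = p_raw,
    detect_c = detect_c, detect_t = detect_t
  )
}

test_that("Holm-Sidak matches its independent step-down oracle", {
  expect_equal(holm_sidak(0.05), 0.05) # m = 1: unchanged
  expect_equal(round(holm_sidak(c(0.01, 0.02, 0.03)), 6),
               c(0.029701, 0.039600, 0.039600))
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  expect_error(holm_sidak(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_sidak(numeric(0)), "empty")

  set.seed(41)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    adj <- holm_sidak(p)
    expect_equal(adj, holm_sidak_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))         # pointwise no smaller than input
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in rank
  }
})

test_that("the elevation pre-filter keeps only significant elevated or treated-only rows", {
  comp <- dplyr::bind_rows(
    comparison_row("DEPLETED", p_raw = 0.01, ratio = 0.4),
    comparison_row("TREATONLY", p_raw = 0.01, ratio = NA, x_c = 0L, x_t = 9L,
                   detect_c = 0L),
    comparison_row("WEAK", p_raw = 0.2, ratio = 5),
    comparison_row("GOOD", p_raw = 0.001, ratio = 3)
  )
  kept <- prefilter_elevated(comp, cascade_config())
  expect_setequal(kept$protein_accession, c("TREATONLY", "GOOD"))
  expect_equal(attr(kept, "family_size"), 2L)

  mixed <- dplyr::bind_rows(comp, comparison_row("X", 0.01, 3, timepoint = "1d"))
  expect_error(prefilter_elevated(mixed, cascade_config()), "time point")
})

test_that("the cascade applies fold and detection rules after adjustment", {
  comp <- dplyr::bind_rows(
    comparison_row("STRONG", p_raw = 1e-6, ratio = 16.9, detect_t = 6L),
    comparison_row("LOWFOLD", p_raw = 1e-5, ratio = 1.9, detect_t = 6L),
    comparison_row("HALFDETECT", p_raw = 1e-5, ratio = NA, x_c = 0L,
                   detect_c = 0L, detect_t = 3L),
    comparison_row("RAREDETECT", p_raw = 1e-5, ratio = NA, x_c = 0L,
                   detect_c = 0L, detect_t = 2L)
  )
  cand <- apply_cascade(comp, cascade_config(), n_treated = 6)
  # twofold rule removes LOWFOLD; 50% detection is inclusive (3 of 6 passes)
  # but 2 of 6 fails; treated-only rows bypass the fold rule
  expect_setequal(cand$protein_accession, c("STRONG", "HALFDETECT"))
  expect_equal(attr(cand, "family_size"), 4L)
  # defined ratios sort first (descending), undefined last
  expect_equal(cand$protein_accession, c("STRONG", "HALFDETECT"))
  expect_true(all(cand$p_adjusted < 0.05))
})

test_that("tightening any cascade threshold never enlarges the candidate set", {
  ss <- data.frame(protein = c(3L, 9L), timepoint = "4h", fold = c(4, 16),
                   treated_only = c(FALSE, TRUE))
  cfg <- study_config(n_proteins = 120, n_timepoints = 1,
                      mean_total_scans_per_sample = 3000,
                      abundance_dispersion = 1, spike_set = ss, seed = 42L)
  comp <- compare_groups(simulate_count_matrix(cfg), "4h")
  base <- cascade_config()
  base_set <- apply_cascade(comp, base, 6)$protein_accession
  tighter <- list(
    cascade_config(alpha_prefilter = 0.01),
    cascade_config(alpha_adjusted = 0.01),
    cascade_config(min_fold = 4),
    cascade_config(min_detection_fraction = 1)
  )
  for (cc in tighter) {
    expect_true(all(apply_cascade(comp, cc, 6)$protein_accession %in% base_set))
  }
})

test_that("the packaged candidate panel is a fixed point of the final filters", {
  panel <- retinal_panel()
  expect_equal(nrow(panel), 23L)
  kept <- filter_candidates(panel, cascade_config(), n_treated = 6)
  expect_equal(nrow(kept), 23L) # published rows all satisfy the cascade
  expect_equal(as.integer(table(factor(kept$timepoint, c("4h", "1d", "3d")))),
               c(8L, 12L, 3L))
  # every defined ratio respects the twofold rule
  expect_gte(min(panel$ratio, na.rm = TRUE), 2)
})

test_that("cross-time-point overlap recovers shared candidate proteins", {
  panel <- retinal_panel()
  by_tp <- split(panel, panel$timepoint)
  overlap <- cross_timepoint_overlap(by_tp)
  pair <- overlap$pairs[overlap$pairs$timepoint_a == "1d" &
                          overlap$pairs$timepoint_b == "4h" |
                          overlap$pairs$timepoint_a == "4h" &
                          overlap$pairs$timepoint_b == "1d", ]
  expect_equal(pair$n_common, 4L)
  # PGK1, CK18, FUT3, EPHA2
  expect_setequal(pair$proteins[[1]], c("Q3YAQ9", "Q8SPT9", "Q8WNP0", "Q1HKZ4"))
  expect_equal(overlap$n_distinct, 19L)

  disjoint <- cross_timepoint_overlap(list(
    a = tibble::tibble(protein_accession = c("P1", "P2")),
    b = tibble::tibble(protein_accession = c("P3"))
  ))
  expect_equal(disjoint$pairs$n_common, 0L)

  same <- cross_timepoint_overlap(list(
    a = tibble::tibble(protein_accession = c("P1", "P2")),
    b = tibble::tibble(protein_accession = c("P2", "P1"))
  ))
  expect_equal(same$pairs$n_common, 2L)
  expect_setequal(same$pairs$proteins[[1]], c("P1", "P2"))
})
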