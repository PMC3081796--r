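# Independent oracles for the statistical core.

# G statistic via the entropy-difference grouping of the likelihood ratio
# (algebraically distinct from the implementation's 2*sum O*ln(O/E) form),
# with the same add-0.5 rule when either observed count is zero.
g_oracle <- function(x_c, x_t, T_c, T_t) {
  if (x_c == 0 || x_t == 0) {
    x_c <- x_c + 0.5; x_t <- x_t + 0.5
    T_c <- T_c + 0.5; T_t <- T_t + 0.5
  }
  n <- x_c + x_t
  2 * (x_c * log(x_c / n) + x_t * log(x_t / n) -
         x_c * log(T_c / (T_c + T_t)) - x_t * log(T_t / (T_c + T_t)))
}

# G via the conditional-binomial likelihood-ratio identity (only valid for
# strictly positive integer counts): a third, fully independent route.
g_oracle_binom <- function(x_c, x_t, T_c, T_t) {
  n <- x_c + x_t
  2 * (dbinom(x_c, n, x_c / n, log = TRUE) -
         dbinom(x_c, n, T_c / (T_c + T_t), log = TRUE))
}

# Step-down Holm-Sidak by explicit per-rank loop with a max over all lower
# ranks, O(m^2); independent of the implementation's sort/cummax route.
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- 0
    for (j in seq_len(i)) {
      best <- max(best, 1 - (1 - p[ord[j]])^(m - j + 1))
    }
    adj_sorted[i] <- min(best, 1)
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Hand-built PSM rows for filtering tests.
psm_row <- function(sample_id = "A1_control_4h", fraction = 1L,
                    protein = "P00001", peptide = "AAAAAAK",
                    spectrum = 0.95, prot_p = 0.9) {
  tibble::tibble(
    sample_id = sample_id,
    animal_id = sub("_.*", "", sample_id),
    group = strsplit(sample_id, "_")[[1]][2],
    timepoint = strsplit(sample_id, "_")[[1]][3],
    fraction = fraction,
    protein_accession = protein,
    peptide_sequence = peptide,
    spectrum_probability = spectrum,
    protein_probability = prot_p
  )
}

# Minimal paired design: n animals x control/treated at one time point.
tiny_design <- function(n_animals = 2, timepoint = "4h") {
  d <- expand.grid(animal_id = sprintf("A%d", seq_len(n_animals)),
                   group = c("control", "treated"),
                   timepoint = timepoint,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- paste(d$animal_id, d$group, d$timepoint, sep = "_")
  tibble::as_tibble(d[, c("sample_id", "animal_id", "group", "timepoint")])
}

# Count matrix straight from a counts matrix and design (bypasses hits).
matrix_fixture <- function(counts, design) {
  colnames(counts) <- design$sample_id
  hits <- tibble::as_tibble(counts, rownames = "protein_accession") |>
    tidyr::pivot_longer(-protein_accession, names_to = "sample_id",
                        values_to = "spectral_count") |>
    dplyr::filter(spectral_count > 0) |>
    dplyr::mutate(unique_peptide_count = 2L)
  build_count_matrix(hits, design)
}
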