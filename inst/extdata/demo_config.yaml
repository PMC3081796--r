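# Demo pipeline configuration: a small simulated paired-control study with
# one abundance spike and one treated-only spike at the 4 h time point.
# All thresholds are the package defaults (0.85 / 0.60 spectrum and protein
# probabilities, two-peptide rule, 0.05 raw and adjusted alpha, twofold,
# 50% treated detection).
simulate:
  n_animals: 6
  n_timepoints: 2
  n_fractions: 10
  n_proteins: 80
  mean_total_scans_per_sample: 1200
  abundance_dispersion: 1.0
  decoy_fraction: 0.05
  seed: 101
  spike_set:
    - protein: 7
      timepoint: 4h
      fold: 16
      treated_only: false
    - protein: 11
      timepoint: 4h
      fold: 8
      treated_only: true
thresholds:
  spectrum_probability_min: 0.85
  protein_probability_min: 0.60
  min_unique_peptides: 2
cascade:
  alpha_prefilter: 0.05
  alpha_adjusted: 0.05
  min_fold: 2
  min_detection_fraction: 0.5
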