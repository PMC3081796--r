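---
title: "Spectral-count biomarker discovery: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count biomarker discovery: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seromark)
```

`seromark` re-implements, as a reusable and tested pipeline, the
spectral-counting biomarker-discovery analysis used in paired-control serum
proteomics: probability filtering of peptide-spectrum matches (PSMs),
fraction merging, a pooled two-group G-test per protein, Holm-Sidak
adjustment, and a stringent candidate filter cascade. This vignette is the
package's own account of the statistical model, the semantics of every
filter, the synthetic-data generator, and the design decisions taken where
the procedure is underdetermined.

## The quantification model

Label-free spectral counting treats the number of tandem spectra matched to
a protein in a sample as a relative abundance measure; it is among the most
reproducible label-free indices and correlates strongly with protein
amount. The unit of information is a PSM carrying two probability scores —
one for the spectrum assignment, one for the protein inference — plus its
provenance: animal, group (control or treated), time point and
isoelectric-focusing (IEF) fraction.

### Identification filtering

Three filters precede all statistics:

* **Probability thresholds** (defaults 0.85 spectrum, 0.60 protein).
  Comparisons are *inclusive* (`>=`): the procedure is described in the
  field as filtering "at" a score, and inclusivity makes the printed
  thresholds attainable values. Filtering is order-preserving and
  idempotent.
* **Fraction merging.** The ten IEF fractions of a sample are pooled before
  any per-protein summary; a sample's serum proteome is the union of its
  fractions.
* **The two-peptide rule** (default 2). A protein is accepted in a sample
  only if at least two *distinct peptide sequences* support it there,
  counted after fraction merging. We apply the rule per sample — not per
  fraction and not study-wide — because fractions are explicitly merged
  "per sample" and because per-sample acceptance is what makes the later
  detection-frequency filter well defined. A study-wide variant would admit
  proteins into samples where they have single-peptide support, changing
  detection counts. Peptide modifications are out of scope: "unique
  peptide" means a distinct sequence string.

### The pooled G-test

For each protein at one time point, counts are summed over the six control
samples (x_c) and six treated samples (x_t); T_c and T_t are the group
totals over all proteins. The test statistic is the likelihood-ratio
(G) statistic against the expectation that the protein occupies the same
fraction of both groups' scans:

$$G = 2\left[x_c \ln\frac{x_c}{\hat e_c} + x_t \ln\frac{x_t}{\hat e_t}\right],
\qquad \hat e_g = T_g\,\frac{x_c + x_t}{T_c + T_t},$$

with p-values from the upper chi-square tail, 1 df. The "normalization" in
the reported normalized p-value is exactly the total-scan scaling inside
the expected counts ê; no further adjustment is applied. The effect size
reported alongside is the normalized scan-count ratio
R = (x_t/T_t)/(x_c/T_c), undefined when x_c = 0 (a treated-only protein),
rendered `-` in reports.

Counts are **pooled across animals** before testing: the procedure computes
one p-value per protein per time point from all control and treated
specimens. Per-animal variance modelling (paired tests, dispersion
estimation as in negative-binomial RNA-seq models) is an explicit non-goal:
the pooled G-test is the method being reproduced, and its anti-conservatism
under between-animal variability is mitigated downstream by the cascade's
fold and detection-frequency rules.

Numerical choices:

* **Zero cells.** When x_c or x_t is 0 the log term diverges; we add 0.5 to
  both counts *and* both totals, for the G computation only. The ratio
  column independently keeps its undefined marker.
* **Underflow.** Raw p-values are floored at 1e-300. A reported value of
  0.00E+00 in this kind of analysis is floating-point underflow, not an
  exact zero; the package never emits exact zero for a nonzero G. The
  Holm-Sidak step uses `-expm1(k * log1p(-p))` so tiny p-values do not
  collapse to zero during adjustment either.
* G is clipped at 0 against sub-epsilon negative rounding at the null.

### The candidate cascade

The cascade for one time point, in order:

1. **Elevation pre-filter**: keep proteins with raw p < 0.05 that are
   elevated in treated samples (R > 1) or treated-only (undefined R with
   x_t > 0). The number m of retained proteins is the **family size** for
   the next step — the adjustment is applied to this subset, not to the
   full protein list. This matters: it changes every adjusted p, and it is
   how the procedure is described; the package records m in each run
   manifest.
2. **Holm-Sidak step-down**: rank the family's p-values ascending; the
   rank-i candidate is 1 − (1 − p_(i))^(m−i+1); enforce monotonicity by
   running maxima; cap at 1. Keep adjusted p < 0.05.
3. **Twofold rule**: keep R ≥ 2. Treated-only proteins have no ratio and
   bypass this rule — consistent with reference panels that retain
   undefined-ratio rows.
4. **Detection frequency**: keep proteins detected in at least 50% of
   treated samples, *inclusive* — 3 of 6 passes. The rule constrains
   treated samples only; control detections are unconstrained. "Detection"
   means presence after all identification filters (so the two-peptide rule
   participates in detection counts).

Output rows are ordered by descending ratio with undefined-ratio rows last,
ties by ascending adjusted p. The ordering is this package's convention;
no ordering is prescribed by the procedure itself.

The package ships a transcribed reference panel from a published primate
retinal-laser-injury study (`retinal_panel()`); the acceptance tests verify
that this published panel is a *fixed point* of filters 2-4 (all 23 rows
survive) and that its per-time-point counts, treated-only counts,
cross-time-point overlap and GO tallies are reproduced by the package's
code.

### GO summaries

GO annotation is deliberately flat: one biological-process and one
cellular-component term per protein, supplied as a mapping table, tallied
over distinct panel proteins; the defining terms are the maximal-count
terms per category with all ties returned. No ontology-graph propagation,
no enrichment statistic against a background — the reproduced analysis
reports term counts, and an enrichment p-value would require a background
set that is not specified anywhere. `gseapy`-style enrichment could be
layered on by users who have a background.

## The synthetic-data generator

Raw PSM-level data for paired-control serum studies are rarely public, so
the generator is a first-class module that emulates the study structure:

* **Design**: n_animals = 6, paired control/treated, three time points
  (4 h, 1 day, 3 days), ten IEF fractions — the generator's defaults are
  the study conditions themselves.
* **Abundance**: relative protein abundances are log-normal
  (`abundance_dispersion`, default sdlog 2.5, spanning roughly five orders
  of magnitude across proteins — serum-like in the sense of being dominated
  by a few very abundant proteins, though real serum spans ten orders).
* **Counts**: a protein's per-sample spectral count is Poisson with rate
  proportional to abundance × peptide count, scaled so a sample's expected
  total is `mean_total_scans_per_sample` (default 5000). This is the
  simplest model consistent with spectral counts being an abundance proxy;
  it has no extra-Poisson between-animal dispersion (see *Limits*).
* **Spikes**: a spike multiplies the treated-group rate by `fold` at one
  time point; `treated_only` zeroes the control rate, reproducing
  undefined-ratio candidates. The expected pooled *raw* count ratio equals
  `fold`; the expected *normalized* ratio is `fold` divided by the spike's
  own inflation of the treated total, 1 + Σ share·(fold−1), which is
  negligible whenever spikes are a small fraction of scans.
* **Fractions**: each protein has a latent isoelectric point, uniform on
  pH 3-10, mapped linearly to the fraction axis; its PSMs scatter over
  adjacent fractions with a discretized normal (sd 0.7 fractions). This
  makes fraction merging a real operation without modelling IEF chemistry.
* **Probability scores**: true identifications draw from high Beta modes
  (defaults Beta(18,2) spectrum, Beta(12,3) protein), decoys from low modes
  (Beta(4,6), Beta(3,5)), mixed in at `decoy_fraction` (default 5%) with
  one-off peptide sequences. Thresholds therefore do real work, and the
  two-peptide rule removes most surviving decoys.
* **Peptides**: synthetic sequences are deterministic encodings unique per
  (protein, peptide slot) and never shared between proteins, so protein
  inference is unambiguous by construction (shared-peptide grouping is out
  of scope).
* **Determinism**: a fixed seed gives byte-identical tables; the RNG state
  of the caller is restored.

### What the simulator does not emulate

No retention-time, m/z or raw-spectrum structure (no mzML); no database
search-engine behaviour; no between-animal biological variability beyond
Poisson sampling; no shared peptides; no missingness mechanism other than
low abundance. Consequently, passing simulation tests demonstrates the
*pipeline's* correctness and calibration under its stated count model —
not that the G-test is well calibrated for real animals, where pooling
ignores biological replication.

### Compositional caveat

With serum-like dispersion (sdlog 2.5) a handful of albumin-like proteins
dominate the totals; their sampling fluctuations shift every other
protein's expected share, inflating the false-candidate rate of the pooled
test. This is a property of the reproduced procedure, not an
implementation artifact. The package's calibration simulations therefore
use moderate dispersion (sdlog 1) and large totals, where the G-test's
assumptions hold: 200 replicate null studies of 300 proteins at 20,000
scans/sample give a type-I error within Monte-Carlo error of the nominal
0.05, and fold-16 spikes at 2,000 scans/sample are recovered through the
full cascade in well over 90% of replicates while null proteins become
candidates at a per-protein rate far below the adjusted alpha. These
problem sizes (300 proteins, 60-200 replicates) were chosen to make the
calibration checks sharp yet quick; the generator's *defaults* remain the
realistic study conditions above.

Spiked proteins in the recovery simulations are chosen at mid-abundance
quantiles of the replicate's deterministic abundance profile
(`protein_profile()`), mirroring how spike-in experiments select analytes
at detectable baseline levels rather than at random from a distribution
whose lower tail is undetectable at any fold change.

## Other design decisions

* **Sample standard deviation** (n−1) is used in `summarize_totals()`; with
  per-time-point identification totals of 818, 928 and 978 it gives
  908 ± 82 (a population sd would give 67), and half-up rounding is applied
  to both summaries.
* **Error reporting** names the offending field, record or stage: invalid
  config fields are reported by name, spike sets referencing unknown
  proteins name the accession, and `run_pipeline()` prefixes failures with
  the stage (`config`, `input`, `simulate`, `filter`, `compare`, `cascade`,
  `overlap`, `go`).
* **Byte-identical runs.** The run manifest deliberately contains no
  timestamps; two runs with the same config and seed produce identical
  bytes in every output file, which the tests enforce with checksums.
* **On-disk formats** are plain TSV with fixed documented headers (PSMs,
  count matrix + design, comparisons, candidate panels, GO tables), YAML
  configuration, and a JSON manifest; undefined ratios are serialized as
  `-`.

## A complete run

```{r, eval = FALSE}
library(seromark)
manifest <- run_pipeline(
  system.file("extdata", "demo_config.yaml", package = "seromark"),
  out_dir = "demo_out")
str(manifest$candidates_retained)
```

The demo config simulates 80 proteins over two time points with a 16-fold
spike and a treated-only spike at 4 h; both — and only both — emerge as
candidates. The same stages are scriptable from a shell via
`inst/scripts/seromark.R` (`simulate`, `filter`, `compare`, `cascade`,
`go`, `report`, `all`), each stage reading and writing standalone TSVs so
any single stage can be re-run or inspected in isolation.
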