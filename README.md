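# spermchrom

Analysis pipeline for studying how a sperm-specific histone H2B variant
(H2B.8) condenses transcriptionally inactive, AT-rich chromatin in
flowering plants. Flowering-plant sperm lack protamines yet have small,
transcriptionally active nuclei; H2B.8 explains this by aggregating
unexpressed euchromatin into phase-separated condensates. The package
re-implements the computational analyses behind that model as tested,
reusable functions, exercised end to end on a synthetic-data generator
with planted, recoverable parameters.

## What it computes

* **Window enrichment and peak calling** — per-window
  `log2((CPM_ip + α)/(CPM_in + α))` and the four-stage peak procedure:
  retain 50-bp windows with enrichment > 1.2, merge gaps ≤ 150 bp, drop
  regions < 200 bp, re-score regions from summed counts and keep scores
  ≥ 1.2. Verified exactly against a per-base brute-force oracle.
* **Chromatin state** — TE classification by the bimodal H3K9me2
  distribution (heterochromatic iff log2 ratio > 0.7), expression
  grouping (silent + expression quantiles), and threshold-based
  differential-expression filters (TPM > 1, |log2FC| ≥ cutoff, q < 0.05).
* **Association** — Spearman correlations, scaled PCA, and incremental
  multivariate regression of H2B.8 enrichment on
  `log10(RPKM + 0.01)`-transformed transcription, GC content and
  chromatin marks over 200-bp windows, with adjusted R² and Gaussian-ML
  AIC (`n·ln(2πRSS/n) + n + 2(k+2)`).
* **Hi-C** — bins-BED + COO triplet I/O, depth normalisation,
  expected-by-distance decay curves, genotype comparison matrices, the
  20-quantile coupling of interaction change with H2B.8 enrichment
  (short-range 200 kb–1.1 Mb band and pericentromere–arm mask, summary
  Spearman ρ with a permutation null), and the map-resolution criterion
  (80% of 1-kb bins with > 1,000 contacts).
* **Cytometry** — Otsu thresholding, 3D nucleus segmentation
  (threshold → Gaussian smooth → re-threshold → 26-connected components),
  nuclear size by projection area or voxel volume, foci volumetry, tile
  colocalization quantiles, and the group statistics used throughout
  (one-way ANOVA + Tukey HSD, Welch t, Fisher exact, χ² segregation
  tests), each verified against independent formula/enumeration oracles.
* **Synthetic data** — genomes with pericentromeres and typed features,
  ChIP/input tracks with a planted enrichment model
  (β_T = −0.5 on transcription, β_GC = −4 on GC), bimodal H3K9me2,
  power-law Hi-C with localised genotype effects, two-channel 3D nucleus
  stacks with known foci, plus writers for FASTA/BED/bedGraph/TSV/COO/
  TIFF and a YAML run manifest.

## Worked example

```r
library(spermchrom)

p  <- sim_params(seed = 1)          # study conditions, one master seed
gm <- simulate_genome(p)
tr <- simulate_chip_tracks(gm, "H2B.8")
e  <- window_enrichment(tr$ip, tr$input, alpha = 0.5)
pk <- call_h2b8_peaks(e, tr$ip, tr$input)
partition_peak_coverage(pk, gm)$genome_fraction
```

On the default synthetic genome this prints a peak coverage of
`0.0039` (0.39% of the genome; coverage scales with the planted
enrichment level, not calibrated to any real data set). The association
stage on the same genome:

```r
cov200 <- window_covariates(gm, 200)
tr200  <- simulate_chip_tracks(gm, "H2B.8", step = 200)
e200   <- window_enrichment(tr200$ip, tr200$input)
fm <- build_feature_matrix(e200,
        predictors = list(transcription = log10(cov200$TPM + 0.01),
                          gc = cov200$gc))
spearman_cor(fm$y, fm$transcription)$statistic   # -0.74
spearman_cor(fm$y, fm$gc)$statistic              # -0.53
```

recovers the planted anticorrelation of the variant with transcription
and GC content. The numbered scripts under `analysis/` run the whole
workflow as a narrative — `01_simulate.R` writes every synthetic artifact
under `results/synthetic/`, `02`–`06` perform peak, state, association,
Hi-C and imaging analyses and print their findings (e.g. distance-decay
slope −1.001 against the planted −1.0, short-range coupling ρ = 0.974,
nuclear-area ratio 1.43 against the planted 1.40 with Welch
p = 9.9e-07).

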