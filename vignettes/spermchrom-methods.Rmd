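---
title: "Methods: quantifying histone-variant-driven chromatin condensation"
author: "spermchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying histone-variant-driven chromatin condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Flowering-plant sperm condense their nuclei without protamines and without
silencing transcription. A sperm-specific histone variant, H2B.8, carries a
long intrinsically disordered region (IDR) in its N-terminal tail and
aggregates transcriptionally inactive, AT-rich chromatin into
phase-separated condensates. The genomic evidence for this model rests on a
set of computational analyses: window-level ChIP enrichment with a bespoke
peak caller, a chromatin-state classification of transposable elements
(TEs) by H3K9me2, multivariate regression of enrichment against
transcription and GC content, Hi-C contact-matrix comparisons between
wild-type and ectopic-expression genotypes, and 3D image quantification of
nuclei and chromatin foci.

`spermchrom` re-implements that analysis stack as a tested, reusable
pipeline, together with a synthetic-data generator that plants every effect
the analyses are supposed to detect. The generator makes each downstream
stage testable end to end with known ground truth and no external
downloads.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. All coordinates
are 0-based half-open; window tilings start at 0; a trailing window shorter
than the step is dropped for coverage tracks and kept (flagged) for Hi-C
bins, because tracks need equal-width windows while contact matrices need
full genome coverage. Every artifact type draws from its own named random
stream derived from one master seed (`derive_seed()`), so adding one
artifact to a run never perturbs another, and a fixed master seed
reproduces every artifact bit for bit.

### Genome layout

The default desk-scale genome is 2 chromosomes of 2 Mb with a central
pericentromere occupying 25% of each chromosome. Features are placed left
to right with exponential gaps; the class of each feature is drawn from
position-dependent weights so that heterochromatic TEs concentrate inside
pericentromeres (roughly 85–90% of them), euchromatic TEs are enriched at
the pericentromere edges and present on arms, and genes dominate the arms.
This mirrors the chromosomal organisation in which the histone variant is
most abundant at pericentromere borders. A small fraction of
heterochromatic TEs on arms is deliberate: real annotations are not
perfectly partitioned.

Per-window GC is drawn around class means (euchromatic TE 0.32, gene 0.38,
intergenic 0.36, heterochromatic TE 0.42, sd 0.04), planting the AT-richness
of euchromatic TEs with a 0.10 GC gap between TE classes. Forty percent of
genes are silent (TPM 0); the rest draw log-normal TPM (log-mean log 10,
log-sd 1.3), a typical shape for expressed-gene abundance.

### Planted ChIP model

For the histone variant, per-window log2 enrichment is

    e = beta0 + betaT * log10(TPM + 0.01) + betaGC * (GC - 0.5)
        + class offset + N(0, sigma)

with `betaT = -0.5`, `betaGC = -4`, `sigma = 0.3`, `beta0 = 0.4`, and class
offsets (+0.4 euchromatic TE, -0.4 heterochromatic TE). The negative
coefficients plant the two anticorrelations the association module must
recover. The `log10(TPM + 0.01)` transform matches the transform used in
the regression module, so recovery is self-consistent; the pseudocount
0.01 handles silent windows. Input coverage is Poisson with mean
`lambda_in = 50` per 50-bp window — ordinary ChIP-seq depth at which the
log-ratio noise is realistic but the structure is recoverable — and IP
coverage is Poisson with mean `lambda_in * 2^e`.

H3K9me2 uses a two-component class model: windows in heterochromatic TEs
draw N(1.5, 0.3), all other windows N(-0.5, 0.3). Over TEs this produces
the bimodal enrichment histogram that motivates the 0.7 classification
cutoff; with these components the cutoff misclassifies about 0.2% of
elements. The IDR-truncated variant keeps the transcription exclusion but
reverses the TE-class preference and loses the GC term, emulating its
relocation into heterochromatin.

### Planted Hi-C model

Expected intra-chromosomal counts follow a power-law distance decay
`(d + d0)^-gamma` with `gamma = 1` and `d0 = 10 kb`, scaled so the
wild-type matrix totals `10^7` contacts at 1-kb bins. A decay exponent near
-1 is typical of plant and animal contact maps; `d0` regularises the
near-diagonal. Inter-chromosomal pairs are not specified by the procedure
being reproduced; we set them to the decay law evaluated at a fixed
effective distance of 2 Mb, which yields a plausible intra/inter contact
split (about 10% inter).

The ectopic-expression genotype multiplies expected counts by three local
effects, each scaling with the mean variant enrichment of the two bins
(negative enrichment clipped to zero, since gains occur where the variant
is abundant): short-range intra pairs at 200 kb–1.1 Mb gain
`1 + gamma_short * hbar`; intra pairs with exactly one bin in a
pericentromere gain `1 + gamma_peri * hbar`; inter-chromosomal
pericentromere–pericentromere pairs lose `1 - delta_interperi`. The
genotype effects are planted on the generator's own (truth) enrichment
field binned at 1 kb; the analysis side ranks bins by the measured
log2(IP/input) track, whose ranks agree with truth to Spearman ≈ 0.996 at
default depth.

When the short-range coupling is the quantity under study, the experiment
varies `gamma_short` alone and holds the other two effects at zero. This
is forced by internal consistency: a live pericentromere–arm gain leaks
into the 200 kb–1.1 Mb band through boundary-crossing pairs, so
`gamma_short = 0` would not be a true null for the coupling statistic.

### Image phantoms

Each stack has two channels (DNA stain and marker) built as background
(10 counts) + ellipsoid plateau (80 / 50 counts) + 3D Gaussian foci in the
marker channel (amplitude 150, sd 2.5 voxels), with Poisson noise. Foci
centres are drawn from a geometry stream so that changing the noise seed
changes the noise only, never the ground truth. Centres are kept well
inside the ellipsoid and mutually separated by at least 3.6 focus radii;
closer foci would merge above threshold because their Gaussian tails add —
with two foci at distance s the midpoint intensity is
`2 A exp(-s^2 / 8 r^2)`, which stays below the half-amplitude detection
threshold only for s > 3.3 r. Voxels are 0.04 x 0.04 x 0.125 um,
3D-SIM-like anisotropy at a 64 x 64 x 16 stack size.

## Analysis procedures and numerical choices

**Window enrichment.** `log2((CPM_ip + alpha)/(CPM_in + alpha))` with
`alpha = 0.5` applied after counts-per-million scaling; a raw-count mode
serves depth-matched designs. Windows where either side is zero without a
pseudocount are missing, never silently zero.

**Peak calling** is the four-stage procedure: retain 50-bp windows with
enrichment strictly above 1.2; merge retained windows whose edge-to-edge
gap is at most 150 bp; drop regions shorter than 200 bp; re-score each
region from summed counts over all windows it spans and keep scores at or
above 1.2. The threshold asymmetry (strict at stage 1, inclusive at stage
4) follows the stated retention/discard wording; the gap is edge-to-edge;
the re-score uses summed coverage, not the mean of window log-ratios. The
caller is verified exactly (intervals and scores) against a per-base
brute-force oracle on 1,000 random tracks.

**Partition and overlap.** Peak coverage is chopped into 50-bp pieces and
assigned by precedence gene > euchromatic TE > heterochromatic TE >
intergenic (the tie rule is not specified anywhere; precedence is
deterministic and documented). Base pairs are conserved exactly. A feature
counts as peak-overlapped when at least 25% of its length is covered,
boundary inclusive.

**TE classification** thresholds per-element H3K9me2 at 0.7; exactly 0.7
is euchromatic because the heterochromatic class is defined by strict
excess. **Expression groups** are silent (TPM at or below 1) plus four
equal-count quantile groups, ties to the lower group. **Differential
calls** require TPM strictly above 1 in at least one condition,
|log2FC| at or above the cutoff (inclusive), and q strictly below 0.05.

**Association.** Spearman is Pearson on mid-ranks; PCA centres and scales
every variable so explained variances sum to the variable count, with
component signs fixed so the dominant loading is positive; regression is
ordinary least squares with adjusted R-squared and the Gaussian
maximum-likelihood AIC, `n log(2 pi RSS/n) + n + 2 (k + 2)`, the
convention standard statistical environments report, so values are
directly comparable. A numerically perfect fit reports AIC as -Inf. The
variable-addition order is an explicit argument (no greedy rule is
invented); all single-variable fits are reported alongside the nested
sequence.

**Hi-C.** Matrices are compared raw after depth scaling only — no ICE/KR
balancing, because the procedure being reproduced feeds raw counts into
the comparison. The coupling statistic sorts 1-kb bins into 20
equal-count enrichment quantiles and averages the difference matrix over
masked pairs per quantile pair, implicit zeros included; the summary rho
is Spearman between the quantile-index sum (a+b) and the cell mean over
non-empty unordered cells (a per-pair alternative is available via
`rho_level = "pair"`). The permutation null shuffles cell means across
cells, matching the level at which rho is defined. Band endpoints are
inclusive; the pericentromere–arm mask keeps intra-chromosomal pairs with
exactly one bin in a pericentromere; inter-chromosomal pericentromere
contacts are summarised as a scalar mean difference.

**Imaging.** Otsu's threshold maximises between-class variance with ties
broken to the lower level. Segmentation is threshold, Gaussian smoothing
of the binary mask (separable, reflected edges, sigma scaled by voxel
anisotropy in z), a repeated Otsu threshold, then 26-connected components
with small components removed. A threshold that fails to separate two
real intensity classes (class separation under twice the overall spread)
returns an empty, flagged result instead of labelling noise. Nuclear size
is either the area of the maximum-intensity projection (um^2) or the voxel
volume (um^3), both units appearing in the original measurements. Foci are
26-connected components above a threshold within the nucleus mask, at
least 5 voxels. Colocalization tiles each z-slice into 20 x 20-voxel
regions; a tile's value is its mean over covered mask voxels divided by
the whole-nucleus channel sum, edge tiles entering with their covered
voxels as weight; tiles are ranked by the second channel into 8
equal-count groups.

**Group statistics** wrap the standard implementations (`aov`,
`TukeyHSD`, `t.test` with Welch correction, `fisher.test`,
`chisq.test`-equivalent formula) behind a uniform result type, and every
one of them is verified against an independent formula or enumeration
oracle in the test suite. The degenerate ANOVA input (all observations
equal) reports F = 0 with p = 1. The Fisher odds ratio is the sample
cross-product ratio, with the conditional MLE also returned.

## Problem sizes

The default study conditions are sized so the whole test suite and the
acceptance script each run in minutes on one CPU: a 2 x 2 Mb genome
(80,000 windows at 50 bp; 20,000 at 200 bp), Hi-C at 1-kb bins and 10^7
contacts, 20 replicate matrix pairs for the permutation-null calibration,
and 16 image stacks for the size-ratio recovery. Unit tests use a further
scaled-down 2 x 200 kb genome.

## What passing tests show — and what they do not

The generator emulates the statistical structure of the real analyses:
anticorrelated enrichment, bimodal H3K9me2, power-law contact decay with
localised genotype effects, and ellipsoid nuclei with Gaussian foci. It
does not emulate mappability artefacts, copy-number variation,
restriction-fragment geometry, replicate structure, optical aberrations,
or the real genome's repeat content. Passing recovery tests therefore
demonstrates that the implementations are correct and statistically
calibrated, not that the biological conclusions would replicate from raw
data; the published headline numbers (17% genome peak coverage, the exact
Hi-C coupling rho values, the 40% sperm-nucleus enlargement) depend on the
deposited sequencing data and microscope images and are outside what a
desk-scale synthetic study can or should reproduce.

## Known limitations

* The peak caller assumes fixed-step tracks; variable-step input is out of
  scope.
* Contact matrices are held as sparse upper-triangle tables; dense
  operations (e.g. eigen-decomposition for compartments) are deliberately
  absent, as are TAD and loop calling.
* 3D labelling is breadth-first search in R; it is comfortable at phantom
  sizes (10^5–10^6 voxels) but not tuned for full-resolution microscopy
  volumes.
* The permutation test calibrates the cell-level rho only; it does not
  model spatial autocorrelation between overlapping quantile-pair cells.
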