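#!/usr/bin/env Rscript
# 3D image quantification: nucleus segmentation, nuclear size in two
# genotype-like groups, foci volumetry, tile colocalization quantiles, and
# the group statistics used across the figures (ANOVA + Tukey, Welch t,
# Fisher exact, chi-squared segregation check).

suppressMessages({ library(spermchrom); library(data.table) })

out <- "results"
dir.create(out, showWarnings = FALSE)

p <- sim_params(seed = 1L)

# per-nucleus size jitter (5% sd on the linear scale) emulates natural
# cell-to-cell variability on top of the planted group effect
measure <- function(scales, seeds) vapply(seq_along(seeds), function(k) {
  st <- simulate_nucleus_stack(p, seed = seeds[k], axes_scale = scales[k])
  seg <- segment_nuclei(st, sigma = 1.5)
  nuclear_size(seg, st$voxel_size, "area_of_max_projection")$size[1]
}, numeric(1))

set.seed(1)
wt_area <- measure(exp(rnorm(10, 0, 0.05)), 1:10)
mut_area <- measure(sqrt(1.4) * exp(rnorm(10, 0, 0.05)), 11:20)
cat(sprintf("nuclear area: %.3f vs %.3f um^2 (ratio %.3f, planted 1.40)\n",
            mean(wt_area), mean(mut_area), mean(mut_area) / mean(wt_area)))
fwrite(data.table(group = rep(c("WT", "mutant"), each = 10),
                  area_um2 = c(wt_area, mut_area)),
       file.path(out, "nuclear_areas.tsv"), sep = "\t")

tt <- two_sample_t(mut_area, wt_area)
cat(sprintf("Welch t = %.2f, p = %.2g\n", tt$statistic, tt$p_value))
an <- one_way_anova_tukey(list(WT = wt_area, mutant = mut_area))
cat(sprintf("ANOVA F = %.2f, p = %.2g; Tukey p = %.2g\n",
            an$statistic, an$p_value, an$tukey$p_adj[1]))

st <- simulate_nucleus_stack(p, seed = 5)
seg <- segment_nuclei(st, sigma = 1.5)
thr <- p$background + p$plateau_marker + p$focus_amp / 2
fc <- detect_foci(st, seg, focus_threshold = thr, min_voxels = 5L)
cat(sprintf("foci: %d detected, total volume %.4f um^3\n",
            fc$per_nucleus$n_foci, fc$per_nucleus$total_volume))
fwrite(fc$foci, file.path(out, "foci.tsv"), sep = "\t")

cq <- colocalization_quantiles(st, seg, tile = 20L, n_quantiles = 8L,
                               channels = c("dna", "marker"))
fwrite(cq, file.path(out, "colocalization_quantiles.tsv"), sep = "\t")
cat("tile colocalization (DNA stain by marker quantile):\n")
print(round(cq$mean_a * 1e3, 4))

# transmission-assay style statistics: planted 30% deficit at n = 743
set.seed(2)
n <- 743L
mut <- rbinom(1, n, 0.35 / 0.85)
tab <- matrix(c(mut, n - mut, rbinom(1, n, 0.5), n - rbinom(1, n, 0.5)), 2)
fe <- fisher_exact_2x2(tab)
cat(sprintf("transmission Fisher test: OR = %.2f, p = %.2g\n",
            fe$statistic, fe$p_value))

seg_counts <- c(AA = 380, Aa = 720, aa = 362)   # selfing progeny
cg <- chi_square_gof(seg_counts, c(1, 2, 1))
cat(sprintf("segregation chi^2 = %.2f (df %d), p = %.2f\n",
            cg$statistic, cg$df, cg$p_value))
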