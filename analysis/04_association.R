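#!/usr/bin/env Rscript
# Association analyses over 200-bp windows: Spearman correlations of H2B.8
# enrichment with transcription and GC, PCA of chromatin features, and the
# incremental multivariate regression with adjusted R-squared and AIC.

suppressMessages({ library(spermchrom); library(data.table) })

out <- "results"
dir.create(out, showWarnings = FALSE)

p <- sim_params(seed = 1L)
gm <- simulate_genome(p)
cov200 <- window_covariates(gm, 200L)
tr <- simulate_chip_tracks(gm, "H2B.8", step = 200L)
k9 <- simulate_chip_tracks(gm, "H3K9me2", step = 200L)
e <- window_enrichment(tr$ip, tr$input)
ek9 <- window_enrichment(k9$ip, k9$input)

fm <- build_feature_matrix(
  e, predictors = list(transcription = log10(cov200$TPM + 0.01),
                       gc = cov200$gc,
                       h3k9me2 = ek9$value))
cat("feature matrix:", nrow(fm), "windows (",
    attr(fm, "n_dropped"), "dropped )\n")

for (v in c("transcription", "gc", "h3k9me2")) {
  r <- spearman_cor(fm$y, fm[[v]])
  cat(sprintf("spearman(H2B.8, %-13s) = %+.3f\n", v, r$statistic))
}

pca <- chromatin_pca(fm[, .(y, transcription, gc, h3k9me2)])
cat("PCA explained variance:", round(pca$explained, 3), "\n")
fwrite(as.data.table(pca$loadings, keep.rownames = "variable"),
       file.path(out, "pca_loadings.tsv"), sep = "\t")

tab <- incremental_model_selection(
  fm$y, as.data.frame(fm[, .(transcription, gc, h3k9me2)]),
  order = c("transcription", "gc", "h3k9me2"))
fwrite(tab, file.path(out, "incremental_models.tsv"), sep = "\t")
cat("incremental model selection (adjusted R^2 / AIC):\n")
print(tab[, .(model, variables, adj_r2 = round(adj_r2, 4),
              aic = round(aic, 1))])
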