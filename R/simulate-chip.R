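#' Simulate IP and input coverage tracks for a chromatin mark
#'
#' Input counts are Poisson(\code{lambda_in}) per window. IP counts are
#' Poisson(\code{lambda_in * 2^e}) where the planted log2 enrichment
#' \code{e} depends on the mark:
#' \itemize{
#'   \item \code{"H2B.8"}: \code{beta0 + betaT*log10(TPM + 0.01) +
#'     betaGC*(GC - 0.5) + class offset + N(0, sigma)} — the histone
#'     variant anticorrelated with transcription and GC content.
#'   \item \code{"H2B.8dIDR"}: same transcription exclusion but no GC
#'     preference and a reversed class preference (heterochromatic TEs
#'     gain, euchromatic TEs lose), emulating the tail-truncated variant.
#'   \item \code{"H3K9me2"}: a two-component class model — windows in
#'     heterochromatic TEs draw \code{N(k9_mu[2], k9_sd)}, all others
#'     \code{N(k9_mu[1], k9_sd)} — producing a bimodal enrichment
#'     histogram over TEs.
#' }
#'
#' @param gm a \code{genome_model}.
#' @param mark one of \code{"H2B.8"}, \code{"H2B.8dIDR"}, \code{"H3K9me2"}.
#' @param params a \code{sim_params}; defaults to the genome's.
#' @param seed integer; defaults to a stream derived from the master seed
#'   and the mark name.
#' @param step window width (bp), a multiple of the genome's base tiling.
#' @return a list with \code{ip} and \code{input} coverage tracks and a
#'   \code{truth} table holding the planted per-window enrichment.
#' @export
simulate_chip_tracks <- function(gm, mark = c("H2B.8", "H2B.8dIDR", "H3K9me2"),
                                 params = gm$params,
                                 seed = derive_seed(params$seed,
                                                    paste0("chip/", mark[1L])),
                                 step = params$track_step) {
  mark <- match.arg(mark)
  cov <- window_covariates(gm, step)
  with_seed(seed, {
    n <- nrow(cov)
    e <- switch(mark,
      "H2B.8" = params$beta0 +
        params$betaT * log10(cov$TPM + 0.01) +
        params$betaGC * (cov$gc - 0.5) +
        unname(params$class_offset[cov$klass]) +
        rnorm(n, 0, params$sigma),
      "H2B.8dIDR" = params$beta0 +
        params$betaT * log10(cov$TPM + 0.01) +
        unname(c(gene = 0, TE_eu = -0.5, TE_het = 1.0,
                 intergenic = 0)[cov$klass]) +
        rnorm(n, 0, params$sigma),
      "H3K9me2" = {
        mu <- ifelse(cov$klass == "TE_het", params$k9_mu[2L], params$k9_mu[1L])
        rnorm(n, mu, params$k9_sd)
      })
    input <- rpois(n, params$lambda_in)
    ip <- rpois(n, params$lambda_in * 2^e)
    grid <- cov[, .(chrom, start, end)]
    list(ip = coverage_track(copy(grid)[, count := ip], step),
         input = coverage_track(copy(grid)[, count := input], step),
         truth = copy(grid)[, `:=`(e = e, klass = cov$klass, gc = cov$gc,
                                   TPM = cov$TPM)])
  })
}

#' Simulate a two-condition expression table
#'
#' Builds the TSV-style expression table consumed by the differential
#' expression filters: per-gene TPM in two conditions, log2 fold-change and
#' q-value. The default planted truth is the null (no differential
#' expression), matching a regime in which the variant does not alter
#' transcription; a subset of genes can be planted as responsive.
#'
#' @param gm a \code{genome_model}.
#' @param n_de number of genes with a planted expression change.
#' @param lfc planted absolute log2 fold-change for those genes.
#' @param seed integer seed.
#' @return a data.table with gene_id, TPM_WT, TPM_mut, log2FC, q.
#' @export
simulate_expression_table <- function(gm, n_de = 0L, lfc = 3,
                                      seed = derive_seed(gm$params$seed,
                                                         "expression")) {
  with_seed(seed, {
    tab <- copy(gm$expression)
    noise <- function(x) x * 2^rnorm(length(x), 0, 0.15)
    tab[, TPM_WT := noise(TPM)]
    tab[, TPM_mut := noise(TPM)]
    tab[, q := runif(.N, 0.2, 1)]
    if (n_de > 0L) {
      idx <- sample(which(tab$TPM > 1), min(n_de, sum(tab$TPM > 1)))
      up <- sample(c(-1, 1), length(idx), replace = TRUE)
      tab[idx, TPM_mut := TPM_WT * 2^(up * lfc)]
      tab[idx, q := runif(length(idx), 0, 0.01)]
    }
    tab[, log2FC := log2((TPM_mut + 0.01) / (TPM_WT + 0.01))]
    tab[, TPM := NULL]
    tab[]
  })
}
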