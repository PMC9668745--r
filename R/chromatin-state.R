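#' Classify transposable elements by H3K9me2 enrichment
#'
#' The bimodal distribution of H3K9me2 log2(IP/input) over TEs supports a
#' single cutoff: elements strictly above it are heterochromatic, all
#' others euchromatic (an element exactly at the cutoff is euchromatic,
#' since the heterochromatic class is defined by strict excess). Elements
#' with missing enrichment are labelled \code{"unassigned"} and counted.
#'
#' @param te_enrichment named numeric vector (or data.table with id,
#'   enrichment) of per-TE H3K9me2 log2 ratios.
#' @param cutoff classification cutoff (log2 units).
#' @return a data.table with id, enrichment, state; attribute
#'   \code{n_unassigned}.
#' @export
classify_tes <- function(te_enrichment, cutoff = 0.7) {
  if (is.data.frame(te_enrichment)) {
    dt <- as.data.table(te_enrichment)[, .(id, enrichment)]
  } else {
    dt <- data.table(id = names(te_enrichment) %||%
                       as.character(seq_along(te_enrichment)),
                     enrichment = as.numeric(te_enrichment))
  }
  dt[, state := fifelse(is.na(enrichment), "unassigned",
                        fifelse(enrichment > cutoff, "heterochromatic",
                                "euchromatic"))]
  setattr(dt, "n_unassigned", sum(dt$state == "unassigned"))
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group genes by expression level
#'
#' Genes with TPM at or below 1 form a \code{"silent"} group; the
#' remaining genes are split into \code{n_groups} equal-count quantile
#' groups by TPM, ties assigned to the lower group. Group \code{"q1"} is
#' the least expressed.
#'
#' @param expr a data.table with gene_id and TPM (or a named numeric
#'   vector).
#' @param n_groups number of quantile groups among expressed genes.
#' @return a data.table with gene_id, TPM, group.
#' @export
group_genes_by_expression <- function(expr, n_groups = 4L) {
  if (!is.data.frame(expr))
    expr <- data.table(gene_id = names(expr), TPM = as.numeric(expr))
  dt <- as.data.table(expr)[, .(gene_id, TPM)]
  dt[, group := "silent"]
  idx <- which(dt$TPM > 1)
  if (length(idx)) {
    if (n_groups > length(idx))
      stop("n_groups exceeds the number of expressed genes")
    dt[idx, group := sprintf("q%d", quantile_groups(TPM, n_groups))]
  }
  dt[]
}

#' Differential-expression threshold filter
#'
#' Retains genes expressed (TPM strictly above \code{tpm_min}) in at least
#' one condition, with \code{|log2FC| >= lfc_min} (inclusive) and
#' \code{q < q_max} (strict), and reports the up/down split by fold-change
#' sign.
#'
#' @param expr data.table with gene_id, TPM_WT, TPM_mut, log2FC, q.
#' @param lfc_min minimal absolute log2 fold-change (>= 0).
#' @param q_max q-value cutoff (strict less-than).
#' @param tpm_min expression cutoff (strict greater-than, any condition).
#' @return a list with retained ids, \code{up} and \code{down} id vectors
#'   and \code{n_expressed} (genes passing the TPM filter alone).
#' @export
de_filter <- function(expr, lfc_min = 2, q_max = 0.05, tpm_min = 1) {
  if (lfc_min < 0) stop("lfc_min must be >= 0")
  dt <- as.data.table(expr)
  if (nrow(dt) == 0L)
    return(list(retained = character(), up = character(),
                down = character(), n_expressed = 0L))
  expressed <- dt$TPM_WT > tpm_min | dt$TPM_mut > tpm_min
  keep <- expressed & abs(dt$log2FC) >= lfc_min & dt$q < q_max
  list(retained = dt$gene_id[keep],
       up = dt$gene_id[keep & dt$log2FC > 0],
       down = dt$gene_id[keep & dt$log2FC < 0],
       n_expressed = sum(expressed))
}
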