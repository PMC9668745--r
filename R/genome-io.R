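#' Write genome artifacts to standard plain-text formats
#'
#' \code{write_genome_fasta} emits a genome sequence whose per-window base
#' composition follows the model's per-window target GC (bases drawn
#' deterministically from the sequence stream of the master seed).
#' \code{write_expression_tsv} writes the two-condition expression table.
#'
#' @param gm a \code{genome_model}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(gm, path) {
  seqs <- with_seed(derive_seed(gm$params$seed, "sequence"), {
    lapply(split(gm$gc, gm$gc$chrom), function(w) {
      w <- w[order(start)]
      unlist(lapply(seq_len(nrow(w)), function(i) {
        n <- w$end[i] - w$start[i]
        gcp <- w$gc[i]
        sample(c("a", "c", "g", "t"), n, replace = TRUE,
               prob = c((1 - gcp) / 2, gcp / 2, gcp / 2, (1 - gcp) / 2))
      }), use.names = FALSE)
    })
  })
  seqinr::write.fasta(seqs, names = names(seqs), file.out = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param expr an expression table from
#'   \code{\link{simulate_expression_table}}.
#' @export
write_expression_tsv <- function(expr, path) {
  fwrite(as.data.table(expr)[, .(gene = gene_id, TPM_WT, TPM_mut, log2FC,
                                 q)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_expression_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  setnames(dt, "gene", "gene_id")
  dt
}
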