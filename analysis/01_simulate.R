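#!/usr/bin/env Rscript
# Generate the full set of synthetic study inputs — annotated genome,
# ChIP/input coverage tracks for the H2B variant and H3K9me2, a
# two-condition expression table, wild-type and ectopic-expression Hi-C
# matrices, and 3D nucleus stacks — and write them to results/synthetic/
# in the plain-text formats the rest of the workflow consumes.

suppressMessages({ library(spermchrom); library(data.table) })

seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

p <- sim_params(seed = seed)
write_manifest(p, file.path(out, "manifest.yaml"))

gm <- simulate_genome(p)
cat("genome:", nrow(gm$chromosomes), "chromosomes;",
    nrow(gm$features), "features\n")
print(gm$features[, .N, by = klass])
write_features_bed(gm$features, file.path(out, "features.bed"))
write_genome_fasta(gm, file.path(out, "genome.fa"))
fwrite(gm$pericentromere, file.path(out, "pericentromere.bed"),
       sep = "\t", col.names = FALSE)

for (mark in c("H2B.8", "H3K9me2")) {
  tr <- simulate_chip_tracks(gm, mark)
  tag <- gsub("[.]", "", mark)
  write_bedgraph(tr$ip, file.path(out, paste0(tag, "_ip.bedGraph")))
  write_bedgraph(tr$input, file.path(out, paste0(tag, "_input.bedGraph")))
  cat(mark, "tracks written; IP library",
      format(attr(tr$ip, "library_size"), big.mark = ","), "\n")
}

expr <- simulate_expression_table(gm)
write_expression_tsv(expr, file.path(out, "expression.tsv"))
cat("expression table:", nrow(expr), "genes;",
    sum(expr$TPM_WT > 1), "expressed (TPM > 1) in WT\n")

# Hi-C: plant the genotype effect on the generator's own enrichment field
tr <- simulate_chip_tracks(gm, "H2B.8")
tru <- enrichment_track(tr$truth[, .(chrom, start, end, value = e)], 50L)
h <- bin_enrichment(tru, p$hic_binsize, drop_short = FALSE)$value
for (gt in c("WT", "H2B8_ectopic")) {
  m <- simulate_hic(gm, gt, h, p)
  write_contacts(m, file.path(out, paste0("hic_", gt, "_bins.bed")),
                 file.path(out, paste0("hic_", gt, "_coo.txt")))
  cat("Hi-C", gt, ":", format(m$total, big.mark = ","), "contacts\n")
}

st <- simulate_nucleus_stack(p, seed = seed)
paths <- write_image_stack(st, out, "nucleus")
cat("image stack written:", paste(basename(paths), collapse = ", "), "\n")
cat("done; artifacts under", out, "\n")
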