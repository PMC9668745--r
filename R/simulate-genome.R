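#' Simulate an annotated genome with planted chromatin structure
#'
#' Generates a small genome whose layout mirrors the organisation relevant
#' to pericentromeric chromatin biology: heterochromatic transposable
#' elements (TE_het) concentrated inside pericentromeres, euchromatic TEs
#' (TE_eu) enriched at pericentromere edges and scattered along arms, genes
#' on the arms, and AT-rich euchromatic TEs (lower GC than heterochromatic
#' TEs). A stated fraction of genes is silent (TPM 0); the rest draw
#' log-normal TPM values.
#'
#' All coordinates are 0-based half-open. Features are non-overlapping.
#' Per-window GC fractions are tiled at \code{params$track_step}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return an object of class \code{genome_model}: a list with
#'   \code{chromosomes}, \code{pericentromere}, \code{features}, \code{gc}
#'   (fixed-step windows) and \code{expression} (gene TPM) tables.
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$chrom_length < params$track_step)
    stop("chromosome shorter than one window")
  seed <- derive_seed(params$seed, "genome")
  with_seed(seed, {
    chroms <- data.table(
      chrom = sprintf("chr%d", seq_len(params$n_chrom)),
      length = as.integer(rep(params$chrom_length, params$n_chrom)))
    peri_half <- params$chrom_length * params$peri_frac / 2
    peri <- chroms[, .(chrom,
                       start = as.integer(round(length / 2 - peri_half)),
                       end = as.integer(round(length / 2 + peri_half)))]

    feats <- rbindlist(lapply(seq_len(nrow(chroms)), function(i) {
      place_features(chroms$length[i], peri$start[i], peri$end[i],
                     chroms$chrom[i])
    }))
    feats[, id := sprintf("%s%05d",
                          c(gene = "AT_G", TE_eu = "TE_EU", TE_het = "TE_HT")[klass],
                          seq_len(.N)), by = klass]

    wins <- tile_windows(chroms, params$track_step)[, short := NULL][]
    wins <- assign_window_class(wins, feats)
    mu <- params$gc_mean[wins$klass]
    wins[, gc := pmin(0.95, pmax(0.05, rnorm(.N, mu, params$gc_sd)))]

    genes <- feats[klass == "gene"]
    expr <- data.table(gene_id = genes$id)
    silent <- runif(nrow(expr)) < params$silent_frac
    expr[, TPM := ifelse(silent, 0, rlnorm(.N, log(10), 1.3))]

    gm <- structure(list(chromosomes = chroms, pericentromere = peri,
                         features = feats,
                         gc = wins[, .(chrom, start, end, klass, gc)],
                         expression = expr, params = params),
                    class = "genome_model")
    validate_genome_model(gm)
    gm
  })
}

# Sequential left-to-right placement: feature type drawn from position-
# dependent weights (pericentromere core, pericentromere edges, arms),
# separated by exponential gaps. Guarantees non-overlap by construction.
place_features <- function(len, peri_start, peri_end, chrom) {
  edge <- 0.1 * (peri_end - peri_start)  # pericentromere-edge zone width
  pos <- 0
  out <- vector("list", 4096L)
  n <- 0L
  while (pos < len) {
    pos <- pos + round(rexp2(300))               # intergenic gap
    in_peri <- pos >= peri_start && pos < peri_end
    near_edge <- !in_peri &&
      (abs(pos - peri_start) < edge || abs(pos - peri_end) < edge)
    w <- if (in_peri) c(gene = 0.05, TE_eu = 0.20, TE_het = 0.75)
         else if (near_edge) c(gene = 0.15, TE_eu = 0.70, TE_het = 0.15)
         else c(gene = 0.60, TE_eu = 0.35, TE_het = 0.05)
    klass <- sample(names(w), 1L, prob = w)
    flen <- round(rlnorm(1, log(if (klass == "gene") 1500 else 900), 0.4))
    if (pos + flen > len) break
    n <- n + 1L
    out[[n]] <- data.table(chrom = chrom, start = as.integer(pos),
                           end = as.integer(pos + flen),
                           strand = sample(c("+", "-"), 1L), klass = klass)
    pos <- pos + flen
  }
  rbindlist(out[seq_len(n)])
}

rexp2 <- function(mean) stats::rexp(1, 1 / mean)

# Window class by precedence gene > TE_eu > TE_het > intergenic, decided by
# any-overlap of the window with a feature of that class.
assign_window_class <- function(wins, feats) {
  wins <- copy(wins)[, klass := "intergenic"]
  for (kl in c("TE_het", "TE_eu", "gene")) {
    f <- feats[klass == kl, .(chrom, start, end)]
    if (nrow(f) == 0L) next
    hit <- overlap_pairs(f, wins)
    wins[unique(hit$yid), klass := kl]
  }
  wins
}

#' Validate genome-model invariants
#'
#' Checks 0-based half-open intervals within chromosome bounds, per-class
#' non-overlap of features, one TPM entry per gene and complete GC tiling.
#'
#' @param gm a \code{genome_model}.
#' @return \code{TRUE} invisibly; stops on violation.
#' @export
validate_genome_model <- function(gm) {
  stopifnot(inherits(gm, "genome_model"))
  len <- setNames(gm$chromosomes$length, gm$chromosomes$chrom)
  check_intervals(gm$features, len, "feature")
  check_intervals(gm$pericentromere, len, "pericentromere")
  check_intervals(gm$gc, len, "gc window")
  ov <- gm$features[order(chrom, start),
                    .(bad = any(start[-1] < head(end, -1))),
                    by = .(chrom, klass)]
  if (any(ov$bad)) stop("features overlap within a class")
  genes <- gm$features[klass == "gene", id]
  if (!setequal(genes, gm$expression$gene_id) ||
      anyDuplicated(gm$expression$gene_id))
    stop("every gene must have exactly one TPM entry")
  if (any(gm$expression$TPM < 0)) stop("TPM must be non-negative")
  if (any(gm$gc$gc < 0 | gm$gc$gc > 1)) stop("gc must lie in [0, 1]")
  invisible(TRUE)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic genome:", nrow(x$chromosomes), "chromosomes,",
      sum(x$chromosomes$length) / 1e6, "Mb total\n")
  print(x$features[, .N, by = klass])
  invisible(x)
}

#' Per-window covariates at an arbitrary multiple of the base step
#'
#' Aggregates the genome's base-resolution GC tiling to \code{step}-bp
#' windows (mean GC), attaches the window class (precedence gene > TE_eu >
#' TE_het > intergenic) and the TPM of the overlapping gene (0 outside
#' genes).
#'
#' @param gm a \code{genome_model}.
#' @param step window width in bp; must be a multiple of the base tiling.
#' @return a data.table with chrom, start, end, gc, klass, TPM.
#' @export
window_covariates <- function(gm, step = gm$params$track_step) {
  base <- gm$params$track_step
  if (step %% base != 0) stop("step must be a multiple of the base tiling")
  clen <- setNames(gm$chromosomes$length, gm$chromosomes$chrom)
  w <- copy(gm$gc)[, wstart := (start %/% step) * as.integer(step)]
  w <- w[wstart + step <= clen[chrom]]  # drop trailing partial aggregate
  out <- w[, .(start = wstart[1L], end = wstart[1L] + as.integer(step),
               gc = mean(gc)), by = .(chrom, wstart)][, wstart := NULL]
  out <- assign_window_class(out, gm$features)
  genes <- merge(gm$features[klass == "gene", .(chrom, start, end, id)],
                 gm$expression, by.x = "id", by.y = "gene_id")
  out[, TPM := 0]
  if (nrow(genes)) {
    hit <- overlap_pairs(genes, out)
    out[hit$yid, TPM := genes$TPM[hit$xid]]
  }
  out[order(chrom, start)]
}

#' Randomly shuffle a residue sequence
#'
#' Returns a uniformly random permutation of the input characters,
#' preserving the residue multiset; deterministic per seed. Used to build
#' scrambled control sequences for intrinsically disordered regions.
#'
#' @param seq non-empty character string.
#' @param seed integer seed.
#' @return the scrambled string.
#' @export
scramble_sequence <- function(seq, seed = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("sequence must be non-empty")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  with_seed(seed, paste(sample(ch), collapse = ""))
}

#' Bundled reference sequences
#'
#' \code{scrambled_idr_sequence()} returns the published scrambled
#' 93-residue intrinsically-disordered-region control peptide;
#' \code{widom_601_repeat()} returns the 177-bp nucleosome-positioning
#' repeat unit used to assemble 12-mer nucleosomal arrays.
#'
#' @return a character string.
#' @export
scrambled_idr_sequence <- function() {
  readLines(system.file("extdata", "scrambled_idr.txt",
                        package = "spermchrom"))[1L]
}

#' @rdname scrambled_idr_sequence
#' @export
widom_601_repeat <- function() {
  readLines(system.file("extdata", "widom_601_repeat.txt",
                        package = "spermchrom"))[1L]
}
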