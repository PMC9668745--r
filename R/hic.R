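#' Sparse symmetric contact matrix
#'
#' Stores binned Hi-C contacts as upper-triangle triplets (i <= j, 0-based
#' bin indices) over a bin table; symmetry is implicit. A trailing bin
#' shorter than the bin size is kept and flagged.
#'
#' @param bins data.table with chrom, start, end, index (0-based) and
#'   optional short flag.
#' @param counts data.table with i, j, count (i <= j after folding).
#' @param binsize bin width in bp.
#' @param tidy set when counts are already folded, unique and sorted
#'   (skips the folding pass; used by the simulator).
#' @return an object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(bins, counts, binsize, tidy = FALSE) {
  bins <- as.data.table(bins)
  if (!"short" %in% names(bins)) bins[, short := end - start < binsize]
  counts <- as.data.table(counts)[, .(i, j, count)]
  if (any(counts$count < 0)) stop("negative count")
  if (nrow(counts) && !tidy) {
    ii <- pmin(counts$i, counts$j)
    jj <- pmax(counts$i, counts$j)
    counts <- data.table(i = ii, j = jj, count = counts$count)
    counts <- counts[, .(count = sum(count)), keyby = .(i, j)]
    if (min(counts$i) < 0L || max(counts$j) > max(bins$index))
      stop("triplet indices outside the bin table")
  }
  structure(list(bins = bins[order(index)], counts = counts,
                 binsize = as.integer(binsize),
                 total = sum(counts$count)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix:", nrow(x$bins), "bins of", x$binsize, "bp,",
      format(x$total, big.mark = ","), "contacts\n")
  invisible(x)
}

#' Tile a genome into Hi-C bins
#'
#' Full-coverage tiling: a trailing bin shorter than \code{binsize} is
#' kept and flagged.
#'
#' @param gm a \code{genome_model} (or a chromosomes data.table).
#' @param binsize bin width in bp.
#' @return a bin table with 0-based \code{index}.
#' @export
hic_bins <- function(gm, binsize) {
  chroms <- if (inherits(gm, "genome_model")) gm$chromosomes else gm
  bins <- tile_windows(chroms, binsize, drop_short = FALSE)
  bins[, index := .I - 1L]
  bins[]
}

#' Read / write a contact matrix as bins BED + COO triplets
#'
#' The bin table is BED4 (chrom, start, end, index); triplets are
#' tab-separated \code{bin_i bin_j count} with i <= j. Duplicate and
#' lower-triangle entries are folded on read.
#'
#' @param bins_path,triplets_path file paths.
#' @param binsize bin width in bp.
#' @param m a \code{contact_matrix}.
#' @return \code{load_contacts} returns a \code{contact_matrix}.
#' @export
load_contacts <- function(bins_path, triplets_path, binsize) {
  bins <- fread(bins_path, header = FALSE,
                col.names = c("chrom", "start", "end", "index"))
  trip <- if (file.size(triplets_path) == 0) {
    data.table(i = integer(), j = integer(), count = numeric())
  } else fread(triplets_path, header = FALSE,
               col.names = c("i", "j", "count"))
  contact_matrix(bins, trip, binsize)
}

#' @rdname load_contacts
#' @export
write_contacts <- function(m, bins_path, triplets_path) {
  fwrite(m$bins[, .(chrom, start, end, index)], bins_path, sep = "\t",
         col.names = FALSE)
  fwrite(m$counts, triplets_path, sep = "\t", col.names = FALSE)
  invisible(c(bins_path, triplets_path))
}

#' Simulate a Hi-C contact matrix with planted genotype effects
#'
#' Expected intra-chromosomal counts follow a power-law distance decay,
#' \code{mu_ij = c (d_ij + d0)^-gamma}, scaled so the wild-type total is
#' \code{hic_depth}; inter-chromosomal pairs sit at the decay level of
#' \code{inter_distance}. For the ectopic-expression genotype three local
#' effects are planted, each scaling with the mean histone-variant
#' enrichment of the two bins (negative enrichment clipped to zero):
#' short-range intra pairs (within \code{hic_band}) gain
#' \code{1 + gamma_short * hbar}; pericentromere-arm intra pairs gain
#' \code{1 + gamma_peri * hbar}; inter-chromosomal pericentromere pairs
#' lose \code{1 - delta_interperi}. Counts are Poisson.
#'
#' @param gm a \code{genome_model}.
#' @param genotype \code{"WT"} or \code{"H2B8_ectopic"}.
#' @param enrichment numeric vector of per-bin enrichment aligned to the
#'   bin table (e.g. from \code{\link{bin_enrichment}}); missing values
#'   are treated as zero effect.
#' @param params a \code{sim_params}.
#' @param seed integer seed.
#' @param noise draw Poisson counts (default) or return the expected
#'   (non-integer) matrix.
#' @return a \code{contact_matrix}.
#' @export
simulate_hic <- function(gm, genotype = c("WT", "H2B8_ectopic"),
                         enrichment = NULL, params = gm$params,
                         seed = derive_seed(params$seed,
                                            paste0("hic/", genotype[1L])),
                         noise = TRUE) {
  genotype <- match.arg(genotype)
  bins <- hic_bins(gm, params$hic_binsize)
  nb <- nrow(bins)
  h <- if (is.null(enrichment)) rep(0, nb) else pmax(enrichment, 0)
  h[is.na(h)] <- 0
  if (length(h) != nb) stop("enrichment must align with the bin table")
  peri <- bin_in_pericentromere(bins, gm$pericentromere)

  pairs <- all_bin_pairs(bins)
  d <- fifelse(pairs$intra, (pairs$j - pairs$i) * params$hic_binsize,
               params$inter_distance)
  w <- (d + params$d0)^(-params$decay_gamma)
  scale <- params$hic_depth / sum(w)
  mult <- rep(1, length(pairs$i))
  if (genotype == "H2B8_ectopic") {
    hbar <- (h[pairs$i + 1L] + h[pairs$j + 1L]) / 2
    band <- pairs$intra & d >= params$hic_band[1L] & d <= params$hic_band[2L]
    mult[band] <- mult[band] * (1 + params$gamma_short * hbar[band])
    pa <- pairs$intra & xor(peri[pairs$i + 1L], peri[pairs$j + 1L])
    mult[pa] <- mult[pa] * (1 + params$gamma_peri * hbar[pa])
    pp <- !pairs$intra & peri[pairs$i + 1L] & peri[pairs$j + 1L]
    mult[pp] <- mult[pp] * (1 - params$delta_interperi)
  }
  mu <- scale * w * mult
  cnt <- if (noise) with_seed(seed, rpois(length(mu), mu)) else mu
  keep <- cnt > 0
  contact_matrix(bins,
                 data.table(i = pairs$i[keep], j = pairs$j[keep],
                            count = cnt[keep]),
                 params$hic_binsize, tidy = TRUE)
}

# Enumerate all unordered bin pairs i <= j with an intra flag.
all_bin_pairs <- function(bins) {
  idx <- bins$index
  n <- length(idx)
  i <- rep.int(idx, n - seq_len(n) + 1L)
  j <- sequence(n:1, from = seq_len(n)) - 1L
  chrom_id <- as.integer(factor(bins$chrom, levels = unique(bins$chrom)))
  list(i = i, j = j, intra = chrom_id[i + 1L] == chrom_id[j + 1L])
}

bin_in_pericentromere <- function(bins, peri) {
  inside <- rep(FALSE, nrow(bins))
  hits <- overlap_pairs(peri[, .(chrom, start, end)],
                        bins[, .(chrom, start, end)])
  inside[unique(hits$yid)] <- TRUE
  inside
}

#' Scale two contact matrices to a common depth
#'
#' Each matrix is multiplied by a scalar so both totals equal the mean of
#' the two original totals; within-matrix structure is unchanged.
#'
#' @param A,B \code{contact_matrix} objects.
#' @return a list with the two rescaled matrices.
#' @export
depth_normalize <- function(A, B) {
  target <- (A$total + B$total) / 2
  rescale <- function(m, f) {
    m$counts <- copy(m$counts)[, count := count * f]
    m$total <- m$total * f
    m
  }
  list(A = rescale(A, target / A$total), B = rescale(B, target / B$total))
}

#' Expected contact frequency by genomic distance
#'
#' For every intra-chromosomal distance (a multiple of the bin size,
#' measured between bin starts), the mean count over all bin pairs at that
#' distance across chromosomes, zero entries included. Mass is conserved:
#' \code{sum(expected * n_pairs)} equals the total intra-chromosomal
#' contacts.
#'
#' @param m a \code{contact_matrix}.
#' @return a data.table with distance (bp), expected, n_pairs.
#' @export
expected_by_distance <- function(m) {
  bins <- m$bins
  per_chrom <- bins[, .N, by = chrom]
  if (all(per_chrom$N < 1L) || nrow(per_chrom) == 0L)
    stop("matrix has no intra-chromosomal pairs")
  max_n <- max(per_chrom$N)
  # pair counts per distance (in bins): sum over chroms of (n - d)
  n_pairs <- vapply(0:(max_n - 1L), function(d)
    sum(pmax(per_chrom$N - d, 0L)), numeric(1))
  cnt <- m$counts
  if (nrow(cnt)) {
    ci <- bins$chrom[cnt$i + 1L]
    cj <- bins$chrom[cnt$j + 1L]
    intra <- ci == cj
    dsum <- data.table(d = cnt$j[intra] - cnt$i[intra],
                       count = cnt$count[intra])
    dsum <- dsum[, .(count = sum(count)), keyby = d]
  } else dsum <- data.table(d = integer(), count = numeric())
  sums <- numeric(max_n)
  if (nrow(dsum)) sums[dsum$d + 1L] <- dsum$count
  data.table(distance = (0:(max_n - 1L)) * m$binsize,
             expected = sums / n_pairs, n_pairs = n_pairs)
}

#' Compare two depth-matched contact matrices
#'
#' Fold change is reported as \code{log2((A + alpha)/(B + alpha))};
#' difference as \code{A - B}. Cells absent from both matrices are zero
#' under either mode and stay implicit.
#'
#' @param A,B \code{contact_matrix} objects on identical bin tables
#'   (depth-normalise first; see \code{\link{depth_normalize}}).
#' @param mode \code{"fold_change"} or \code{"difference"}.
#' @param alpha pseudocount for fold change.
#' @return a list (class \code{contact_comparison}) with bins, sparse
#'   \code{cells} (i, j, value), binsize and mode.
#' @export
compare_matrices <- function(A, B, mode = c("fold_change", "difference"),
                             alpha = 0.5) {
  mode <- match.arg(mode)
  if (!identical(A$bins[, .(chrom, start, end, index)],
                 B$bins[, .(chrom, start, end, index)]))
    stop("bin tables differ")
  a <- copy(A$counts); b <- copy(B$counts)
  setnames(a, "count", "a"); setnames(b, "count", "b")
  cells <- merge(a, b, by = c("i", "j"), all = TRUE)
  cells[is.na(a), a := 0]
  cells[is.na(b), b := 0]
  cells[, value := if (mode == "fold_change")
    log2((a + alpha) / (b + alpha)) else a - b]
  structure(list(bins = A$bins, cells = cells[, .(i, j, value)],
                 binsize = A$binsize, mode = mode),
            class = "contact_comparison")
}

#' Quantile-pair summary of interaction change against enrichment
#'
#' Bins are ranked by their enrichment value and cut into
#' \code{n_quantiles} equal-count groups (ties to the lower group). For
#' every unordered quantile pair (a, b) the mean of the comparison value
#' over the masked intra-chromosomal bin pairs with one bin in each group
#' is computed, implicit zero cells included. Masks: \code{"short_range"}
#' keeps pairs with start distance inside \code{band} (inclusive);
#' \code{"peri_arm"} keeps intra pairs with exactly one bin inside a
#' pericentromere. The summary correlation is Spearman's rho between the
#' quantile-index sum (a + b) and the cell mean over non-empty cells
#' (\code{rho_level = "pair"} instead correlates the per-pair enrichment
#' mean with the per-pair value).
#'
#' @param D a \code{contact_comparison} (typically mode "difference" at
#'   1-kb bins).
#' @param h numeric per-bin enrichment aligned to the bin table.
#' @param n_quantiles number of enrichment quantiles.
#' @param mask \code{"short_range"} or \code{"peri_arm"}.
#' @param band inclusive distance band in bp for the short-range mask.
#' @param pericentromere data.table (chrom, start, end), required for the
#'   peri_arm mask.
#' @param rho_level \code{"cell"} (default) or \code{"pair"}.
#' @return a list (class \code{quantile_pair_summary}) with the q x q
#'   matrix of cell means, cell pair counts, quantile assignment, rho and
#'   n_quantiles.
#' @export
quantile_pair_summary <- function(D, h, n_quantiles = 20L,
                                  mask = c("short_range", "peri_arm"),
                                  band = c(2e5, 1.1e6),
                                  pericentromere = NULL,
                                  rho_level = c("cell", "pair")) {
  mask <- match.arg(mask)
  rho_level <- match.arg(rho_level)
  bins <- D$bins
  nb <- nrow(bins)
  if (length(h) != nb) stop("enrichment must align with the bin table")
  if (n_quantiles > sum(!is.na(h)))
    stop("n_quantiles exceeds the number of bins")
  q <- rep(NA_integer_, nb)
  q[!is.na(h)] <- quantile_groups(h[!is.na(h)], n_quantiles)

  pairs <- masked_pairs(bins, D$binsize, mask, band, pericentromere)
  if (nrow(pairs) == 0L) stop("mask selects no bin pairs")
  vals <- merge(pairs, D$cells, by = c("i", "j"), all.x = TRUE)
  vals[is.na(value), value := 0]
  vals[, `:=`(qa = pmin(q[i + 1L], q[j + 1L]),
              qb = pmax(q[i + 1L], q[j + 1L]),
              hbar = (h[i + 1L] + h[j + 1L]) / 2)]
  vals <- vals[!is.na(qa)]
  cellagg <- vals[, .(mean = mean(value), n = .N), keyby = .(qa, qb)]

  mat <- matrix(NA_real_, n_quantiles, n_quantiles)
  npair <- matrix(0L, n_quantiles, n_quantiles)
  mat[cbind(cellagg$qa, cellagg$qb)] <- cellagg$mean
  mat[cbind(cellagg$qb, cellagg$qa)] <- cellagg$mean
  npair[cbind(cellagg$qa, cellagg$qb)] <- cellagg$n
  npair[cbind(cellagg$qb, cellagg$qa)] <- cellagg$n

  rho <- if (rho_level == "cell") {
    tryCatch(spearman_cor(cellagg$qa + cellagg$qb, cellagg$mean)$statistic,
             warning = function(w) { warning(w); NA_real_ })
  } else {
    tryCatch(spearman_cor(vals$hbar, vals$value)$statistic,
             warning = function(w) { warning(w); NA_real_ })
  }
  structure(list(matrix = mat, n_pairs = npair, quantile = q, rho = rho,
                 n_quantiles = n_quantiles, mask = mask),
            class = "quantile_pair_summary")
}

# Enumerate masked intra-chromosomal bin pairs (i < j, 0-based).
masked_pairs <- function(bins, binsize, mask, band, pericentromere) {
  out <- vector("list", length(unique(bins$chrom)))
  k <- 0L
  if (mask == "peri_arm") {
    if (is.null(pericentromere))
      stop("peri_arm mask needs a pericentromere annotation")
    peri <- bin_in_pericentromere(bins, pericentromere)
  }
  for (ch in unique(bins$chrom)) {
    idx <- bins$index[bins$chrom == ch]
    n <- length(idx)
    if (mask == "short_range") {
      dmin <- max(1L, as.integer(ceiling(band[1L] / binsize)))
      dmax <- as.integer(floor(band[2L] / binsize))
      if (dmax < dmin) next
      dd <- dmin:dmax
      reps <- pmax(n - dd, 0L)
      i <- unlist(lapply(seq_along(dd), function(t)
        if (reps[t] > 0L) idx[seq_len(reps[t])] else integer()),
        use.names = FALSE)
      j <- unlist(lapply(seq_along(dd), function(t)
        if (reps[t] > 0L) idx[seq_len(reps[t]) + dd[t]] else integer()),
        use.names = FALSE)
      if (length(i)) { k <- k + 1L; out[[k]] <- data.table(i = i, j = j) }
    } else {
      p <- peri[bins$chrom == ch]
      a <- idx[p]; b <- idx[!p]
      if (length(a) && length(b)) {
        g <- CJ(x = a, y = b)
        k <- k + 1L
        out[[k]] <- g[, .(i = pmin(x, y), j = pmax(x, y))]
      }
    }
  }
  if (k == 0L) data.table(i = integer(), j = integer())
  else rbindlist(out[seq_len(k)])
}

#' Permutation test for the quantile-coupling correlation
#'
#' Permutes the cell means across quantile-pair cells and recomputes the
#' summary correlation, giving a null distribution for rho under no
#' coupling between enrichment quantile and interaction change.
#'
#' @param qps a \code{quantile_pair_summary}.
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @return a list with rho, p_value (two-sided) and the null sample.
#' @export
quantile_rho_permutation <- function(qps, n_perm = 1000L, seed = 1L) {
  idx <- which(upper.tri(qps$matrix, diag = TRUE) & !is.na(qps$matrix),
               arr.ind = TRUE)
  means <- qps$matrix[idx]
  qsum <- idx[, 1L] + idx[, 2L]
  obs <- suppressWarnings(spearman_cor(qsum, means)$statistic)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(r)
    suppressWarnings(spearman_cor(qsum, sample(means))$statistic),
    numeric(1)))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(rho = obs, p_value = p, null = null)
}

#' Hi-C map resolution criterion
#'
#' The fraction of bins whose total contact sum (each interaction counted
#' toward both partners, the diagonal once) strictly exceeds
#' \code{min_contacts}; the resolution is achieved when that fraction
#' reaches \code{pass_frac}.
#'
#' @param m a \code{contact_matrix}.
#' @param min_contacts per-bin contact threshold (strict greater-than).
#' @param pass_frac required fraction of passing bins.
#' @return a list with fraction, achieved, bin_sums.
#' @export
estimate_resolution <- function(m, min_contacts = 1000, pass_frac = 0.8) {
  nb <- nrow(m$bins)
  sums <- numeric(nb)
  cnt <- m$counts
  if (nrow(cnt)) {
    ti <- tapply(cnt$count, cnt$i, sum)
    sums[as.integer(names(ti)) + 1L] <- sums[as.integer(names(ti)) + 1L] + ti
    off <- cnt[i != j]
    if (nrow(off)) {
      tj <- tapply(off$count, off$j, sum)
      sums[as.integer(names(tj)) + 1L] <- sums[as.integer(names(tj)) + 1L] + tj
    }
  }
  frac <- mean(sums > min_contacts)
  list(fraction = frac, achieved = frac >= pass_frac, bin_sums = sums)
}
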