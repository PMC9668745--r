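#' Four-stage peak calling on window enrichment
#'
#' Implements the bespoke peak procedure for the sperm histone-variant
#' ChIP data: (1) retain 50-bp windows with enrichment strictly greater
#' than \code{threshold}; (2) merge retained windows whose edge-to-edge gap
#' is at most \code{merge_gap} bp (adjacent windows, gap 0, merge); (3)
#' drop merged regions shorter than \code{min_len} bp; (4) re-score every
#' surviving region from the summed IP and input counts of all windows it
#' spans, \code{log2((sum_ip + alpha)/(sum_in + alpha))} on the CPM or raw
#' scale, and keep regions scoring at least \code{threshold}.
#'
#' Stage 1 is strictly greater-than and stage 4 keeps ties at the
#' threshold, following the asymmetric retention/discard wording of the
#' original procedure.
#'
#' @param e50 an \code{enrichment_track}, normally on a 50-bp grid (other
#'   grids are accepted with a warning).
#' @param ip,input the coverage tracks \code{e50} was computed from.
#' @param threshold log2 enrichment cutoff (stages 1 and 4).
#' @param merge_gap maximal gap (bp, edge-to-edge) merged across.
#' @param min_len minimal region length (bp).
#' @param alpha pseudocount for the region re-score.
#' @param scale \code{"cpm"} or \code{"raw"}; use the scale the enrichment
#'   was computed on.
#' @return a \code{peak_set}: data.table of chrom, start, end, score,
#'   sorted and non-overlapping with pairwise gaps above \code{merge_gap}.
#' @export
call_h2b8_peaks <- function(e50, ip, input, threshold = 1.2,
                            merge_gap = 150, min_len = 200, alpha = 0.5,
                            scale = c("cpm", "raw")) {
  scale <- match.arg(scale)
  if (threshold < 0 || merge_gap < 0 || min_len < 0 || alpha < 0)
    stop("negative parameters are not allowed")
  if (!same_grid(e50, ip) || !same_grid(e50, input))
    stop("enrichment and count tracks must share one grid")
  if (!identical(track_step(e50), 50L))
    warning("enrichment grid is not 50 bp; proceeding")

  keep <- !is.na(e50$value) & e50$value > threshold
  regions <- merge_kept_windows(e50[keep, .(chrom, start, end)], merge_gap)
  regions <- regions[end - start >= min_len]
  if (nrow(regions) == 0L) return(peak_set(regions[, score := numeric(0)]))

  lib_ip <- attr(ip, "library_size")
  lib_in <- attr(input, "library_size")
  hits <- overlap_pairs(ip[, .(chrom, start, end)], regions)
  sums <- data.table(region = hits$yid,
                     ip = ip$count[hits$xid], input = input$count[hits$xid])
  sums <- sums[, .(ip = sum(ip), input = sum(input)), keyby = region]
  score <- log2((scaled_counts(sums$ip, lib_ip, scale) + alpha) /
                (scaled_counts(sums$input, lib_in, scale) + alpha))
  regions <- regions[sums$region][, score := score]
  peak_set(regions[score >= threshold])
}

# Merge sorted intervals whose gap (next start - previous end) is <= gap.
merge_kept_windows <- function(iv, gap) {
  if (nrow(iv) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  iv <- iv[order(chrom, start)]
  new_chrom <- c(TRUE, iv$chrom[-1L] != head(iv$chrom, -1L))
  new_run <- new_chrom | c(TRUE, iv$start[-1L] - head(iv$end, -1L) > gap)
  run <- cumsum(new_run)
  iv[, .(start = min(start), end = max(end)), by = .(chrom, run = run)][
    , run := NULL][]
}

#' Peak-set constructor and validator
#'
#' @param dt a data.table with chrom, start, end, score.
#' @param min_len,threshold,merge_gap invariants enforced by
#'   \code{validate_peak_set}.
#' @return a \code{peak_set} data.table.
#' @export
peak_set <- function(dt) {
  dt <- as.data.table(dt)[, .(chrom, start, end, score)][order(chrom, start)]
  setattr(dt, "class", c("peak_set", class(dt)))
  dt
}

#' @rdname peak_set
#' @export
validate_peak_set <- function(dt, min_len = 200, threshold = 1.2,
                              merge_gap = 150) {
  stopifnot(inherits(dt, "peak_set"))
  if (nrow(dt) == 0L) return(invisible(TRUE))
  if (any(dt$end - dt$start < min_len)) stop("peak shorter than min_len")
  if (any(dt$score < threshold)) stop("peak score below threshold")
  gaps <- dt[, .(gap = start[-1L] - head(end, -1L)), by = chrom]$gap
  if (length(gaps) && any(gaps <= merge_gap))
    stop("peaks closer than merge_gap")
  invisible(TRUE)
}

#' Partition peak coverage among annotation classes
#'
#' Divides every peak into \code{subwindow}-bp pieces (a shorter remainder
#' piece is kept) and assigns each piece to exactly one class with
#' precedence gene > euchromatic TE > heterochromatic TE > intergenic,
#' decided by any overlap of the piece. Base-pair totals conserve the
#' total peak length exactly.
#'
#' @param peaks a \code{peak_set}.
#' @param gm a \code{genome_model}.
#' @param subwindow piece width in bp.
#' @return a list with \code{coverage} (bp per class), \code{total_bp} and
#'   \code{genome_fraction} (peak bp over genome bp).
#' @export
partition_peak_coverage <- function(peaks, gm, subwindow = 50L) {
  clen <- setNames(gm$chromosomes$length, gm$chromosomes$chrom)
  classes <- c("gene", "TE_eu", "TE_het", "intergenic")
  empty <- setNames(rep(0, 4L), classes)
  if (nrow(peaks) == 0L)
    return(list(coverage = empty, total_bp = 0, genome_fraction = 0))
  check_intervals(peaks, clen, "peak")
  pieces <- peaks[, {
    s <- seq.int(start, end - 1L, by = subwindow)
    .(start = as.integer(s), end = as.integer(pmin(s + subwindow, end)))
  }, by = .(chrom, pstart = start)][, .(chrom, start, end)]
  pieces[, klass := "intergenic"]
  for (kl in c("TE_het", "TE_eu", "gene")) {
    f <- gm$features[klass == kl, .(chrom, start, end)]
    if (nrow(f) == 0L) next
    hit <- overlap_pairs(f, pieces)
    pieces[unique(hit$yid), klass := kl]
  }
  cov <- pieces[, .(bp = sum(end - start)), by = klass]
  out <- empty
  out[cov$klass] <- cov$bp
  list(coverage = out, total_bp = sum(out),
       genome_fraction = sum(peaks$end - peaks$start) / sum(clen))
}

#' Feature overlap under a minimum-coverage rule
#'
#' A feature counts as overlapped when the union of peak base pairs inside
#' it reaches \code{min_frac} of the feature length (boundary inclusive).
#'
#' @param peaks a \code{peak_set} (non-overlapping intervals).
#' @param features a data.table with chrom, start, end, id.
#' @param min_frac minimal covered fraction, in (0, 1].
#' @return a data.table with id, covered_bp, frac, overlap (logical).
#' @export
feature_overlap <- function(peaks, features, min_frac = 0.25) {
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  f <- as.data.table(features)
  out <- f[, .(id, len = end - start)]
  out[, covered_bp := 0L]
  if (nrow(peaks)) {
    # union of peak bp: collapse any overlapping intervals first
    peaks <- merge_kept_windows(peaks[, .(chrom, start, end)], -1L)
    hits <- overlap_pairs(peaks[, .(chrom, start, end)], f)
    if (nrow(hits)) {
      ov <- data.table(
        yid = hits$yid,
        bp = pmin(peaks$end[hits$xid], f$end[hits$yid]) -
             pmax(peaks$start[hits$xid], f$start[hits$yid]))
      ov <- ov[, .(bp = sum(bp)), by = yid]
      out[ov$yid, covered_bp := ov$bp]
    }
  }
  out[, frac := covered_bp / len]
  out[, overlap := covered_bp >= min_frac * len]
  out[, len := NULL]
  out[]
}

#' Read/write peaks as BED6+score
#'
#' Columns: chrom, start, end, name, score, strand (`.`).
#' @param peaks a \code{peak_set}.
#' @param path file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  dt <- as.data.table(peaks)[, .(chrom, start, end,
                                 name = sprintf("peak_%05d", .I),
                                 score, strand = ".")]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score",
                            "strand"))
  peak_set(dt[, .(chrom, start, end, score)])
}

#' Write features as BED6 with `id|class` in the name column
#' @param features a data.table with chrom, start, end, strand, klass, id.
#' @param path file path.
#' @export
write_features_bed <- function(features, path) {
  dt <- as.data.table(features)[, .(chrom, start, end,
                                    name = paste(id, klass, sep = "|"),
                                    score = 0L, strand)]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_features_bed
#' @export
read_features_bed <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score",
                            "strand"))
  dt[, c("id", "klass") := tstrsplit(name, "|", fixed = TRUE)]
  dt[, .(chrom, start, end, strand, klass, id)]
}
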