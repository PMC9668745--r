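#' Fixed-step coverage and enrichment tracks
#'
#' A coverage track stores non-negative counts on a fixed-width window grid
#' (0-based half-open, tiling from 0, trailing short window dropped); an
#' enrichment track stores log2 IP/input ratios on the same grid, with
#' missing values explicit (\code{NA}), never silently zero.
#'
#' @param windows a data.table with chrom, start, end and \code{count}
#'   (coverage) or \code{value} (enrichment) columns.
#' @param step window width in bp.
#' @return an object of class \code{coverage_track} / \code{enrichment_track}
#'   (a data.table with \code{step} and, for coverage, \code{library_size}
#'   attributes).
#' @export
coverage_track <- function(windows, step) {
  dt <- as.data.table(windows)[, .(chrom, start, end, count)]
  if (any(dt$count < 0)) stop("counts must be non-negative")
  if (any(dt$end - dt$start != step)) stop("windows must all have width `step`")
  setattr(dt, "step", as.integer(step))
  setattr(dt, "library_size", as.numeric(sum(dt$count)))
  setattr(dt, "class", c("coverage_track", class(dt)))
  dt
}

#' @rdname coverage_track
#' @export
enrichment_track <- function(windows, step) {
  dt <- as.data.table(windows)[, .(chrom, start, end, value)]
  setattr(dt, "step", as.integer(step))
  setattr(dt, "class", c("enrichment_track", class(dt)))
  dt
}

track_step <- function(x) attr(x, "step", exact = TRUE)

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && identical(track_step(a), track_step(b)) &&
    all(a$chrom == b$chrom) && all(a$start == b$start)
}

#' Window-level log2(IP/input) enrichment
#'
#' Computes per-window \code{log2((CPM_ip + alpha) / (CPM_in + alpha))}
#' where CPM is counts per million of library size. With
#' \code{scale = "raw"} the raw counts are used instead (appropriate when
#' libraries are depth-matched); with \code{alpha = 0} in raw mode,
#' windows where either count is zero are reported as missing.
#'
#' @param ip,input coverage tracks on identical grids.
#' @param alpha pseudocount added to both numerator and denominator after
#'   scaling; must be \code{> 0} unless both counts are positive.
#' @param scale \code{"cpm"} (library-normalised, default) or \code{"raw"}.
#' @return an \code{enrichment_track}.
#' @export
window_enrichment <- function(ip, input, alpha = 0.5,
                              scale = c("cpm", "raw")) {
  scale <- match.arg(scale)
  if (!same_grid(ip, input)) stop("IP and input grids differ")
  if (alpha < 0) stop("alpha must be >= 0")
  num <- scaled_counts(ip$count, attr(ip, "library_size"), scale) + alpha
  den <- scaled_counts(input$count, attr(input, "library_size"), scale) + alpha
  value <- ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
  enrichment_track(ip[, .(chrom, start, end)][, value := value],
                   track_step(ip))
}

scaled_counts <- function(count, libsize, scale) {
  if (scale == "cpm") {
    if (libsize <= 0) stop("empty library")
    count * 1e6 / libsize
  } else count
}

#' Average an enrichment track over coarser bins
#'
#' Means the window values inside each \code{binsize}-bp bin, ignoring
#' missing windows; bins with no defined window are missing.
#'
#' @param track an \code{enrichment_track}.
#' @param binsize target bin width, a multiple of the track step.
#' @param drop_short drop a trailing short bin (default) or keep it.
#' @return an \code{enrichment_track} at \code{binsize} resolution.
#' @export
bin_enrichment <- function(track, binsize, drop_short = TRUE) {
  step <- track_step(track)
  if (binsize %% step != 0) stop("binsize must be a multiple of the step")
  b <- as.data.table(track)[, .(chrom, start, end, value)]
  b[, bstart := (start %/% binsize) * as.integer(binsize)]
  out <- b[, .(value = if (all(is.na(value))) NA_real_
               else mean(value, na.rm = TRUE),
               end = max(end)), by = .(chrom, bstart)]
  setnames(out, "bstart", "start")
  if (drop_short) out <- out[end - start == binsize]
  enrichment_track(out[, .(chrom, start, end, value)], binsize)
}

#' Per-window CG methylation from per-site bisulfite counts
#'
#' For every window, the methylation fraction is the summed methylated-C
#' count divided by the summed (methylated + unmethylated) coverage over CG
#' sites inside the window. Windows without CG sites or without aligned
#' reads are absent from the output, not zero. Sites falling outside all
#' windows are ignored and counted in the \code{n_outside} attribute.
#'
#' @param sites a data.table with chrom, pos (0-based), mC, uC counts.
#' @param windows a data.table with chrom, start, end (0-based half-open).
#' @return a data.table with chrom, start, end, mCG fraction, n_sites,
#'   n_reads; attribute \code{n_outside} counts discarded sites.
#' @export
window_methylation <- function(sites, windows) {
  sites <- as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "mC", "uC") %in% names(sites)))
  if (any(sites$mC < 0 | sites$uC < 0)) stop("counts must be >= 0")
  win <- as.data.table(windows)[, .(chrom, start, end)]
  s <- sites[, .(chrom, start = pos, end = pos + 1L, mC, uC)]
  hits <- overlap_pairs(s, win)
  n_outside <- nrow(s) - length(unique(hits$xid))
  agg <- data.table(yid = hits$yid, mC = s$mC[hits$xid], uC = s$uC[hits$xid])
  agg <- agg[, .(mC = sum(mC), reads = sum(mC + uC), n_sites = .N), by = yid]
  agg <- agg[reads > 0]
  out <- win[agg$yid]
  out[, `:=`(mCG = agg$mC / agg$reads, n_sites = agg$n_sites,
             n_reads = agg$reads)]
  setattr(out, "n_outside", n_outside)
  out[order(chrom, start)]
}

#' Read/write bedGraph tracks
#'
#' Plain four-column bedGraph (chrom, start, end, value), 0-based
#' half-open. Missing enrichment values are omitted on write.
#'
#' @param track a coverage or enrichment track.
#' @param path file path.
#' @param step window width, required when reading a coverage track.
#' @param what \code{"coverage"} or \code{"enrichment"}.
#' @return \code{write_bedgraph} returns the path invisibly;
#'   \code{read_bedgraph} returns a track object.
#' @export
write_bedgraph <- function(track, path) {
  col <- if (inherits(track, "coverage_track")) "count" else "value"
  dt <- as.data.table(track)[, c("chrom", "start", "end", col), with = FALSE]
  if (col == "value") dt <- dt[!is.na(value)]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, step, what = c("coverage", "enrichment")) {
  what <- match.arg(what)
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end",
                            if (what == "coverage") "count" else "value"))
  if (what == "coverage") coverage_track(dt, step)
  else enrichment_track(dt, step)
}
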