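#' Strand-aware metaprofile of an enrichment track over feature groups
#'
#' Each feature body is linearly rescaled to \code{body_bins} bins; flanks
#' of \code{flank} bp are cut into fixed \code{flank_bin}-bp bins. A bin's
#' value is the coverage-weighted mean of the track windows overlapping the
#' bin interval (missing windows carry no weight). Minus-strand profiles
#' are reversed so every profile reads 5' to 3'. The group profile is the
#' mean over its features, ignoring missing bins. Features shorter than one
#' source window are skipped and counted in the \code{n_skipped} attribute.
#'
#' @param track an \code{enrichment_track}.
#' @param features data.table with chrom, start, end, strand, id.
#' @param groups named assignment of feature id to group (character vector
#'   or data.table with id, group); groups must partition the features.
#' @param body_bins number of body bins.
#' @param flank flank width in bp.
#' @param flank_bin flank bin width in bp.
#' @return a group x bin matrix; bins run upstream flank, body, downstream
#'   flank. Attribute \code{n_skipped} counts skipped features.
#' @export
metaprofile <- function(track, features, groups, body_bins = 100L,
                        flank = 1000L, flank_bin = 50L) {
  f <- as.data.table(features)
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$id)
  if (!setequal(names(groups), f$id))
    stop("groups must partition the features")
  step <- track_step(track)
  n_flank <- as.integer(flank / flank_bin)
  n_bins <- 2L * n_flank + body_bins
  short <- f$end - f$start < step
  n_skipped <- sum(short)
  f <- f[!short]

  grp_names <- sort(unique(groups))
  acc <- matrix(0, length(grp_names), n_bins,
                dimnames = list(grp_names, NULL))
  cnt <- matrix(0L, length(grp_names), n_bins)

  for (i in seq_len(nrow(f))) {
    prof <- feature_profile(track, f$chrom[i], f$start[i], f$end[i],
                            body_bins, flank, flank_bin, n_flank)
    if (f$strand[i] == "-") prof <- rev(prof)
    g <- as.character(groups[[f$id[i]]])
    ok <- !is.na(prof)
    acc[g, ok] <- acc[g, ok] + prof[ok]
    cnt[grp_names == g, ok] <- cnt[grp_names == g, ok] + 1L
  }
  out <- acc / ifelse(cnt > 0L, cnt, NA_integer_)
  colnames(out) <- c(sprintf("up_%d", seq_len(n_flank)),
                     sprintf("body_%d", seq_len(body_bins)),
                     sprintf("down_%d", seq_len(n_flank)))
  setattr(out, "n_skipped", n_skipped)
  out
}

# Coverage-weighted mean of track windows over one bin interval [s, e).
feature_profile <- function(track, chrom, start, end, body_bins, flank,
                            flank_bin, n_flank) {
  body_edges <- start + (end - start) * (0:body_bins) / body_bins
  up_edges <- seq(start - flank, start, by = flank_bin)
  down_edges <- seq(end, end + flank, by = flank_bin)
  edges_s <- c(head(up_edges, -1L), head(body_edges, -1L),
               head(down_edges, -1L))
  edges_e <- c(up_edges[-1L], body_edges[-1L], down_edges[-1L])
  tw <- track[track$chrom == chrom]
  step <- track_step(track)
  vapply(seq_along(edges_s), function(k) {
    s <- edges_s[k]; e <- edges_e[k]
    i0 <- max(1L, as.integer(floor(s / step)) + 1L)
    i1 <- min(nrow(tw), as.integer(ceiling(e / step)))
    if (i0 > i1) return(NA_real_)
    w <- pmin(tw$end[i0:i1], e) - pmax(tw$start[i0:i1], s)
    v <- tw$value[i0:i1]
    ok <- !is.na(v) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}
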