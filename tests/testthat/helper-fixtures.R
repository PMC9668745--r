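# Desk-scale fixtures built in code; no files.

# A small genome for fast unit tests (full defaults are exercised in the
# acceptance suite).
tiny_params <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_chrom = 2L, chrom_length = 2e5)
  do.call(sim_params, utils::modifyList(defaults, args))
}

# Hand-built fixed-step coverage track on one chromosome.
make_track <- function(counts, step = 50L, chrom = "chr1") {
  n <- length(counts)
  coverage_track(data.table::data.table(
    chrom = chrom, start = seq.int(0L, by = step, length.out = n),
    end = seq.int(step, by = step, length.out = n), count = counts), step)
}

make_etrack <- function(values, step = 50L, chrom = "chr1") {
  n <- length(values)
  enrichment_track(data.table::data.table(
    chrom = chrom, start = seq.int(0L, by = step, length.out = n),
    end = seq.int(step, by = step, length.out = n), value = values), step)
}

# Brute-force per-base reimplementation of the four-stage peak caller used
# as the independent oracle. Operates on one chromosome.
peaks_oracle <- function(values, ip, input, step = 50L, threshold = 1.2,
                         merge_gap = 150, min_len = 200, alpha = 0.5,
                         scale = "raw") {
  n <- length(values)
  glen <- n * step
  keep_base <- rep(FALSE, glen)
  for (w in seq_len(n)) {
    if (!is.na(values[w]) && values[w] > threshold)
      keep_base[((w - 1L) * step + 1L):(w * step)] <- TRUE
  }
  # merge: close gaps of length <= merge_gap between kept runs
  r <- rle(keep_base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1L && k < length(r$values) &&
        r$lengths[k] <= merge_gap)
      keep_base[starts[k]:ends[k]] <- TRUE
  }
  r <- rle(keep_base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  lib_ip <- sum(ip); lib_in <- sum(input)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s0 <- starts[k] - 1L; e0 <- ends[k]   # 0-based half-open
    if (e0 - s0 < min_len) next
    widx <- which(seq.int(0L, by = step, length.out = n) >= s0 &
                  seq.int(step, by = step, length.out = n) <= e0)
    si <- sum(ip[widx]); sn <- sum(input[widx])
    if (scale == "cpm") { si <- si * 1e6 / lib_ip; sn <- sn * 1e6 / lib_in }
    sc <- log2((si + alpha) / (sn + alpha))
    if (sc >= threshold)
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = "chr1", start = s0, end = e0, score = sc)
  }
  if (length(out)) data.table::rbindlist(out)
  else data.table::data.table(chrom = character(), start = integer(),
                              end = integer(), score = numeric())
}

expect_dt_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         tolerance = tol, ignore_attr = TRUE)
}
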