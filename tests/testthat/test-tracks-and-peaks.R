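test_that("window enrichment matches the per-window formula", {
  # raw mode, equal depths: 8 over 2 is exactly two doublings
  ip <- make_track(c(8, 2)); input <- make_track(c(2, 8))
  e <- window_enrichment(ip, input, alpha = 0, scale = "raw")
  expect_equal(e$value, c(2, -2))
  # identical tracks give zero everywhere (cpm mode)
  t1 <- make_track(c(5, 9, 3, 0))
  e0 <- window_enrichment(t1, t1, alpha = 0.5)
  expect_equal(e0$value, rep(0, 4))
  # random Poisson windows against a direct formula oracle
  set.seed(21)
  a <- rpois(1000, 30); b <- rpois(1000, 25)
  ta <- make_track(a); tb <- make_track(b)
  e1 <- window_enrichment(ta, tb, alpha = 0.5)
  oracle <- log2((a * 1e6 / sum(a) + 0.5) / (b * 1e6 / sum(b) + 0.5))
  expect_equal(e1$value, oracle, tolerance = 1e-12)
})

test_that("enrichment is antisymmetric under IP/input swap at equal depth", {
  set.seed(4)
  a <- rpois(300, 20); b <- sample(a)   # equal library sizes
  e1 <- window_enrichment(make_track(a), make_track(b), alpha = 0.5)
  e2 <- window_enrichment(make_track(b), make_track(a), alpha = 0.5)
  expect_equal(e1$value, -e2$value, tolerance = 1e-12)
})

test_that("grid mismatch and zero counts are handled explicitly", {
  expect_error(window_enrichment(make_track(1:4), make_track(1:5)),
               "grids differ")
  e <- window_enrichment(make_track(c(0, 4)), make_track(c(0, 4)),
                         alpha = 0, scale = "raw")
  expect_true(is.na(e$value[1]))   # missing, never silently zero
  expect_equal(e$value[2], 0)
})

test_that("peak caller reproduces the hand-traced worked example", {
  # input 2 per 50-bp window, IP 12 in [100,200) and [350,450), 0 elsewhere
  n <- 20L
  input <- rep(2, n)
  ip <- rep(0, n)
  ip[c(3, 4, 8, 9)] <- 12       # windows [100,150),[150,200),[350,400),[400,450)
  tin <- make_track(input); tip <- make_track(ip)
  e <- window_enrichment(tip, tin, alpha = 0.5, scale = "raw")
  pk <- call_h2b8_peaks(e, tip, tin, threshold = 1.2, merge_gap = 150,
                        min_len = 200, alpha = 0.5, scale = "raw")
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$start, 100L)
  expect_identical(pk$end, 450L)
  expect_equal(pk$score, log2(48.5 / 14.5), tolerance = 1e-12)
})

test_that("peak caller edge rules: empty input, short regions, thresholds", {
  # nothing above threshold
  e <- make_etrack(rep(1.2, 10))   # strictly-greater rule excludes ties
  tip <- make_track(rep(4, 10)); tin <- make_track(rep(4, 10))
  expect_identical(nrow(call_h2b8_peaks(e, tip, tin, scale = "raw")), 0L)
  # one qualifying 50-bp window dies at the length filter
  v <- rep(0, 10); v[4] <- 3
  e1 <- make_etrack(v)
  expect_identical(nrow(call_h2b8_peaks(e1, tip, tin, scale = "raw")), 0L)
  # negative parameters rejected
  expect_error(call_h2b8_peaks(e1, tip, tin, merge_gap = -1), "negative")
  # non-50-bp grid warns but proceeds
  e2 <- make_etrack(rep(0, 10), step = 100L)
  t2 <- make_track(rep(1, 10), step = 100L)
  expect_warning(call_h2b8_peaks(e2, t2, t2), "not 50 bp")
})

test_that("peak caller equals the per-base brute-force oracle", {
  set.seed(77)
  for (rep_i in 1:200) {
    n <- 100L
    input <- rpois(n, 5) + 1
    ip <- rpois(n, 5) * rbinom(n, 1, 0.3) * sample(1:8, n, TRUE)
    tin <- make_track(input); tip <- make_track(ip)
    e <- window_enrichment(tip, tin, alpha = 0.5, scale = "raw")
    pk <- call_h2b8_peaks(e, tip, tin, alpha = 0.5, scale = "raw")
    orc <- peaks_oracle(e$value, ip, input)
    expect_identical(nrow(pk), nrow(orc))
    if (nrow(orc)) {
      expect_identical(pk$start, orc$start)
      expect_identical(pk$end, orc$end)
      expect_equal(pk$score, orc$score, tolerance = 1e-12)
      validate_peak_set(pk)
    }
  }
})

test_that("window methylation follows the summed-count ratio", {
  win <- data.table::data.table(chrom = "chr1", start = c(0L, 100L),
                                end = c(100L, 200L))
  sites <- data.table::data.table(chrom = "chr1", pos = c(10L, 50L, 150L),
                                  mC = c(5L, 3L, 0L), uC = c(0L, 1L, 0L))
  m <- window_methylation(sites, win)
  # window 2's only site has zero reads: absent, not zero
  expect_identical(nrow(m), 1L)
  expect_equal(m$mCG, 8 / 9)
  expect_identical(m$n_sites, 2L)
  # single fully methylated site
  m1 <- window_methylation(
    data.table::data.table(chrom = "chr1", pos = 5L, mC = 5L, uC = 0L), win)
  expect_equal(m1$mCG, 1)
  # site outside all windows is ignored but counted
  m2 <- window_methylation(
    data.table::data.table(chrom = "chr1", pos = c(5L, 999L),
                           mC = c(1L, 1L), uC = c(1L, 0L)), win)
  expect_identical(attr(m2, "n_outside"), 1L)
  # random sites against a per-window ratio oracle
  set.seed(12)
  ns <- 500L
  s <- data.table::data.table(chrom = "chr1",
                              pos = sample(0:199, ns, TRUE),
                              mC = rpois(ns, 2), uC = rpois(ns, 2))
  mr <- window_methylation(s, win)
  for (r in seq_len(nrow(mr))) {
    inw <- s[s$pos >= mr$start[r] & s$pos < mr$end[r], ]
    expect_equal(mr$mCG[r], sum(inw$mC) / sum(inw$mC + inw$uC))
  }
})

test_that("peak coverage partition conserves base pairs exactly", {
  p <- tiny_params(seed = 8)
  gm <- simulate_genome(p)
  # wholly inside a gene
  g1 <- gm$features[klass == "gene" & end - start > 400][1]
  pk <- peak_set(data.table::data.table(chrom = g1$chrom,
                                        start = g1$start + 50L,
                                        end = g1$start + 250L, score = 2))
  out <- partition_peak_coverage(pk, gm)
  expect_equal(unname(out$coverage["gene"]), 200)
  expect_equal(out$total_bp, 200)
  # straddling a boundary at a 50-bp multiple: exact split
  iv <- gm$features[klass == "gene"][2]
  b <- (iv$end %/% 50L) * 50L            # 50-bp-aligned point inside gene end
  pk2 <- peak_set(data.table::data.table(chrom = iv$chrom, start = b - 100L,
                                         end = b + 100L, score = 2))
  out2 <- partition_peak_coverage(pk2, gm)
  expect_equal(out2$total_bp, 200)
  expect_gte(unname(out2$coverage["gene"]), 100)
  # empty set
  empty <- peak_set(data.table::data.table(chrom = character(),
                                           start = integer(),
                                           end = integer(),
                                           score = numeric()))
  expect_equal(partition_peak_coverage(empty, gm)$total_bp, 0)
  # conservation on a random peak set from the caller
  tr <- simulate_chip_tracks(gm, "H2B.8")
  e <- window_enrichment(tr$ip, tr$input, scale = "raw")
  pks <- call_h2b8_peaks(e, tr$ip, tr$input, scale = "raw")
  out3 <- partition_peak_coverage(pks, gm)
  expect_equal(out3$total_bp, sum(pks$end - pks$start))
  expect_equal(out3$genome_fraction,
               sum(pks$end - pks$start) / sum(gm$chromosomes$length))
  # peak beyond chromosome end rejected
  bad <- peak_set(data.table::data.table(chrom = "chr1", start = 0L,
                                         end = 10 * sum(gm$chromosomes$length),
                                         score = 2))
  expect_error(partition_peak_coverage(bad, gm), "bounds")
})

test_that("feature overlap applies the 25% rule boundary-inclusively", {
  f <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                              id = "te1")
  mk <- function(cov) peak_set(data.table::data.table(
    chrom = "chr1", start = 0L, end = as.integer(cov), score = 2))
  expect_true(feature_overlap(mk(250), f)$overlap)
  expect_false(feature_overlap(mk(249), f)$overlap)
  # no peaks: all false
  empty <- peak_set(data.table::data.table(chrom = character(),
                                           start = integer(),
                                           end = integer(),
                                           score = numeric()))
  expect_false(any(feature_overlap(empty, f)$overlap))
  expect_error(feature_overlap(mk(250), f, min_frac = 0), "min_frac")
  # randomized instances against a per-base oracle
  set.seed(31)
  for (r in 1:50) {
    feats <- data.table::data.table(chrom = "chr1",
                                    start = seq(0L, 900L, 100L),
                                    end = seq(0L, 900L, 100L) +
                                      sample(30:100, 10, TRUE))
    feats$id <- sprintf("f%d", 1:10)
    ps <- sort(sample(0:950, 5))
    pk <- data.table::data.table(chrom = "chr1", start = ps,
                                 end = ps + sample(10:50, 5, TRUE),
                                 score = 2)
    # enforce non-overlap
    pk <- pk[c(TRUE, pk$start[-1] >= head(pk$end, -1))]
    pk <- peak_set(pk)
    ov <- feature_overlap(pk, feats, 0.25)
    base <- rep(FALSE, 1000)
    for (q in seq_len(nrow(pk))) base[(pk$start[q] + 1):pk$end[q]] <- TRUE
    for (k in seq_len(nrow(feats))) {
      cov <- sum(base[(feats$start[k] + 1):feats$end[k]])
      expect_identical(ov$overlap[k],
                       cov >= 0.25 * (feats$end[k] - feats$start[k]))
      expect_identical(ov$covered_bp[k], cov)
    }
  }
})

test_that("metaprofiles rescale bodies and respect strand", {
  # constant track: every bin equals the constant
  tr <- make_etrack(rep(1.5, 100))
  f <- data.table::data.table(chrom = "chr1", start = 1000L, end = 3000L,
                              strand = "+", id = "g1")
  grp <- c(g1 = "all")
  mp <- metaprofile(tr, f, grp, body_bins = 20L, flank = 500L,
                    flank_bin = 50L)
  expect_equal(unname(mp["all", ]), rep(1.5, 40), tolerance = 1e-12)
  # linear ramp against a direct per-base resampling oracle
  ramp <- seq(0, 9.9, by = 0.1)
  tr2 <- make_etrack(ramp)
  mp2 <- metaprofile(tr2, f, grp, body_bins = 10L, flank = 200L,
                     flank_bin = 50L)
  per_base <- rep(ramp, each = 50L)
  oracle <- c(
    vapply(0:3, function(k) mean(per_base[(800 + k * 50 + 1):(800 + (k + 1) * 50)]),
           numeric(1)),
    vapply(0:9, function(k) mean(per_base[(1000 + k * 200 + 1):(1000 + (k + 1) * 200)]),
           numeric(1)),
    vapply(0:3, function(k) mean(per_base[(3000 + k * 50 + 1):(3000 + (k + 1) * 50)]),
           numeric(1)))
  expect_equal(unname(mp2["all", ]), oracle, tolerance = 1e-9)
  # minus strand reverses the profile
  f2 <- data.table::data.table(chrom = "chr1", start = 1000L, end = 3000L,
                               strand = "-", id = "g1")
  mp3 <- metaprofile(tr2, f2, grp, body_bins = 10L, flank = 200L,
                     flank_bin = 50L)
  expect_equal(unname(mp3["all", ]), rev(oracle), tolerance = 1e-9)
  # a feature shorter than one source window is skipped and counted
  f3 <- data.table::data.table(chrom = "chr1",
                               start = c(1000L, 500L), end = c(3000L, 520L),
                               strand = "+", id = c("g1", "g2"))
  mp4 <- metaprofile(tr2, f3, c(g1 = "all", g2 = "all"), body_bins = 10L,
                     flank = 200L, flank_bin = 50L)
  expect_identical(attr(mp4, "n_skipped"), 1L)
})

test_that("tracks round-trip through bedGraph", {
  tr <- make_track(c(3, 0, 7, 2))
  td <- withr::local_tempdir()
  pth <- file.path(td, "t.bedGraph")
  write_bedgraph(tr, pth)
  back <- read_bedgraph(pth, step = 50L, what = "coverage")
  expect_equal(back$count, tr$count)
  expect_identical(attr(back, "library_size"), attr(tr, "library_size"))
})
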