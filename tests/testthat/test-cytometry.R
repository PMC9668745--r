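test_that("Otsu threshold maximises between-class variance", {
  # two spikes: threshold strictly between them
  x <- c(rep(10, 40), rep(200, 60))
  t1 <- otsu_threshold(x)
  expect_gte(t1, 10); expect_lt(t1, 200)
  # brute-force oracle over all candidate split levels
  set.seed(3)
  for (r in 1:100) {
    v <- sample(0:30, 200, TRUE)
    lev <- sort(unique(v))
    bvar <- vapply(head(lev, -1), function(t) {
      lo <- v[v <= t]; hi <- v[v > t]
      length(lo) / length(v) * length(hi) / length(v) *
        (mean(lo) - mean(hi))^2
    }, numeric(1))
    got <- otsu_threshold(v)
    # achieved between-class variance equals the exhaustive maximum
    expect_equal(bvar[match(got, head(lev, -1))], max(bvar),
                 tolerance = 1e-12)
    # invariance to duplicating every observation
    expect_equal(otsu_threshold(rep(v, 3)), got)
  }
  expect_error(otsu_threshold(rep(5, 10)), "distinct")
})

test_that("segmentation recovers a synthetic nucleus and its volume", {
  p <- tiny_params(n_foci = 0L)
  st <- simulate_nucleus_stack(p, seed = 4)
  seg <- segment_nuclei(st, sigma = 1.5)
  expect_identical(seg$n_nuclei, 1L)
  vol <- nuclear_size(seg, st$voxel_size, "volume")$size
  expect_equal(vol, st$truth$ellipsoid_volume, tolerance = 0.1)
  # pure-noise stack: empty result, flagged
  noise_stack <- structure(list(
    channels = list(dna = array(rpois(64 * 64 * 8, 5), c(64, 64, 8))),
    voxel_size = p$voxel_size, truth = NULL), class = "image_stack")
  seg0 <- segment_nuclei(noise_stack, sigma = 1.5, min_size = 500L)
  expect_true(seg0$empty)
})

test_that("two well-separated nuclei get two labels", {
  d <- c(64L, 64L, 10L)
  g <- spermchrom:::voxel_grid(d)
  m1 <- ((g$x - 16)^2 / 64 + (g$y - 16)^2 / 64 + (g$z - 5)^2 / 9) <= 1
  m2 <- ((g$x - 48)^2 / 64 + (g$y - 48)^2 / 64 + (g$z - 5)^2 / 9) <= 1
  img <- 10 + 100 * (m1 | m2)
  st <- structure(list(channels = list(dna = img),
                       voxel_size = c(0.1, 0.1, 0.2), truth = NULL),
                  class = "image_stack")
  seg <- segment_nuclei(st, sigma = 1, min_size = 50L)
  expect_identical(seg$n_nuclei, 2L)
})

test_that("nuclear size modes measure projection area and voxel volume", {
  lab <- array(0L, c(12, 12, 3))
  lab[2:11, 2:11, 2] <- 1L          # 10 x 10 x 1 slab
  seg <- structure(list(labels = lab, n_nuclei = 1L, empty = FALSE),
                   class = "segmentation_result")
  a <- nuclear_size(seg, c(0.1, 0.1, 0.3), "area_of_max_projection")
  expect_equal(a$size, 1.0)
  v <- nuclear_size(seg, c(0.1, 0.1, 0.3), "volume")
  expect_equal(v$size, 100 * 0.1 * 0.1 * 0.3)
  expect_error(nuclear_size(seg, c(0.1, 0.1, 0.3), "perimeter"))
})

test_that("a planted nuclear-size ratio between groups is recovered", {
  p <- tiny_params()
  sizes <- function(scale, seeds) vapply(seeds, function(s) {
    st <- simulate_nucleus_stack(p, seed = s, axes_scale = scale)
    seg <- segment_nuclei(st, sigma = 1.5)
    nuclear_size(seg, st$voxel_size, "area_of_max_projection")$size[1]
  }, numeric(1))
  small <- sizes(1, 1:8)
  large <- sizes(sqrt(1.4), 9:16)
  expect_equal(mean(large) / mean(small), 1.4, tolerance = 0.05)
})

test_that("foci detection counts planted foci and their volume", {
  p <- tiny_params(n_foci = 5L)
  st <- simulate_nucleus_stack(p, seed = 21)
  seg <- segment_nuclei(st, sigma = 1.5)
  thr <- p$background + p$plateau_marker + p$focus_amp / 2
  fc <- detect_foci(st, seg, focus_threshold = thr, min_voxels = 5L)
  expect_identical(fc$per_nucleus$n_foci, 5L)
  # ground truth: Gaussian focus isosurface above (thr - plateau)
  rel <- thr - (p$background + p$plateau_marker)
  rstar <- p$focus_radius * sqrt(2 * log(p$focus_amp / rel))
  vol_truth <- 5 * 4 / 3 * pi * rstar^3 * prod(st$voxel_size)
  expect_equal(fc$per_nucleus$total_volume, vol_truth, tolerance = 0.15)
  # zero planted foci give zero detections
  st0 <- simulate_nucleus_stack(tiny_params(n_foci = 0L), seed = 21)
  seg0 <- segment_nuclei(st0, sigma = 1.5)
  fc0 <- detect_foci(st0, seg0, focus_threshold = thr)
  expect_identical(fc0$per_nucleus$n_foci, 0L)
  # total volume is monotone non-increasing in the threshold
  fc2 <- detect_foci(st, seg, focus_threshold = thr + 20)
  expect_lte(fc2$per_nucleus$total_volume, fc$per_nucleus$total_volume)
  # a threshold below background warns
  expect_warning(detect_foci(st, seg, focus_threshold = 1), "background")
})

test_that("close foci merge into one 26-connected component", {
  m <- array(FALSE, c(10, 10, 3))
  m[3, 3, 2] <- TRUE; m[4, 4, 2] <- TRUE    # diagonal neighbours
  m[8, 8, 2] <- TRUE
  lab <- label_components_3d(m)
  expect_identical(max(lab), 2L)
  expect_identical(lab[3, 3, 2], lab[4, 4, 2])
})

test_that("colocalization quantiles rank tiles and normalise by nucleus sums", {
  d <- c(48L, 48L, 4L)
  g <- spermchrom:::voxel_grid(d)
  mask <- ((g$x - 24)^2 / 400 + (g$y - 24)^2 / 400 +
           (g$z - 2.5)^2 / 4) <= 1
  lab <- array(0L, d); lab[mask] <- 1L
  seg <- structure(list(labels = lab, n_nuclei = 1L, empty = FALSE),
                   class = "segmentation_result")
  # both channels uniform: all quantile means equal
  st_u <- structure(list(channels = list(dna = array(50, d),
                                         marker = array(80, d)),
                         voxel_size = c(0.1, 0.1, 0.2), truth = NULL),
                    class = "image_stack")
  cq <- colocalization_quantiles(st_u, seg, tile = 8L, n_quantiles = 4L)
  expect_lt(diff(range(cq$mean_a)), 1e-12)
  # planted A = B coupling: strictly increasing quantile means
  grad <- 10 + g$x + 2 * g$y
  st_c <- structure(list(channels = list(dna = grad, marker = grad),
                         voxel_size = c(0.1, 0.1, 0.2), truth = NULL),
                    class = "image_stack")
  cq2 <- colocalization_quantiles(st_c, seg, tile = 8L, n_quantiles = 4L)
  expect_true(all(diff(cq2$mean_a) > 0))
  # normalised tile values sum to at most one per channel
  tiles <- attr(cq2, "tiles")
  expect_lte(sum(tiles$a), 1 + 1e-9)
  expect_lte(sum(tiles$b), 1 + 1e-9)
  # nucleus smaller than one tile rejected
  expect_error(colocalization_quantiles(st_c, seg, tile = 64L), "tile")
})

test_that("ANOVA and Tukey match formula oracles", {
  # all groups identical constant: F = 0, p = 1
  gs0 <- one_way_anova_tukey(list(a = rep(3, 4), b = rep(3, 5)))
  expect_equal(gs0$statistic, 0)
  expect_equal(gs0$p_value, 1)
  # random 3-group data against a direct sums-of-squares oracle
  set.seed(77)
  for (r in 1:20) {
    gr <- list(a = rnorm(6, 0), b = rnorm(8, 0.5), c = rnorm(5, 1))
    gs <- one_way_anova_tukey(gr)
    all_y <- unlist(gr)
    gm <- mean(all_y)
    ssb <- sum(vapply(gr, function(g) length(g) * (mean(g) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(gr, function(g) sum((g - mean(g))^2), numeric(1)))
    f_oracle <- (ssb / 2) / (ssw / (length(all_y) - 3))
    expect_equal(gs$statistic, f_oracle, tolerance = 1e-10)
    expect_equal(gs$p_value,
                 pf(f_oracle, 2, length(all_y) - 3, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # k = 2: Tukey p equals the pooled-variance two-sample p (q = sqrt(2)|t|)
  a <- rnorm(7); b <- rnorm(9, 0.8)
  gs2 <- one_way_anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(gs2$tukey$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(gs2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(one_way_anova_tukey(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Welch t equals its formula oracle and is antisymmetric", {
  set.seed(6)
  for (r in 1:20) {
    a <- rnorm(8); b <- rnorm(12, 0.5, 2)
    gs <- two_sample_t(a, b)
    se <- sqrt(var(a) / 8 + var(b) / 12)
    t_oracle <- (mean(a) - mean(b)) / se
    df_oracle <- se^4 / ((var(a) / 8)^2 / 7 + (var(b) / 12)^2 / 11)
    expect_equal(gs$statistic, t_oracle, tolerance = 1e-10)
    expect_equal(gs$df, df_oracle, tolerance = 1e-10)
    expect_equal(gs$p_value, 2 * pt(-abs(t_oracle), df_oracle),
                 tolerance = 1e-10)
    rev <- two_sample_t(b, a)
    expect_equal(rev$statistic, -gs$statistic, tolerance = 1e-12)
    expect_equal(rev$p_value, gs$p_value, tolerance = 1e-12)
  }
  gs1 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gs1$statistic, 0)
  expect_equal(gs1$p_value, 1)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  gs <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(gs$p_value, 1)
  expect_equal(gs$statistic, 1)
  # enumeration oracle over all tables with fixed margins
  set.seed(11)
  for (r in 1:30) {
    tab <- matrix(rpois(4, 8), 2)
    gs <- fisher_exact_2x2(tab)
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    a_obs <- tab[1, 1]
    a_all <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    pr <- dhyper(a_all, rs[1], rs[2], cs[1])
    p_oracle <- sum(pr[pr <= dhyper(a_obs, rs[1], rs[2], cs[1]) *
                         (1 + 1e-7)])
    expect_equal(gs$p_value, p_oracle, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("male-transmission design has power to detect a 30% deficit", {
  # reciprocal-cross style: n progeny, mutant-allele probability reduced
  # 30% relative to the balanced expectation, against a balanced control
  set.seed(202)
  n <- 743L
  hits <- replicate(200, {
    mut <- rbinom(1, n, 0.35 / (0.35 + 0.5))   # 30% transmission deficit
    ctl <- rbinom(1, n, 0.5)                   # female side: no deficit
    tab <- matrix(c(mut, n - mut, ctl, n - ctl), 2)
    fisher_exact_2x2(tab)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("chi-squared GOF follows the formula and scales linearly", {
  gs0 <- chi_square_gof(c(25, 50, 25), c(1, 2, 1))
  expect_equal(gs0$statistic, 0)
  expect_equal(gs0$p_value, 1)
  set.seed(9)
  for (r in 1:20) {
    o <- rpois(4, 40) + 1
    ratio <- c(1, 2, 3, 2)
    gs <- chi_square_gof(o, ratio)
    e <- sum(o) * ratio / sum(ratio)
    expect_equal(gs$statistic, sum((o - e)^2 / e), tolerance = 1e-12)
    expect_equal(gs$p_value, pchisq(sum((o - e)^2 / e), 3,
                                    lower.tail = FALSE), tolerance = 1e-12)
    gs10 <- chi_square_gof(o * 10, ratio)
    expect_equal(gs10$statistic, 10 * gs$statistic, tolerance = 1e-9)
  }
  expect_warning(chi_square_gof(c(1, 1), c(1, 3)), "below 1")
})
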