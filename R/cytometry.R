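#' Otsu's threshold from an intensity histogram
#'
#' Maximises the between-class variance over all candidate split
#' intensities; the threshold separates the low class (values <= t) from
#' the high class (values > t). Ties are broken toward the lower
#' threshold. Intensities are rounded to integers (count images).
#'
#' @param x numeric vector or array of intensities, or a named histogram
#'   (table of counts per integer intensity).
#' @return the threshold intensity.
#' @export
otsu_threshold <- function(x) {
  if (is.table(x)) {
    lev <- as.numeric(names(x)); cnt <- as.numeric(x)
  } else {
    tab <- table(round(as.numeric(x)))
    lev <- as.numeric(names(tab)); cnt <- as.numeric(tab)
  }
  o <- order(lev); lev <- lev[o]; cnt <- cnt[o]
  if (length(lev) < 2L) stop("need at least 2 distinct intensities")
  w <- cnt / sum(cnt)
  mu <- lev * w
  cw <- cumsum(w)
  cmu <- cumsum(mu)
  mt <- cmu[length(cmu)]
  k <- seq_len(length(lev) - 1L)        # split after level k
  w0 <- cw[k]; w1 <- 1 - w0
  between <- (mt * w0 - cmu[k])^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  lev[k[which.max(between)]]            # which.max takes the first (lower) tie
}

#' Segment nuclei from a 3D stack
#'
#' Otsu threshold on the chosen channel, Gaussian smoothing of the binary
#' mask to round the edges, a repeated Otsu threshold on the smoothed
#' mask, then 26-connected components with small components removed.
#'
#' @param stack an \code{image_stack}.
#' @param sigma Gaussian smoothing sd in voxels (isotropic in x/y, scaled
#'   by voxel aspect in z).
#' @param channel channel name used for segmentation.
#' @param min_size minimal component size in voxels.
#' @return a \code{segmentation_result}: list with \code{labels} (integer
#'   array, 0 = background), thresholds, sigma and \code{n_nuclei}; an
#'   empty result carries \code{empty = TRUE}.
#' @export
segment_nuclei <- function(stack, sigma = 1.5, channel = "dna",
                           min_size = 200L) {
  x <- stack$channels[[channel]]
  if (is.null(x)) stop("unknown channel: ", channel)
  t1 <- otsu_threshold(x)
  mask1 <- x > t1
  # require a real foreground/background separation; a threshold that splits
  # noise has classes closer than twice the overall spread
  sep <- mean(x[mask1]) - mean(x[!mask1])
  if (!any(mask1) || all(mask1) || sep < 2 * stats::sd(x)) {
    return(structure(list(labels = array(0L, dim(x)),
                          threshold = c(t1, NA), sigma = sigma,
                          n_nuclei = 0L, empty = TRUE),
                     class = "segmentation_result"))
  }
  zscale <- stack$voxel_size[3L] / stack$voxel_size[1L]
  sm <- gaussian_smooth_3d(array(as.numeric(mask1), dim(x)),
                           c(sigma, sigma, sigma / zscale))
  sm255 <- round(sm * 255)
  t2 <- tryCatch(otsu_threshold(sm255), error = function(e) 127)
  mask2 <- sm255 > t2
  labels <- label_components_3d(mask2)
  keep <- which(tabulate(labels) >= min_size)
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  structure(list(labels = labels, threshold = c(t1, t2), sigma = sigma,
                 n_nuclei = length(keep), empty = length(keep) == 0L),
            class = "segmentation_result")
}

# Separable Gaussian smoothing along the three axes with reflected edges.
gaussian_smooth_3d <- function(a, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-(-r:r)^2 / (2 * s^2))
    kern <- kern / sum(kern)
    a <- convolve_axis(a, kern, ax)
  }
  a
}

convolve_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1L])
  r <- (length(kern) - 1L) / 2
  idx <- c(rev(seq_len(r)), seq_len(dp[1L]), dp[1L] - seq_len(r) + 1L)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = dp[1L], ncol = ncol(m))
  for (t in seq_along(kern))
    out <- out + kern[t] * mp[(t - 1L) + seq_len(dp[1L]), , drop = FALSE]
  aperm(array(out, dp), order(perm))
}

#' 26-connected component labelling of a 3D mask
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 is background, components
#'   are numbered 1..n in first-voxel order.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  n <- 0L
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  todo <- which(mask)
  visited <- array(FALSE, d)
  for (start in todo) {
    if (visited[start]) next
    n <- n + 1L
    frontier <- start
    visited[start] <- TRUE
    labels[start] <- n
    while (length(frontier)) {
      iz <- (frontier - 1L) %/% (nx * ny)
      rem <- (frontier - 1L) %% (nx * ny)
      iy <- rem %/% nx
      ix <- rem %% nx
      nbr <- integer(0)
      for (o in seq_len(nrow(offs))) {
        x2 <- ix + offs[o, 1L]; y2 <- iy + offs[o, 2L]; z2 <- iz + offs[o, 3L]
        ok <- x2 >= 0L & x2 < nx & y2 >= 0L & y2 < ny & z2 >= 0L & z2 < nz
        if (!any(ok)) next
        cand <- 1L + x2[ok] + nx * (y2[ok] + ny * z2[ok])
        cand <- cand[mask[cand] & !visited[cand]]
        if (length(cand)) {
          visited[cand] <- TRUE
          labels[cand] <- n
          nbr <- c(nbr, cand)
        }
      }
      frontier <- unique(nbr)
    }
  }
  labels
}

#' Per-nucleus size from a segmentation
#'
#' \code{"area_of_max_projection"} measures the 2D mask of the maximum
#' projection along z in um^2 (the nuclear-area readout used for sperm and
#' root nuclei); \code{"volume"} counts voxels times the voxel volume in
#' um^3.
#'
#' @param seg a \code{segmentation_result}.
#' @param voxel_size micrometres per voxel (x, y, z).
#' @param mode \code{"area_of_max_projection"} or \code{"volume"}.
#' @return a data.table with label and size.
#' @export
nuclear_size <- function(seg, voxel_size,
                         mode = c("area_of_max_projection", "volume")) {
  mode <- match.arg(mode)
  labs <- sort(unique(seg$labels[seg$labels > 0L]))
  size <- vapply(labs, function(l) {
    m <- seg$labels == l
    if (mode == "volume") sum(m) * prod(voxel_size)
    else sum(apply(m, c(1L, 2L), any)) * voxel_size[1L] * voxel_size[2L]
  }, numeric(1))
  data.table(label = labs, size = size)
}

#' Detect intensity foci inside segmented nuclei
#'
#' Within each nucleus mask, voxels of the chosen channel above
#' \code{focus_threshold} are grouped into 26-connected components;
#' components of at least \code{min_voxels} voxels are reported with their
#' voxel counts and volumes, plus a per-nucleus total. A threshold at or
#' below the nucleus median intensity triggers a warning (everything
#' becomes one focus).
#'
#' @param stack an \code{image_stack}.
#' @param seg a \code{segmentation_result}.
#' @param focus_threshold intensity cutoff (strict greater-than).
#' @param min_voxels minimal focus size in voxels.
#' @param channel channel holding the foci signal.
#' @return a list with \code{foci} (data.table label, focus, voxels,
#'   volume) and \code{per_nucleus} (label, n_foci, total_volume).
#' @export
detect_foci <- function(stack, seg, focus_threshold, min_voxels = 5L,
                        channel = "marker") {
  x <- stack$channels[[channel]]
  vx <- prod(stack$voxel_size)
  labs <- sort(unique(seg$labels[seg$labels > 0L]))
  rows <- list(); per <- list()
  for (l in labs) {
    m <- seg$labels == l
    if (focus_threshold <= median(x[m]))
      warning("focus threshold at or below nucleus background")
    fm <- m & x > focus_threshold
    comp <- label_components_3d(fm)
    sizes <- tabulate(comp)
    keep <- which(sizes >= min_voxels)
    if (length(keep))
      rows[[length(rows) + 1L]] <-
        data.table(label = l, focus = seq_along(keep),
                   voxels = sizes[keep], volume = sizes[keep] * vx)
    per[[length(per) + 1L]] <-
      data.table(label = l, n_foci = length(keep),
                 total_volume = sum(sizes[keep]) * vx)
  }
  list(foci = if (length(rows)) rbindlist(rows) else
         data.table(label = integer(), focus = integer(),
                    voxels = integer(), volume = numeric()),
       per_nucleus = rbindlist(per))
}

#' Tile-level colocalization quantiles of two channels
#'
#' Per z-slice, the nucleus mask is tiled into \code{tile} x \code{tile}
#' voxel regions. The tile value of a channel is the mean intensity over
#' the mask voxels it covers, divided by the whole-nucleus channel sum
#' (edge tiles enter with their covered voxels as weight). Tiles are
#' ranked by the second channel into \code{n_quantiles} equal-count groups
#' (ties to the lower group) and the coverage-weighted mean normalised
#' first-channel value per group is returned.
#'
#' @param stack an \code{image_stack}.
#' @param seg a \code{segmentation_result} (the first nucleus is used
#'   unless \code{label} is given).
#' @param tile tile edge length in voxels.
#' @param n_quantiles number of ranking groups.
#' @param channels length-2 character: (A = reported, B = ranking).
#' @param label nucleus label.
#' @return a data.table with quantile, mean_a, mean_b, n_tiles; attribute
#'   \code{tiles} carries the per-tile table.
#' @export
colocalization_quantiles <- function(stack, seg, tile = 20L,
                                     n_quantiles = 8L,
                                     channels = c("dna", "marker"),
                                     label = 1L) {
  a <- stack$channels[[channels[1L]]]
  b <- stack$channels[[channels[2L]]]
  m <- seg$labels == label
  if (!any(m)) stop("no such nucleus label")
  bb <- apply(which(m, arr.ind = TRUE), 2L, range)
  if (bb[2L, 1L] - bb[1L, 1L] + 1L < tile ||
      bb[2L, 2L] - bb[1L, 2L] + 1L < tile)
    stop("nucleus smaller than one tile")
  suma <- sum(a[m]); sumb <- sum(b[m])
  idx <- which(m, arr.ind = TRUE)
  tl <- data.table(tx = (idx[, 1L] - bb[1L, 1L]) %/% tile,
                   ty = (idx[, 2L] - bb[1L, 2L]) %/% tile,
                   z = idx[, 3L], va = a[m], vb = b[m])
  tiles <- tl[, .(n = .N, a = mean(va) / suma, b = mean(vb) / sumb),
              by = .(tx, ty, z)]
  tiles[, quantile := quantile_groups(b, n_quantiles)]
  out <- tiles[, .(mean_a = sum(a * n) / sum(n),
                   mean_b = sum(b * n) / sum(n), n_tiles = .N),
               keyby = quantile]
  setattr(out, "tiles", tiles)
  out[]
}
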