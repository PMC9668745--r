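#' Simulate a two-channel 3D nucleus image stack
#'
#' Both channels (DNA stain and marker) are background plus an ellipsoid
#' plateau; the marker channel additionally carries 3D Gaussian foci whose
#' centres lie inside the nucleus ellipsoid. Voxel intensities are Poisson
#' draws around the noiseless image (or the noiseless image itself with
#' \code{noise = FALSE}). Foci geometry is drawn from a stream derived
#' from the parameter seed, while \code{seed} drives only the Poisson
#' noise — so two stacks with the same parameters and different seeds share
#' their ground truth.
#'
#' @param params a \code{sim_params} (image fields; semi-axes in voxels).
#' @param seed integer noise seed.
#' @param noise draw Poisson noise (default) or return the clean image.
#' @param axes_scale multiplies the x/y semi-axes (used to plant size
#'   ratios between groups).
#' @return an \code{image_stack}: list with \code{channels} (named list of
#'   3D arrays), \code{voxel_size} and \code{truth} (ellipsoid centre and
#'   semi-axes, ellipsoid volume in um^3, foci centres/sd/amplitudes).
#' @export
simulate_nucleus_stack <- function(params = sim_params(), seed = params$seed,
                                   noise = TRUE, axes_scale = 1) {
  dim <- params$image_dim
  axes <- params$nucleus_axes * c(axes_scale, axes_scale, 1)
  if (params$n_foci > 0L && params$focus_radius < 1)
    stop("focus radius must be at least 1 voxel")
  centre <- (dim + 1) / 2
  foci <- with_seed(derive_seed(params$seed, "image/geometry"), {
    if (params$n_foci == 0L) NULL else {
      # rejection-sample centres well inside the ellipsoid (xy within 65%,
      # z within 50% of the semi-axis) and mutually separated so that
      # thresholded foci stay disjoint
      out <- matrix(NA_real_, params$n_foci, 3L)
      placed <- 0L
      attempts <- 0L
      lim <- c(0.65, 0.65, 0.5)
      while (placed < params$n_foci) {
        attempts <- attempts + 1L
        if (attempts > 1e5L) stop("could not place foci inside the nucleus")
        cand <- centre + (runif(3L) * 2 - 1) * lim * axes
        r2 <- sum(((cand - centre) / (lim * axes))^2)
        ok <- r2 <= 1 &&
          (placed == 0L ||
           all(sqrt(colSums((t(out[seq_len(placed), , drop = FALSE]) -
                             cand)^2)) > 3.6 * params$focus_radius))
        if (ok) { placed <- placed + 1L; out[placed, ] <- cand }
      }
      out
    }
  })
  inside <- ellipsoid_mask(dim, centre, axes)
  dna <- params$background + params$plateau_dna * inside
  marker <- params$background + params$plateau_marker * inside
  if (!is.null(foci)) {
    grid <- voxel_grid(dim)
    for (k in seq_len(nrow(foci))) {
      r2 <- (grid$x - foci[k, 1L])^2 + (grid$y - foci[k, 2L])^2 +
            (grid$z - foci[k, 3L])^2
      marker <- marker + params$focus_amp * exp(-r2 / (2 * params$focus_radius^2))
    }
  }
  if (noise) {
    dna <- with_seed(derive_seed(seed, "image/noise-dna"),
                     array(rpois(length(dna), dna), dim))
    marker <- with_seed(derive_seed(seed, "image/noise-marker"),
                        array(rpois(length(marker), marker), dim))
  }
  vx <- params$voxel_size
  structure(list(
    channels = list(dna = dna, marker = marker),
    voxel_size = vx,
    truth = list(centre = centre, axes = axes,
                 ellipsoid_volume = 4 / 3 * pi * prod(axes) * prod(vx),
                 projection_area = pi * axes[1L] * axes[2L] * vx[1L] * vx[2L],
                 foci = foci, focus_radius = params$focus_radius,
                 focus_amp = params$focus_amp)),
    class = "image_stack")
}

voxel_grid <- function(dim) {
  list(x = array(rep(seq_len(dim[1L]), times = dim[2L] * dim[3L]), dim),
       y = array(rep(rep(seq_len(dim[2L]), each = dim[1L]), times = dim[3L]),
                 dim),
       z = array(rep(seq_len(dim[3L]), each = dim[1L] * dim[2L]), dim))
}

ellipsoid_mask <- function(dim, centre, axes) {
  g <- voxel_grid(dim)
  ((g$x - centre[1L]) / axes[1L])^2 + ((g$y - centre[2L]) / axes[2L])^2 +
    ((g$z - centre[3L]) / axes[3L])^2 <= 1
}

#' Write / read an image stack as multi-page TIFF
#'
#' Channels are written as separate files (one z-page per slice),
#' intensities scaled to [0, 1] 16-bit on disk with the scale recorded in
#' the return value.
#'
#' @param stack an \code{image_stack}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named vector of file paths, invisibly.
#' @export
write_image_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    mx <- max(a, 1)
    pages <- lapply(seq_len(dim(a)[3L]), function(z) a[, , z] / mx)
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    paths[ch] <- path
  }
  invisible(paths)
}

#' @rdname write_image_stack
#' @param paths named character vector of per-channel TIFF paths.
#' @param voxel_size micrometres per voxel (x, y, z).
#' @export
read_image_stack <- function(paths, voxel_size) {
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    simplify2array(pages)
  })
  structure(list(channels = channels, voxel_size = voxel_size,
                 truth = NULL),
            class = "image_stack")
}
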