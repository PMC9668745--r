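#' Simulation parameters with planted, recoverable effects
#'
#' Bundles every knob of the synthetic-data generator: the genome layout,
#' the planted ChIP enrichment model, the Hi-C contact model with its
#' genotype effects, and the 3D image geometry. Defaults define the study
#' conditions the pipeline is tested under; they are chosen for statistical
#' recoverability at desk scale, not to match any deposited data set.
#'
#' The planted per-window enrichment model for the sperm-specific H2B
#' variant is
#' \deqn{e = \beta_0 + \beta_T \log_{10}(TPM + 0.01) + \beta_{GC}(GC - 0.5)
#'   + \delta_{class} + N(0, \sigma^2)}
#' with IP counts Poisson(\eqn{\lambda_{in} 2^e}) against Poisson
#' (\eqn{\lambda_{in}}) input. Negative \eqn{\beta_T} and \eqn{\beta_{GC}}
#' plant the anticorrelation of the variant with transcription and GC
#' content.
#'
#' @param seed master seed; all artifact streams are derived from it.
#' @param n_chrom,chrom_length genome layout (bp).
#' @param peri_frac fraction of each chromosome occupied by the central
#'   pericentromere, in (0, 1).
#' @param track_step coverage-track window width (bp).
#' @param beta0,betaT,betaGC,sigma planted enrichment model coefficients
#'   (log2 units) and Gaussian noise sd.
#' @param class_offset named log2 offsets for gene / TE_eu / TE_het /
#'   intergenic windows.
#' @param lambda_in mean input count per window.
#' @param silent_frac fraction of genes with TPM 0.
#' @param gc_mean named per-class mean GC fraction; \code{gc_sd} the
#'   per-window spread.
#' @param gc_sd per-window GC standard deviation.
#' @param k9_mu,k9_sd two-component H3K9me2 model: means (euchromatic,
#'   heterochromatic) and common sd, log2 units.
#' @param hic_binsize,hic_depth Hi-C bin width (bp) and expected total
#'   contacts.
#' @param decay_gamma,d0 power-law distance decay: expected contacts
#'   proportional to \code{(d + d0)^-decay_gamma}.
#' @param gamma_short,gamma_peri,delta_interperi planted genotype effects:
#'   short-range (200 kb to 1.1 Mb) gain and pericentromere-arm gain scale
#'   with local enrichment; inter-chromosomal pericentromere contacts are
#'   reduced by \code{delta_interperi}.
#' @param hic_band short-range band limits in bp (inclusive).
#' @param inter_distance effective distance (bp) setting the
#'   inter-chromosomal baseline contact level.
#' @param voxel_size micrometres per voxel along x, y, z.
#' @param image_dim stack dimensions in voxels (x, y, z).
#' @param nucleus_axes ellipsoid semi-axes in voxels (x, y, z).
#' @param n_foci,focus_radius,focus_amp foci count, Gaussian sd in voxels
#'   and peak amplitude above the plateau.
#' @param background,plateau_dna,plateau_marker image intensity levels.
#' @return an object of class \code{sim_params} (a named list).
#' @export
sim_params <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 2e6, peri_frac = 0.25,
                       track_step = 50L,
                       beta0 = 0.4, betaT = -0.5, betaGC = -4, sigma = 0.3,
                       class_offset = c(gene = 0, TE_eu = 0.4, TE_het = -0.4,
                                        intergenic = 0),
                       lambda_in = 50,
                       silent_frac = 0.4,
                       gc_mean = c(gene = 0.38, TE_eu = 0.32, TE_het = 0.42,
                                   intergenic = 0.36),
                       gc_sd = 0.04,
                       k9_mu = c(-0.5, 1.5), k9_sd = 0.3,
                       hic_binsize = 1000L, hic_depth = 1e7,
                       decay_gamma = 1.0, d0 = 1e4,
                       gamma_short = 0.5, gamma_peri = 0.5,
                       delta_interperi = 0.3,
                       hic_band = c(2e5, 1.1e6),
                       inter_distance = 2e6,
                       voxel_size = c(0.04, 0.04, 0.125),
                       image_dim = c(64L, 64L, 16L),
                       nucleus_axes = c(20, 18, 6),
                       n_foci = 5L, focus_radius = 2.5, focus_amp = 150,
                       background = 10, plateau_dna = 80,
                       plateau_marker = 50) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (lambda_in <= 0) stop("lambda_in must be > 0")
  if (decay_gamma <= 0) stop("decay_gamma must be > 0")
  if (peri_frac <= 0 || peri_frac >= 1)
    stop("peri_frac must lie in (0, 1)")
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

#' Write a plain-text manifest of all simulation parameters
#'
#' Records every parameter and the master seed of a run as YAML so that any
#' synthetic artifact can be regenerated exactly.
#'
#' @param params a \code{sim_params} object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  yaml::write_yaml(lapply(unclass(params), function(x)
    if (is.numeric(x)) unname(x) else x), path)
  # named vectors flattened above; keep names where they matter
  named <- Filter(function(n) !is.null(names(params[[n]])),
                  names(unclass(params)))
  if (length(named)) {
    extra <- lapply(named, function(n) as.list(params[[n]]))
    names(extra) <- paste0(named, "_named")
    yaml::write_yaml(c(lapply(unclass(params), function(x)
      if (is.numeric(x)) unname(x) else x), extra), path)
  }
  invisible(path)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (seed ", x$seed, "):\n", sep = "")
  cat("  genome: ", x$n_chrom, " x ", x$chrom_length / 1e6,
      " Mb, pericentromere fraction ", x$peri_frac, "\n", sep = "")
  cat("  enrichment: beta0=", x$beta0, " betaT=", x$betaT,
      " betaGC=", x$betaGC, " sigma=", x$sigma,
      " lambda_in=", x$lambda_in, "\n", sep = "")
  cat("  hic: ", x$hic_binsize, "-bp bins, depth ", x$hic_depth,
      ", gamma=", x$decay_gamma,
      ", effects (", x$gamma_short, ", ", x$gamma_peri, ", ",
      x$delta_interperi, ")\n", sep = "")
  invisible(x)
}
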