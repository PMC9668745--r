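#' @import data.table
#' @importFrom stats rnorm rpois rlnorm runif aov anova TukeyHSD t.test
#'   fisher.test chisq.test pchisq cor prcomp lm coef quantile density median
#'   setNames complete.cases rbinom AIC
#' @importFrom utils head tail combn
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a named sub-stream seed from a master seed
#'
#' Each artifact type draws from its own pseudo-random stream so that adding
#' an artifact to a run never perturbs the others. The sub-seed is a
#' deterministic hash of the master seed and the stream name, kept below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"genome"`, `"chip/H2B.8"`.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(paste(name, collapse = "/"))) h <- (h * 131 + ch) %% m
  as.integer(((abs(master) %% m) * 48271 + h) %% m)
}

# 0-based half-open interval checks used by the simulators and validators.
check_intervals <- function(dt, chrom_len, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  if (nrow(dt) == 0L) return(invisible(TRUE))
  if (any(dt$start < 0) || any(dt$start >= dt$end))
    stop(what, "s must satisfy 0 <= start < end")
  len <- chrom_len[dt$chrom]
  if (anyNA(len) || any(dt$end > len))
    stop(what, "s must lie within chromosome bounds")
  invisible(TRUE)
}

# Tile [0, len) with fixed-width windows; a trailing short window is dropped
# when drop_short, else kept and flagged.
tile_windows <- function(chromosomes, step, drop_short = TRUE) {
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    len <- as.integer(chromosomes$length[i])
    step <- as.integer(step)
    n_full <- len %/% step
    starts <- seq.int(0L, by = step, length.out = n_full)
    ends <- starts + step
    short <- rep(FALSE, n_full)
    if (!drop_short && len %% step > 0L) {
      starts <- c(starts, n_full * step)
      ends <- c(ends, len)
      short <- c(short, TRUE)
    }
    data.table(chrom = chromosomes$chrom[i], start = starts, end = ends,
               short = short)
  })
  rbindlist(out)
}

# Overlap join with 0-based half-open semantics (data.table::foverlaps works
# on closed intervals, so ends are shifted by one base). Returns xid/yid
# pairs of genuinely overlapping intervals.
overlap_pairs <- function(x, y) {
  xi <- x[, .(chrom, start, end = end - 1L)]
  yi <- y[, .(chrom, start, end = end - 1L, orig = .I)]
  setkey(yi, chrom, start, end)
  hits <- foverlaps(xi, yi, type = "any", which = TRUE, nomatch = NULL)
  hits <- hits[!is.na(yid)]
  hits[, yid := yi$orig[yid]]
  hits[]
}

# Equal-count quantile grouping with ties assigned to the lower group.
quantile_groups <- function(x, n_groups) {
  n <- length(x)
  if (n_groups > n) stop("more groups than observations")
  r <- rank(x, ties.method = "min")
  as.integer(ceiling(r * n_groups / n))
}
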