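#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#' Zero variance in either rank vector leaves the coefficient undefined;
#' this is signalled with a warning and an \code{NA} statistic.
#'
#' @param x,y numeric vectors of equal length (at least 3 pairs); pairs
#'   with missing values are dropped.
#' @return a \code{correlation_result}: list with statistic, n, method.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("rank variance is zero; correlation undefined")
    rho <- NA_real_
  } else rho <- cor(rx, ry)
  structure(list(statistic = rho, n = length(x), method = "spearman"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.4f (n = %d)\n", x$method, x$statistic,
              x$n))
  invisible(x)
}

#' Principal component analysis of chromatin features
#'
#' Variables (columns) are centred and scaled to unit variance; components
#' come from the correlation structure, so explained variances sum to the
#' number of variables. Signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param m numeric matrix or data.frame, observations (genomic regions or
#'   windows) in rows, variables in columns.
#' @return a list with loadings, scores and explained (variance units).
#' @export
chromatin_pca <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L || nrow(m) < 3L)
    stop("need at least 2 variables and 3 observations")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  rotation <- sweep(p$rotation, 2L, flip, `*`)
  scores <- sweep(p$x, 2L, flip, `*`)
  list(loadings = rotation, scores = scores, explained = p$sdev^2)
}

#' Ordinary least squares with adjusted R-squared and AIC
#'
#' Gaussian maximum-likelihood AIC convention counting the intercept and
#' the variance: \code{AIC = n log(2 pi RSS / n) + n + 2 (k + 2)} for
#' \code{k} predictors. A perfect fit (RSS 0) reports \code{-Inf}.
#'
#' @param y response vector.
#' @param X data.frame (or matrix) of predictors; must have full column
#'   rank after expansion (factors allowed).
#' @return a \code{model_fit}: list with coefficients, se, n, k, rss,
#'   r_squared, adj_r_squared, aic.
#' @export
fit_linear_model <- function(y, X) {
  X <- as.data.frame(X)
  mm <- stats::model.matrix(~ ., data = X)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  dat <- cbind(data.frame(.y = y), X)
  fit <- lm(.y ~ ., data = dat)
  n <- length(y)
  k <- length(coef(fit)) - 1L
  if (n <= k + 1L) stop("need n > k + 1 observations")
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  perfect <- rss <= 1e-12 * max(tss, 1)   # numerically exact fit
  if (perfect) { rss <- 0; r2 <- 1; adj <- 1 }
  aic <- if (perfect) -Inf else AIC(fit)
  sm <- suppressWarnings(summary(fit))
  structure(list(coefficients = coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 n = n, k = k, rss = rss, r_squared = r2,
                 adj_r_squared = adj, aic = aic, lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("linear model: n = %d, k = %d, adj R^2 = %.4f, AIC = %.1f\n",
              x$n, x$k, x$adj_r_squared, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Incremental (nested) model selection
#'
#' Fits the nested sequence of models over the first m predictors of
#' \code{order} for m = 1..length(order), plus every single-variable
#' model, reporting adjusted R-squared and AIC for each. Models whose
#' design is rank deficient are reported as skipped rather than fitted.
#'
#' @param y response vector.
#' @param X data.frame of candidate predictors.
#' @param order character vector naming the addition order (a subset of
#'   \code{names(X)}, no duplicates).
#' @return a data.table with model (label), variables, k, adj_r2, aic,
#'   skipped.
#' @export
incremental_model_selection <- function(y, X, order = names(X)) {
  X <- as.data.frame(X)
  if (anyDuplicated(order)) stop("duplicate names in `order`")
  if (!all(order %in% names(X))) stop("`order` names missing from X")
  one_fit <- function(vars, label) {
    fit <- tryCatch(fit_linear_model(y, X[, vars, drop = FALSE]),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.table(model = label, variables = paste(vars, collapse = "+"),
                 k = NA_integer_, adj_r2 = NA_real_, aic = NA_real_,
                 skipped = TRUE, reason = conditionMessage(fit))
    else
      data.table(model = label, variables = paste(vars, collapse = "+"),
                 k = fit$k, adj_r2 = fit$adj_r_squared, aic = fit$aic,
                 skipped = FALSE, reason = "")
  }
  singles <- rbindlist(lapply(order, function(v)
    one_fit(v, paste0("single:", v))))
  nested <- rbindlist(lapply(seq_along(order), function(m)
    one_fit(order[seq_len(m)], paste0("nested:", m))))
  rbindlist(list(singles, nested))
}

#' Assemble the window-level feature matrix for regression
#'
#' Joins the response enrichment with predictor tracks and covariates on a
#' common window grid; windows with any missing cell are dropped and
#' counted.
#'
#' @param response an \code{enrichment_track} (the histone-variant signal).
#' @param predictors named list of \code{enrichment_track}s and/or numeric
#'   vectors aligned to the response grid.
#' @param covariates optional data.table aligned to the grid (e.g. gc,
#'   transcription transform).
#' @return a data.table with chrom, start, end, y and predictor columns;
#'   attribute \code{n_dropped}.
#' @export
build_feature_matrix <- function(response, predictors = list(),
                                 covariates = NULL) {
  out <- as.data.table(response)[, .(chrom, start, end, y = value)]
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    if (inherits(p, "enrichment_track")) {
      if (!same_grid(response, p)) stop("grid mismatch for ", nm)
      out[, (nm) := p$value]
    } else {
      if (length(p) != nrow(out)) stop("length mismatch for ", nm)
      out[, (nm) := p]
    }
  }
  if (!is.null(covariates)) {
    cv <- as.data.table(covariates)
    keep <- setdiff(names(cv), c("chrom", "start", "end"))
    if (nrow(cv) != nrow(out)) stop("covariate grid mismatch")
    out[, (keep) := cv[, keep, with = FALSE]]
  }
  ok <- complete.cases(out)
  res <- out[ok]
  setattr(res, "n_dropped", sum(!ok))
  res
}
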