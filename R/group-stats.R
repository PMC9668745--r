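#' One-way ANOVA with Tukey HSD post-hoc tests
#'
#' F is the ratio of between- to within-group mean squares with an
#' upper-tail p-value; all pairwise comparisons use Tukey's honestly
#' significant difference based on the studentized range distribution at
#' the ANOVA residual degrees of freedom.
#'
#' @param groups a named list of numeric samples (each of size >= 2).
#' @return a \code{group_stats} list with statistic (F), df, p_value and
#'   a \code{tukey} table (comparison, diff, p_adj).
#' @export
one_way_anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 observations")
  if (is.null(names(groups)))
    names(groups) <- sprintf("g%d", seq_along(groups))
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L)),
               levels = names(groups)))
  if (stats::var(dat$y) == 0) {
    # degenerate: no variance anywhere; F taken as 0 with p = 1
    cmb <- utils::combn(names(groups), 2L)
    return(structure(list(statistic = 0, df = c(length(groups) - 1L,
                                                nrow(dat) - length(groups)),
                          p_value = 1,
                          tukey = data.table(
                            comparison = paste(cmb[2L, ], cmb[1L, ],
                                               sep = "-"),
                            diff = 0, lwr = 0, upr = 0, p_adj = 1),
                          method = "one-way ANOVA + Tukey HSD"),
                     class = "group_stats"))
  }
  fit <- aov(y ~ g, data = dat)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$g
  structure(list(statistic = an$`F value`[1L],
                 df = c(an$Df[1L], an$Df[2L]),
                 p_value = an$`Pr(>F)`[1L],
                 tukey = data.table(comparison = rownames(tk),
                                    diff = tk[, "diff"],
                                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                                    p_adj = tk[, "p adj"]),
                 method = "one-way ANOVA + Tukey HSD"),
            class = "group_stats")
}

#' Welch two-sample t-test
#'
#' @param a,b numeric samples of size >= 2.
#' @return a \code{group_stats} list with statistic (t), df, p_value
#'   (two-sided).
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations")
  tt <- t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value, method = "Welch two-sample t"),
            class = "group_stats")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one. The reported odds ratio is the sample
#' cross-product ratio; the conditional maximum-likelihood estimate is
#' also returned.
#'
#' @param tab a 2x2 matrix of non-negative counts.
#' @return a \code{group_stats} list with statistic (odds ratio),
#'   \code{or_mle}, p_value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("table must be 2x2")
  if (any(tab < 0)) stop("negative cell")
  ft <- fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(statistic = or_sample,
                 or_mle = unname(ft$estimate),
                 p_value = ft$p.value, method = "Fisher exact (2x2)"),
            class = "group_stats")
}

#' Chi-squared goodness of fit against an expected ratio
#'
#' \code{chi2 = sum (O - E)^2 / E} with E proportional to the expected
#' ratio, df = cells - 1, upper-tail p. Expected cells below 1 trigger a
#' warning.
#'
#' @param observed integer counts.
#' @param expected_ratio expected proportions (any positive weights).
#' @return a \code{group_stats} list with statistic, df, p_value,
#'   expected.
#' @export
chi_square_gof <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio))
    stop("observed and expected lengths differ")
  expected <- sum(observed) * expected_ratio / sum(expected_ratio)
  if (any(expected < 1)) warning("expected cell count below 1")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 expected = expected, method = "chi-squared GOF"),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}
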