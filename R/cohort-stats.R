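#' @include utils.R
NULL

#' Bland-Altman agreement analysis
#'
#' Agreement between two paired measurement series: differences are taken
#' as `x - y`; the bias is their mean, and the limits of agreement are
#' `bias +/- kSd * SD(diff)`. The default `kSd = 2` matches the common
#' "plus or minus 2 SD" reporting; `kSd = 1.96` gives the asymptotic 95
#' percent limits. A paired t-test p-value for bias different from zero is
#' attached; with zero-variance differences the conventions are p = 1 for
#' zero bias (logged) and p = 0 otherwise.
#'
#' @param x,y paired numeric series of equal length >= 3, no missing pairs.
#' @param kSd the limit multiplier (default 2).
#' @return A list of class `BlandAltmanResult`: `bias`, `sdDiff`, `lower`,
#'   `upper`, `n`, `p`, `kSd`, and `data` (data.frame of pair means vs
#'   differences, ready for plotting).
#' @examples
#' blandAltman(c(1, 2, 3, 4), c(1.1, 2.4, 2.9, 4.2))
#' @export
blandAltman <- function(x, y, kSd = 2) {
  if (length(x) != length(y))
    stopf("x and y must be paired series of equal length (%d vs %d)",
          length(x), length(y))
  if (length(x) < 3L) stopf("at least 3 pairs required")
  if (anyNA(x) || anyNA(y)) stopf("missing values in paired series")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  if (s < 1e-15) {
    if (abs(bias) < 1e-15) {
      message("identical series: bias 0, p = 1 by convention")
      p <- 1
    } else {
      message("constant non-zero differences: p = 0 by convention")
      p <- 0
    }
  } else {
    p <- t.test(x, y, paired = TRUE)$p.value
  }
  structure(list(bias = bias, sdDiff = s, lower = bias - kSd * s,
                 upper = bias + kSd * s, n = length(x), p = p, kSd = kSd,
                 data = data.frame(mean = (x + y) / 2, diff = d)),
            class = "BlandAltmanResult")
}

#' @export
print.BlandAltmanResult <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g [%.4g, %.4g] (+/- %g SD), p = %.3g\n",
              x$n, x$bias, x$lower, x$upper, x$kSd, x$p))
  invisible(x)
}

#' Spearman rank correlation with strength label
#'
#' Rank correlation with average ranks for ties; the p-value uses the t
#' approximation. The absolute coefficient is labelled with the
#' conventional strength bins: very weak 0.00-0.19, weak 0.20-0.39,
#' moderate 0.40-0.59, strong 0.60-0.79, very strong >= 0.80.
#'
#' @param x,y numeric series of equal length >= 4.
#' @return A list of class `CorrelationResult`: `rho`, `p`, `n`,
#'   `strength`.
#' @examples
#' spearmanCorr(1:10, (1:10)^3)$strength  # monotone: "very strong"
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stopf("series must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("at least 4 complete pairs required")
  if (sd(x) < 1e-15 || sd(y) < 1e-15)
    stopf("Spearman correlation undefined for a constant series")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  structure(list(rho = rho, p = ct$p.value, n = length(x),
                 strength = correlationStrength(rho)),
            class = "CorrelationResult")
}

#' Strength label of a correlation coefficient
#'
#' @param rho correlation coefficient in [-1, 1].
#' @return `"very weak"` (|rho| < 0.20), `"weak"` (< 0.40), `"moderate"`
#'   (< 0.60), `"strong"` (< 0.80) or `"very strong"` (>= 0.80).
#' @examples
#' correlationStrength(0.60)  # "strong"
#' @export
correlationStrength <- function(rho) {
  stopifnot(all(abs(rho) <= 1 + 1e-12))
  cut(abs(rho), breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf), right = FALSE,
      labels = c("very weak", "weak", "moderate", "strong", "very strong")) |>
    as.character()
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (%s), n = %d, p = %.3g\n",
              x$rho, x$strength, x$n, x$p))
  invisible(x)
}

#' Paired t-test
#'
#' Standard paired t-test on the differences `x - y`. Zero-variance
#' differences use the same conventions as [blandAltman()]: t = 0 and
#' p = 1 when the mean difference is also zero (logged), otherwise p = 0.
#'
#' @param x,y paired numeric series of equal length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stopf("paired series must have equal length")
  if (length(x) < 2L) stopf("at least 2 pairs required")
  d <- x - y
  if (sd(d) < 1e-15) {
    if (abs(mean(d)) < 1e-15) {
      message("identical series: t = 0, p = 1 by convention")
      return(list(t = 0, df = length(x) - 1L, p = 1))
    }
    message("constant non-zero differences: p = 0 by convention")
    return(list(t = sign(mean(d)) * Inf, df = length(x) - 1L, p = 0))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Omnibus one-way ANOVA across the groups, followed by all pairwise
#' t-tests using the pooled within-group standard deviation, with each
#' p-value multiplied by the number of comparisons performed (capped at
#' 1). Groups with fewer than 2 values are excluded with a warning.
#'
#' @param groups named list of numeric vectors (at least 2 usable groups).
#' @return A list of class `AnovaBonferroniResult`: `F`, `df` (numeric(2)),
#'   `p`, and `pairwise` (data.frame `group1`, `group2`, `p_adj`).
#' @export
anovaBonferroni <- function(groups) {
  stopifnot(is.list(groups))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warnf("excluding group(s) with < 2 values: %s",
          paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) stopf("at least 2 groups with >= 2 values required")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- aov(value ~ grp)
  tab <- anova(fit)
  pw <- pairwise.t.test(value, grp, p.adjust.method = "bonferroni",
                        pool.sd = TRUE)$p.value
  idx <- which(!is.na(pw), arr.ind = TRUE)
  pairwise <- data.frame(group1 = rownames(pw)[idx[, 1]],
                         group2 = colnames(pw)[idx[, 2]],
                         p_adj = pw[idx])
  structure(list(F = tab$`F value`[1], df = c(tab$Df[1], tab$Df[2]),
                 p = tab$`Pr(>F)`[1], pairwise = pairwise),
            class = "AnovaBonferroniResult")
}

#' @export
print.AnovaBonferroniResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Bonferroni-adjusted pairwise comparisons:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
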