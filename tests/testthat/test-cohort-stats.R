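# Independent closed-form oracles, written against the textbook formulas.
oracleSpearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  rho <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))      # no-ties formula
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2))
}
oraclePairedT <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}
oracleAnova <- function(groups) {
  k <- length(groups); n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, p = pf(Fv, k - 1, n - k, lower.tail = FALSE),
       mse = ssw / (n - k), dfw = n - k)
}

test_that("Bland-Altman bias, limits and degenerate conventions", {
  x <- c(1, 2, 3, 4, 5)
  suppressMessages({
    ba0 <- blandAltman(x, x)
    expect_equal(ba0$bias, 0)
    expect_equal(ba0$lower, 0); expect_equal(ba0$upper, 0)
    expect_equal(ba0$p, 1)
    ba2 <- blandAltman(x, x + 2)
    expect_equal(ba2$bias, -2)
    expect_equal(ba2$sdDiff, 0)
    expect_equal(ba2$p, 0)
  })
  # limits symmetric about the bias; k scales them
  set.seed(4)
  a <- rnorm(50); b <- a + rnorm(50, 0.3, 0.5)
  ba <- blandAltman(a, b)
  expect_equal(ba$upper - ba$bias, ba$bias - ba$lower, tolerance = 1e-12)
  expect_equal(ba$upper - ba$lower, 2 * ba$kSd * ba$sdDiff, tolerance = 1e-12)
  expect_equal(blandAltman(a, b, kSd = 1.96)$upper - ba$bias,
               1.96 * ba$sdDiff, tolerance = 1e-12)
  expect_equal(ba$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_error(blandAltman(1:4, 1:5), "equal length")
})

test_that("Bland-Altman 1.96 SD limits contain about 95% of Gaussian differences", {
  set.seed(11)
  x <- rnorm(4000); y <- x - rnorm(4000, 1, 0.8)
  ba <- blandAltman(x, y, kSd = 1.96)
  inside <- mean(ba$data$diff >= ba$lower & ba$data$diff <= ba$upper)
  expect_gt(inside, 0.93); expect_lt(inside, 0.97)
  # k = 2 limits are slightly wider
  ba2 <- blandAltman(x, y, kSd = 2)
  expect_gt(ba2$upper, ba$upper)
})

test_that("Spearman matches the closed-form rank formula to 1e-9", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(2.0, 3.1, 4.9, 6.5, 5.1)
  got <- spearmanCorr(x, y)
  ref <- oracleSpearman(x, y)
  expect_equal(got$rho, ref$rho, tolerance = 1e-9)
  expect_equal(got$p, ref$p, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    got <- spearmanCorr(a, b); ref <- oracleSpearman(a, b)
    expect_equal(got$rho, ref$rho, tolerance = 1e-9)
    expect_equal(got$p, ref$p, tolerance = 1e-9)
  }
})

test_that("Spearman is invariant under monotone transforms and labels strength", {
  set.seed(9)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.4)
  base <- spearmanCorr(x, y)
  expect_equal(spearmanCorr(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearmanCorr(x, y^3 + 5 * y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearmanCorr(1:10, (1:10)^3)$rho, 1)
  expect_identical(spearmanCorr(1:10, (1:10)^3)$strength, "very strong")
  expect_identical(correlationStrength(0.60), "strong")
  expect_identical(correlationStrength(0.599), "moderate")
  expect_identical(correlationStrength(c(0.1, 0.2, 0.4, 0.8)),
                   c("very weak", "weak", "moderate", "very strong"))
  expect_error(spearmanCorr(rep(1, 5), 1:5), "constant")
})

test_that("paired t matches hand computation; p vanishes for a real shift", {
  x <- c(12.1, 14.3, 11.8, 15.0, 13.3)
  y <- c(11.0, 13.1, 12.0, 13.8, 12.4)
  got <- pairedT(x, y)
  ref <- oraclePairedT(x, y)
  expect_equal(got$t, ref$t, tolerance = 1e-9)
  expect_equal(got$df, ref$df)
  expect_equal(got$p, ref$p, tolerance = 1e-9)
  suppressMessages(expect_equal(pairedT(x, x), list(t = 0, df = 4L, p = 1)))
  set.seed(13)
  big <- rnorm(200)
  expect_lt(pairedT(big + 1, big + rnorm(200, 0, 0.01))$p, 1e-10)
})

test_that("one-way ANOVA and Bonferroni match hand formulas to 1e-9", {
  set.seed(17)
  groups <- list(a = rnorm(8, 0), b = rnorm(9, 0.5), c = rnorm(7, 1.2))
  got <- anovaBonferroni(groups)
  ref <- oracleAnova(groups)
  expect_equal(got$F, ref$F, tolerance = 1e-9)
  expect_equal(got$p, ref$p, tolerance = 1e-9)
  # pairwise pooled-SD t with Bonferroni multiplication, by hand
  m <- nrow(got$pairwise)
  expect_equal(m, 3L)
  for (r in seq_len(m)) {
    g1 <- groups[[got$pairwise$group1[r]]]; g2 <- groups[[got$pairwise$group2[r]]]
    t <- (mean(g1) - mean(g2)) /
      sqrt(ref$mse * (1 / length(g1) + 1 / length(g2)))
    pRaw <- 2 * pt(-abs(t), ref$dfw)
    expect_equal(got$pairwise$p_adj[r], min(1, pRaw * m), tolerance = 1e-9)
  }
})

test_that("ANOVA degenerate and identity cases behave", {
  g <- rnorm(10)
  same <- anovaBonferroni(list(a = g, b = g, c = g))
  expect_lt(same$F, 1e-20)
  expect_true(all(same$pairwise$p_adj == 1))
  # two groups: F = t^2 and identical p
  set.seed(19)
  g1 <- rnorm(12); g2 <- rnorm(12, 0.7)
  two <- anovaBonferroni(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(two$p, tt$p.value, tolerance = 1e-9)
  expect_warning(res <- anovaBonferroni(list(a = g1, b = g2, c = 1)),
                 "excluding")
  expect_equal(nrow(res$pairwise), 1L)
  expect_error(suppressWarnings(anovaBonferroni(list(a = g1, b = 2))),
               "at least 2 groups")
})

test_that("ordered groups with a 1 SD effect are detected at n = 20 per group", {
  set.seed(23)
  groups <- lapply(0:3, function(k) rnorm(20, mean = k * 1, sd = 1))
  names(groups) <- c("mild", "moderate", "severe", "very_severe")
  res <- anovaBonferroni(groups)
  expect_lt(res$p, 0.05)
})
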