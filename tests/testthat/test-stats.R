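# construct n paired values whose differences have an exact mean and SD
pairs_with <- function(bias, sd, n = 9) {
  d <- scale(seq_len(n))[, 1] * sd + bias
  b <- seq(10, 20, length.out = n)
  list(a = b + d, b = b)
}

test_that("Bland-Altman limits follow bias plus/minus 1.96 SD", {
  # a typical intra-observer agreement row: bias -0.91 +/- 1.56
  p <- pairs_with(-0.91, 1.56)
  ba <- bland_altman(p$a, p$b)
  expect_equal(round(c(ba$lower, ba$upper), 2), c(-3.97, 2.15))
  # a wider radial-strain agreement row: bias 1.28 +/- 4.23
  p2 <- pairs_with(1.28, 4.23)
  ba2 <- bland_altman(p2$a, p2$b)
  expect_equal(round(c(ba2$lower, ba2$upper), 2), c(-7.01, 9.57))
  # identical raters
  x <- rnorm(6)
  ba3 <- bland_altman(x, x)
  expect_equal(c(ba3$bias, ba3$sd, ba3$lower, ba3$upper), c(0, 0, 0, 0))
  # antisymmetry under swapping the raters
  ba4 <- bland_altman(p$b, p$a)
  expect_equal(ba4$bias, -ba$bias)
  expect_equal(ba4$lower, -ba$upper)
  expect_equal(ba4$upper, -ba$lower)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("coefficient of variation is scale-free and matches hand computation", {
  p <- pairs_with(0.5, 2)
  cv <- coefficient_of_variation(p$a, p$b)
  expect_equal(cv, 100 * sd(p$a - p$b) / mean(abs((p$a + p$b) / 2)),
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(3 * p$a, 3 * p$b), cv,
               tolerance = 1e-12)
  x <- rnorm(5)
  expect_equal(coefficient_of_variation(x + 10, x + 10), 0)
  expect_lt(coefficient_of_variation(p$a, p$b, "within_subject"), cv)
})

test_that("ICC equals the brute-force ANOVA decomposition", {
  # 4-subject, 2-rater hand table
  x <- rbind(c(9, 2), c(1, 10), c(8, 4), c(6, 8))
  n <- 4; k <- 2
  grand <- mean(x)
  MSR <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  SSE <- 0
  for (i in 1:n) for (j in 1:k)
    SSE <- SSE + (x[i, j] - rowMeans(x)[i] - colMeans(x)[j] + grand)^2
  MSE <- SSE / ((n - 1) * (k - 1))
  brute <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  ic <- icc(x)
  expect_equal(ic$icc, brute, tolerance = 1e-10)
  expect_lte(ic$icc, 1)
  # interval sanity on a well-behaved strong-agreement table
  set.seed(13)
  g <- rnorm(12, -15, 4)
  ic2 <- icc(g, g + rnorm(12, 0, 0.8))
  expect_lte(ic2$lower, ic2$icc)
  expect_gte(ic2$upper, ic2$icc)
  # identical raters: perfect agreement
  y <- rnorm(8)
  expect_equal(icc(y, y)$icc, 1, tolerance = 1e-12)
  # independent raters at large n: near zero
  set.seed(31)
  expect_lt(abs(icc(rnorm(4000), rnorm(4000))$icc), 0.05)
  expect_error(icc(rbind(c(1, 1), c(2, 2))), "3 subjects")
})

test_that("ROC on strain magnitudes: AUC equals the Mann-Whitney statistic", {
  set.seed(41)
  for (rep in 1:5) {
    vals <- -sample(seq(2, 30, by = 2), 24, replace = TRUE) # ties on purpose
    lab <- sample(c("control", "HFpEF"), 24, replace = TRUE,
                  prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    r <- roc_strain(vals, lab, positive = "HFpEF")
    mag <- abs(vals)
    pos <- mag[lab == "HFpEF"]
    neg <- mag[lab != "HFpEF"]
    U <- 0
    for (p in pos) for (q in neg) U <- U + (p < q) + 0.5 * (p == q)
    expect_equal(r$auc, U / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("ROC extremes, invariance and cutoff conventions hold", {
  # perfectly separated: diseased strains have smaller magnitude
  vals <- c(-5, -6, -7, -20, -21, -22)
  lab <- c("HFpEF", "HFpEF", "HFpEF", "control", "control", "control")
  r <- roc_strain(vals, lab, "HFpEF")
  expect_equal(c(r$auc, r$sensitivity, r$specificity), c(1, 1, 1))
  expect_gt(r$cutoff, 7)
  expect_lte(r$cutoff, 20)
  # monotone transform of magnitudes leaves AUC unchanged
  r2 <- roc_strain(-(abs(vals)^3), lab, "HFpEF")
  expect_equal(r2$auc, r$auc)
  # shuffled labels at large n: AUC near 0.5
  set.seed(51)
  v <- rnorm(2000, -15, 4)
  l <- sample(c("a", "b"), 2000, replace = TRUE)
  expect_lt(abs(roc_strain(v, l, "a")$auc - 0.5), 0.05)
  expect_error(roc_strain(1:3, rep("a", 3), "a"), "both classes")
})

test_that("ROC agrees with an independent implementation", {
  set.seed(61)
  vals <- c(rnorm(20, -10, 3), rnorm(20, -16, 3))
  lab <- rep(c("HFpEF", "control"), each = 20)
  r <- roc_strain(vals, lab, "HFpEF")
  pr <- pROC::roc(response = lab == "HFpEF", predictor = abs(vals),
                  direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("group comparison gates tests by normality and handles categories", {
  set.seed(71)
  x <- exp(rnorm(30, 0, 2))  # skewed: routed to the rank test
  d_same <- data.frame(v = c(x, x), g = rep(c("a", "b"), each = 30))
  res <- group_compare(d_same, "g")
  expect_identical(res$test, "mann-whitney")
  expect_gt(res$p[res$variable == "v"], 0.9)
  d_gap <- data.frame(v = c(rnorm(40), rnorm(40, 5)),
                      g = rep(c("a", "b"), each = 40))
  expect_lt(group_compare(d_gap, "g")$p, 0.05)
  # heavily skewed data routes to the rank test
  d_skew <- data.frame(v = c(exp(rnorm(40, 0, 2)), exp(rnorm(40, 0, 2))),
                       g = rep(c("a", "b"), each = 40))
  expect_identical(group_compare(d_skew, "g")$test, "mann-whitney")
  # categorical variable: Fisher p equals exhaustive hypergeometric sum
  cat_tab <- data.frame(sex = rep(c("m", "f", "m", "m"), 5)[1:18],
                        g = rep(c("a", "b"), 9))
  res2 <- group_compare(cat_tab, "g")
  tab <- table(cat_tab$sex, cat_tab$g)
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  probs <- dhyper(0:min(m1, n1), m1, m2, n1)
  p_enum <- sum(probs[probs <= dhyper(tab[1, 1], m1, m2, n1) * (1 + 1e-7)])
  expect_equal(res2$p[res2$variable == "sex"], p_enum, tolerance = 1e-10)
})

test_that("agreement report assembles the conventional table", {
  set.seed(81)
  tab <- expand.grid(subject = 1:9, region = c("LV_FREE", "RV_FREE"),
                     component = c("CC", "LL"), stringsAsFactors = FALSE)
  tab$a <- rnorm(nrow(tab), -15, 3)
  tab$b <- tab$a + rnorm(nrow(tab), 0.3, 0.8)
  rep <- agreement_report(tab)
  expect_identical(nrow(rep), 4L)
  expect_true(all(c("bias", "loa_lower", "loa_upper", "cv_percent",
                    "icc") %in% names(rep)))
  expect_true(all(rep$loa_lower < rep$loa_upper))
  expect_true(all(rep$icc > 0.8))
})
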