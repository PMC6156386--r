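#' Bland-Altman agreement analysis
#'
#' Paired differences `d = A - B`, their mean (bias), sample SD, and the
#' 95% limits of agreement `bias +/- 1.96 SD`.
#'
#' @param a,b paired measurements (two observers or two sessions), percent
#'   strain or any common unit.
#' @return list with `bias`, `sd`, `lower`, `upper`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) ws_stopf("paired measurements must have equal length")
  if (length(a) < 2) ws_stopf("at least 2 pairs are required")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       n = length(a))
}

#' Coefficient of variation of paired measurements
#'
#' SD of the paired differences divided by the mean absolute pair mean,
#' in percent: `sd(A - B) / mean(|(A + B)/2|) * 100`.  An alternative
#' within-subject-SD definition (`sd(d)/sqrt(2)` in the numerator) is
#' available, as conventions differ between reproducibility studies.
#'
#' @param a,b paired measurements.
#' @param method `"sd_diff"` (default) or `"within_subject"`.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(a, b, method = c("sd_diff", "within_subject")) {
  method <- match.arg(method)
  if (length(a) != length(b)) ws_stopf("paired measurements must have equal length")
  if (length(a) < 2) ws_stopf("at least 2 pairs are required")
  denom <- mean(abs((a + b) / 2))
  if (denom <= 0) ws_stopf("mean magnitude of the pair means is zero")
  num <- stats::sd(a - b)
  if (method == "within_subject") num <- num / sqrt(2)
  100 * num / denom
}

#' Intraclass correlation coefficient (two-way, absolute agreement, single)
#'
#' ICC(A,1) from the two-way ANOVA mean squares of an n subjects x k raters
#' table, with the conventional F-distribution 95% confidence interval.
#' This is the standard form for observer reproducibility of a single
#' strain measurement.
#'
#' @param a,b paired measurements (k = 2 raters), or pass a matrix via `a`
#'   with subjects in rows and raters in columns.
#' @param conf confidence level for the interval.
#' @return list with `icc`, `lower`, `upper`, the mean squares, `n`, `k`.
#' @export
icc <- function(a, b = NULL, conf = 0.95) {
  x <- if (is.null(b)) as.matrix(a) else cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) ws_stopf("ICC needs at least 3 subjects")
  if (k < 2) ws_stopf("ICC needs at least 2 raters")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + MSC + MSE <= 0) ws_stopf("degenerate table: ICC undefined")
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(denom) < 1e-300) ws_stopf("degenerate variance: ICC undefined")
  est <- (MSR - MSE) / denom
  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 1 - conf
  a_ <- k * est / (n * (1 - est))
  b_ <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a_ * MSC + b_ * MSE)^2 /
       ((a_ * MSC)^2 / (k - 1) + (b_ * MSE)^2 / ((n - 1) * (k - 1)))
  Fl <- stats::qf(1 - alpha / 2, n - 1, v)
  Fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - Fl * MSE) /
           (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (Fu * MSR - MSE) /
           (k * MSC + (k * n - k - n) * MSE + n * Fu * MSE)
  if (!is.finite(lower)) lower <- est
  if (!is.finite(upper)) upper <- 1
  # the F-based bounds are derived for well-behaved tables; clamp them to
  # [-1, 1] and to contain the point estimate
  lower <- min(max(min(lower, 1), -1), est)
  upper <- max(max(min(upper, 1), -1), est)
  list(icc = est, lower = lower, upper = upper,
       MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k)
}

#' ROC analysis of a strain marker
#'
#' Empirical ROC over all thresholds on the strain magnitude, with the
#' polarity "smaller magnitude = diseased" (a failing ventricle deforms
#' less), so printed positive cutoffs are reproducible as |strain|
#' thresholds.  AUC is the trapezoidal area, identical to the
#' Mann-Whitney U statistic divided by n1*n2; the reported cutoff
#' maximizes Youden's J (ties resolved toward the lower cutoff).
#'
#' @param values strain values (sign retained; magnitudes are classified).
#' @param labels class labels, same length.
#' @param positive label of the diseased (positive) class.
#' @return list with `auc`, `cutoff`, `sensitivity`, `specificity`, and
#'   the full `curve` data frame (cutoff, sensitivity, specificity).
#' @export
roc_strain <- function(values, labels, positive) {
  if (length(values) != length(labels)) ws_stopf("values and labels differ in length")
  pos <- labels == positive
  if (!any(pos) || all(pos)) ws_stopf("both classes must be present")
  mag <- abs(values)
  # candidate cutoffs: all observed magnitudes (classify positive if mag < c)
  cand <- sort(unique(c(mag, max(mag) + 1)))
  sens <- vapply(cand, function(cc) mean(mag[pos] < cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(mag[!pos] >= cc), numeric(1))
  # AUC by trapezoid over the full empirical curve (1-spec increasing)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(c(0, fpr[ord], 1)) *
             (c(0, sens[ord]) + c(sens[ord], 1)) / 2)
  J <- sens + spec - 1
  best <- which(J == max(J))[1]  # ties -> lower cutoff (cand is sorted)
  list(auc = auc, cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best],
       curve = data.frame(cutoff = cand, sensitivity = sens,
                          specificity = spec))
}

#' Two-group comparison with normality-gated test choice
#'
#' For each continuous variable, a Shapiro-Wilk test (at 0.05, within each
#' group) gates the choice between an independent t-test and a
#' Mann-Whitney U test; categorical variables (factors / characters with
#' few levels) use Fisher's exact test.  The chosen test is recorded per
#' variable.
#'
#' @param data data frame of variables plus a grouping column.
#' @param group name of the grouping column (exactly 2 levels).
#' @return data frame with variable, test used, and p-value.
#' @export
group_compare <- function(data, group) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) ws_stopf("grouping column must have exactly 2 levels")
  if (any(table(g) < 2)) ws_stopf("each group needs at least 2 observations")
  vars <- setdiff(names(data), group)
  out <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
      normal <- function(z) {
        if (length(unique(z)) < 3 || length(z) < 3) return(FALSE)
        stats::shapiro.test(z)$p.value >= 0.05
      }
      if (normal(x1) && normal(x2)) {
        data.frame(variable = v, test = "t",
                   p = stats::t.test(x1, x2)$p.value)
      } else {
        data.frame(variable = v, test = "mann-whitney",
                   p = stats::wilcox.test(x1, x2, exact = FALSE)$p.value)
      }
    } else {
      tab <- table(factor(x), g)
      data.frame(variable = v, test = "fisher",
                 p = stats::fisher.test(tab)$p.value)
    }
  })
  do.call(rbind, out)
}

#' Reproducibility report for a paired peak-strain table
#'
#' Applies Bland-Altman, coefficient-of-variation and ICC analyses per
#' region/component to a tidy table of paired measurements, producing the
#' conventional agreement table layout.
#'
#' @param table data frame with columns `region`, `component`, `a`, `b`
#'   (paired peak strains in percent; one row per subject).
#' @return data frame with one row per region/component and the agreement
#'   statistics.
#' @export
agreement_report <- function(table) {
  need <- c("region", "component", "a", "b")
  if (!all(need %in% names(table)))
    ws_stopf("table needs columns %s", paste(need, collapse = ", "))
  sp <- split(table, list(table$region, table$component), drop = TRUE)
  out <- lapply(sp, function(d) {
    ba <- bland_altman(d$a, d$b)
    ic <- icc(d$a, d$b)
    data.frame(region = d$region[1], component = d$component[1],
               n = ba$n, bias = ba$bias, sd = ba$sd,
               loa_lower = ba$lower, loa_upper = ba$upper,
               cv_percent = coefficient_of_variation(d$a, d$b),
               icc = ic$icc, icc_lower = ic$lower, icc_upper = ic$upper)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
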