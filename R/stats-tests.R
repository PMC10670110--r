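# Inferential statistics used in the analyses. Where base R already
# provides the test (t.test, cor.test, p.adjust, aov) the operation wraps
# it; the tidy `test_outcome` container keeps downstream code uniform.

test_outcome <- function(statistic, df, p_value, effect, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), effect = unname(effect),
                 method = method),
            class = "test_outcome")
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, effect = %.4g\n",
              x$method, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value, x$effect))
  invisible(x)
}

# zero-variance convention: a constant sample with zero effect is reported
# as t = 0, p = 1 (nothing to detect) rather than an error
degenerate_zero <- function(effect, n, method) {
  if (effect == 0) {
    message("zero-variance sample with zero effect: reporting p = 1")
    return(test_outcome(0, n - 1, 1, 0, method))
  }
  test_outcome(sign(effect) * Inf, n - 1, 0, effect, method)
}

#' One-sample (zero) t-test
#'
#' Tests whether the sample mean differs from zero.
#'
#' @param x numeric sample, `n >= 2`.
#' @return a `test_outcome` (statistic, df, p, mean as effect).
#' @export
ttest_zero <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0) return(degenerate_zero(mean(x), length(x), "one-sample t"))
  tt <- stats::t.test(x, mu = 0)
  test_outcome(tt$statistic, tt$parameter, tt$p.value, mean(x), "one-sample t")
}

#' Independent-samples t-test
#'
#' Pooled-variance by default (the convention of the SPSS analyses this
#' mirrors); set `pooled = FALSE` for Welch.
#'
#' @param x,y numeric samples, each `n >= 2`.
#' @param pooled assume equal variances (default TRUE).
#' @return a `test_outcome` (mean difference as effect).
#' @export
ttest_ind <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 observations per sample")
  eff <- mean(x) - mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(degenerate_zero(eff, length(x) + length(y) - 1, "independent t"))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  test_outcome(tt$statistic, tt$parameter, tt$p.value, eff, "independent t")
}

#' Paired-samples t-test
#'
#' @param x,y paired numeric samples of equal length `>= 2`.
#' @return a `test_outcome` (mean paired difference as effect).
#' @export
ttest_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  if (length(d) < 2) stop("need at least 2 pairs")
  if (stats::sd(d) == 0) return(degenerate_zero(mean(d), length(d), "paired t"))
  tt <- stats::t.test(x, y, paired = TRUE)
  test_outcome(tt$statistic, tt$parameter, tt$p.value, mean(d), "paired t")
}

#' Mixed-design repeated-measures ANOVA
#'
#' One between-subject factor (group) crossed with one within-subject
#' factor (day), subject as random factor, on a complete balanced design.
#' Sums of squares are decomposed by `aov()` with an `Error(subject)`
#' stratum; sphericity is assumed (no epsilon correction), matching the
#' convention of the power computation in [sample_size_rm_anova()].
#'
#' @param data data.frame with columns `subject`, `group`, `day`, `value`.
#' @return data.frame with rows `group`, `day`, `group:day`: columns
#'   `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_mixed <- function(data) {
  need <- c("subject", "group", "day", "value")
  if (!all(need %in% names(data))) stop("data must have columns ", paste(need, collapse = ", "))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$day <- factor(data$day)
  counts <- table(data$group, data$day)
  if (any(counts == 0) || length(unique(as.vector(table(data$subject)))) != 1) {
    stop("design must be complete and balanced (no missing cells)")
  }
  if (stats::var(data$value) == 0) {
    return(data.frame(effect = c("group", "day", "group:day"),
                      df1 = c(nlevels(data$group) - 1, nlevels(data$day) - 1,
                              (nlevels(data$group) - 1) * (nlevels(data$day) - 1)),
                      df2 = NA_real_, F = 0, p = 1))
  }
  fit <- stats::aov(value ~ group * day + Error(subject), data = data)
  sm <- summary(fit)
  btw <- sm[["Error: subject"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  out <- rbind(
    data.frame(effect = "group",
               df1 = btw[rn(btw) == "group", "Df"],
               df2 = btw[rn(btw) == "Residuals", "Df"],
               F = btw[rn(btw) == "group", "F value"],
               p = btw[rn(btw) == "group", "Pr(>F)"]),
    data.frame(effect = "day",
               df1 = wth[rn(wth) == "day", "Df"],
               df2 = wth[rn(wth) == "Residuals", "Df"],
               F = wth[rn(wth) == "day", "F value"],
               p = wth[rn(wth) == "day", "Pr(>F)"]),
    data.frame(effect = "group:day",
               df1 = wth[rn(wth) == "group:day", "Df"],
               df2 = wth[rn(wth) == "Residuals", "Df"],
               F = wth[rn(wth) == "group:day", "F value"],
               p = wth[rn(wth) == "group:day", "Pr(>F)"]))
  rownames(out) <- NULL
  # constant data: every sum of squares vanishes and F is 0/0; report the
  # nothing-to-detect convention F = 0, p = 1
  degenerate <- !is.finite(out$F)
  out$F[degenerate] <- 0
  out$p[degenerate] <- 1
  out
}

#' Pearson correlation with significance test
#'
#' @param x,y numeric vectors, `n >= 3`, non-degenerate.
#' @return a `test_outcome` with `r` as effect and the t-transform
#'   two-sided p value.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_outcome(ct$statistic, ct$parameter, ct$p.value, unname(ct$estimate),
               "Pearson correlation")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure over a vector of p values.
#'
#' @param p p values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return list with `reject` (logical mask) and `adjusted` (BH-adjusted
#'   p values).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(reject = adjusted <= q, adjusted = adjusted)
}

#' Edge-wise independent-samples t-tests
#'
#' Compares two groups on every network edge (per-subject mean Fisher-z
#' summaries, one column per edge in the package's upper-triangle edge
#' order). Pooled-variance t statistics are computed vectorized over the
#' `n(n-1)/2` edges; the selection mask keeps edges with `p < alpha`
#' (default 0.01, the drawing threshold of the edge analysis) or, with
#' `adjust = TRUE`, BH-adjusted `p <= alpha`.
#'
#' @param group_a,group_b subject x edge matrices.
#' @param alpha selection threshold (default 0.01).
#' @param adjust apply BH adjustment before selection (default FALSE).
#' @return data.frame with one row per edge: `edge`, `mean_diff`
#'   (A minus B), `t`, `df`, `p`, `selected`.
#' @export
edgewise_ttest <- function(group_a, group_b, alpha = 0.01, adjust = FALSE) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b)) stop("groups must share the edge set")
  n1 <- nrow(group_a); n2 <- nrow(group_b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  m1 <- colMeans(group_a); m2 <- colMeans(group_b)
  v1 <- apply(group_a, 2, stats::var); v2 <- apply(group_b, 2, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf), (m1 - m2) / se)
  p <- 2 * stats::pt(-abs(tt), df)
  selected <- if (adjust) fdr_bh(p, alpha)$reject else p < alpha
  data.frame(edge = seq_along(p), mean_diff = m1 - m2, t = tt, df = df,
             p = p, selected = selected)
}

#' Power of the mixed repeated-measures ANOVA interaction
#'
#' Noncentral-F power of the within-between interaction under the G*Power
#' convention: noncentrality `lambda = f^2 * N * m * eps / (1 - rho)`,
#' numerator df `(g - 1)(m - 1) eps`, denominator df `(N - g)(m - 1) eps`.
#'
#' @param n_total total sample size across groups.
#' @param f Cohen's effect size f.
#' @param alpha significance level.
#' @param groups number of groups.
#' @param measurements number of repeated measurements m.
#' @param rho assumed correlation among repeated measures.
#' @param epsilon nonsphericity correction (1 = sphericity).
#' @return achieved power in `[0, 1]`.
#' @export
rm_anova_power <- function(n_total, f = 0.25, alpha = 0.05, groups = 2,
                           measurements = 3, rho = 0.5, epsilon = 1) {
  lambda <- f^2 * n_total * measurements * epsilon / (1 - rho)
  df1 <- (groups - 1) * (measurements - 1) * epsilon
  df2 <- (n_total - groups) * (measurements - 1) * epsilon
  1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
}

#' A-priori sample size for the mixed repeated-measures ANOVA
#'
#' Smallest total N (stepped in multiples of the group count so groups
#' stay equal) whose within-between interaction power, by direct
#' noncentral-F evaluation ([rm_anova_power()]), reaches the target.
#'
#' @param f Cohen's effect size f (> 0).
#' @param alpha significance level in `(0, 1)`.
#' @param power target power in `(0, 1)`.
#' @param groups number of groups (>= 2).
#' @param measurements repeated measurements (>= 2).
#' @param rho assumed repeated-measures correlation.
#' @param epsilon nonsphericity correction.
#' @return minimum total N, with the achieved power as attribute
#'   `"power"`.
#' @export
sample_size_rm_anova <- function(f = 0.25, alpha = 0.05, power = 0.8, groups = 2,
                                 measurements = 3, rho = 0.5, epsilon = 1) {
  if (f <= 0) stop("effect size f must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (groups < 2 || measurements < 2) stop("need >= 2 groups and >= 2 measurements")
  n <- 2 * groups
  repeat {
    pw <- rm_anova_power(n, f, alpha, groups, measurements, rho, epsilon)
    if (pw >= power) break
    n <- n + groups
    if (n > 1e6) stop("target power unreachable within N <= 1e6")
  }
  structure(as.integer(n), power = pw)
}
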