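# Two-group comparison layer: D'Agostino-Pearson omnibus normality,
# normality-gated choice between the pooled-variance t-test and the
# two-tailed Mann-Whitney U test, and screening-efficiency summaries.
# The statistics are computed from their defining formulas (only the
# chi-square / t / normal tail functions come from base R), so they can
# be cross-checked against independent implementations.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalizing transforms of sample skewness (D'Agostino)
#' and kurtosis (Anscombe-Glynn) into `K2 = Z_skew^2 + Z_kurt^2`, which is
#' chi-square with 2 degrees of freedom under normality. The small-sample
#' transforms are undefined below n = 8.
#'
#' @param x Numeric sample, `n >= 8`.
#' @return A list with `K2`, `p` (upper chi-square tail), `z_skew`,
#'   `z_kurt` and `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L)
    zf_stop("sample_too_small",
            "D'Agostino-Pearson needs n >= 8 (got %d)", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    zf_stop("degenerate_region", "zero variance; normality undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1e-300
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(varb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  denom <- 1 + xs * sqrt(2 / (A - 4))
  z2 <- ((1 - 2 / (9 * A)) -
           sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  list(K2 = K2, p = pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

# Exact null distribution of the Mann-Whitney U statistic for group sizes
# m, n without ties: counts of rank arrangements with each U value, via
# the standard recursion f(u; m, n) = f(u - n; m - 1, n) + f(u; m, n - 1).
mwu_exact_counts <- function(m, n) {
  f <- vector("list", m + 1L)
  for (mm in 0:m) f[[mm + 1L]] <- vector("list", n + 1L)
  f[[1L]][1:(n + 1L)] <- list(1)            # m = 0: only U = 0
  for (mm in 1:m) {
    f[[mm + 1L]][[1L]] <- 1                 # n = 0: only U = 0
    for (nn in 1:n) {
      a <- f[[mm]][[nn + 1L]]               # f(u - nn; mm-1, nn)
      b <- f[[mm + 1L]][[nn]]               # f(u; mm, nn-1)
      len <- mm * nn + 1L
      out <- numeric(len)
      out[seq_len(len - nn)[seq_along(a)] + nn] <- a
      out[seq_along(b)] <- out[seq_along(b)] + b
      f[[mm + 1L]][[nn + 1L]] <- out
    }
  }
  f[[m + 1L]][[n + 1L]]
}

# Mann-Whitney U from formulas. Exact p when n1*n2 <= 400 and no ties;
# normal approximation with tie correction and continuity otherwise.
mwu_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 * n2 <= 400) {
    cnt <- mwu_exact_counts(n1, n2)
    prob <- cnt / sum(cnt)
    umin <- min(U1, U2)
    p <- min(1, 2 * sum(prob[seq_len(umin + 1L)]))
    exact <- TRUE
  } else {
    N <- n1 + n2
    tt <- table(r)
    tiecor <- sum(tt^3 - tt) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecor))
    mu <- n1 * n2 / 2
    z <- if (sigma == 0) 0 else (U1 - mu - sign(U1 - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(U = U1, U_prime = U2, p = p, exact = exact)
}

# Pooled-variance (Student) two-tailed unpaired t-test from formulas.
student_t_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (tstat == 0) 1 else 0
  } else {
    tstat <- (mean(a) - mean(b)) / se
    p <- 2 * pt(-abs(tstat), df)
  }
  list(statistic = tstat, df = df, p = p)
}

#' Compare two groups with a normality-gated test choice
#'
#' Under the default `"auto"` policy, both groups are checked with the
#' D'Agostino-Pearson omnibus test; if both pass at `alpha_normality`
#' (groups too small to test, n < 8, are treated as passing), a
#' two-tailed unpaired pooled-variance Student's t-test is used,
#' otherwise a two-tailed Mann-Whitney U test (exact when
#' `n1 * n2 <= 400` and there are no ties, normal approximation with tie
#' and continuity correction otherwise). Either test can be forced; the
#' non-chosen test is also reported so the full test trail is available.
#'
#' @param a,b Numeric samples (each `n >= 2`).
#' @param policy `"auto"`, `"t"` or `"mwu"`.
#' @param alpha_normality Significance level of the normality gate.
#' @return A `group_comparison`: per-group `n`, `mean`, `sd` (n-1
#'   denominator), `normality_p`, the chosen `test_used`, `statistic`,
#'   `p_two_tailed`, the full `t` and `mannwhitney` results, and a
#'   `degenerate` flag for the zero-variance/equal-means convention
#'   (p = 1).
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 3, 4), policy = "t")$p_two_tailed
#' @export
compare_groups <- function(a, b, policy = c("auto", "t", "mwu"),
                           alpha_normality = 0.05) {
  policy <- match.arg(policy)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    zf_stop("bad_argument", "each group needs n >= 2")
  norm_p <- vapply(list(a, b), function(x)
    if (length(x) >= 8L && var(x) > 0) dagostino_pearson(x)$p else NA_real_,
    numeric(1))
  tt <- student_t_test(a, b)
  mw <- mwu_test(a, b)
  degenerate <- var(a) == 0 && var(b) == 0 && mean(a) == mean(b)
  test_used <- switch(policy,
    t = "t", mwu = "mannwhitney",
    auto = if (all(is.na(norm_p) | norm_p > alpha_normality)) "t"
           else "mannwhitney")
  if (degenerate) {
    statistic <- 0; p <- 1
  } else if (test_used == "t") {
    statistic <- tt$statistic; p <- tt$p
  } else {
    statistic <- mw$U; p <- mw$p
  }
  structure(list(
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sd = c(sd(a), sd(b)),
    normality_p = norm_p,
    test_used = test_used,
    statistic = statistic,
    p_two_tailed = p,
    t = tt, mannwhitney = mw,
    degenerate = degenerate,
    policy = policy),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Two-group comparison\n")
  for (i in 1:2)
    cat(sprintf("  group %d: n = %d, mean +/- s.d. = %.4g +/- %.4g%s\n",
                i, x$n[i], x$mean[i], x$sd[i],
                if (is.na(x$normality_p[i])) " (too small for normality test)"
                else sprintf(" (normality p = %.3f)", x$normality_p[i])))
  lbl <- if (x$test_used == "t")
    sprintf("Student's t = %.4g (df = %d)", x$statistic, x$t$df)
  else sprintf("Mann-Whitney U = %g%s", x$statistic,
               if (x$mannwhitney$exact) " (exact)" else " (normal approx.)")
  cat(sprintf("  %s, two-tailed p = %.4g%s\n", lbl, x$p_two_tailed,
              if (x$degenerate) " [degenerate: zero variance, equal means]"
              else ""))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(n1 = x$n[1], n2 = x$n[2], mean1 = x$mean[1], mean2 = x$mean[2],
             sd1 = x$sd[1], sd2 = x$sd[2],
             normality_p1 = x$normality_p[1], normality_p2 = x$normality_p[2],
             test_used = x$test_used, statistic = x$statistic,
             p_two_tailed = x$p_two_tailed,
             t_p = x$t$p, mwu_p = x$mannwhitney$p)
}

#' Screening-efficiency summary
#'
#' Proportion of positive embryos among those screened, as a percentage
#' rounded half-up to one decimal (so 20 of 28 prints as 71.4).
#'
#' @param positives Number of positives (`0 <= positives <= total`).
#' @param total Number screened (`>= 1`).
#' @return An `efficiency_summary` with `positives`, `total`, `percent`.
#' @examples
#' screening_efficiency(21, 28)$percent   # 75
#' @export
screening_efficiency <- function(positives, total) {
  if (total < 1 || positives < 0)
    zf_stop("bad_argument", "need total >= 1 and positives >= 0")
  if (positives > total)
    zf_stop("bad_argument", "positives (%d) exceed total (%d)",
            positives, total)
  structure(list(positives = as.integer(positives),
                 total = as.integer(total),
                 percent = round_half_up(100 * positives / total, 1L)),
            class = "efficiency_summary")
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat(sprintf("%d/%d (%.1f%%)\n", x$positives, x$total, x$percent))
  invisible(x)
}

#' @export
as.data.frame.efficiency_summary <- function(x, ...) {
  data.frame(positives = x$positives, total = x$total, percent = x$percent)
}
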