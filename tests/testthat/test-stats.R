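# Independent oracle values frozen from a reference implementation
# (scipy.stats 1.17: normaltest / skewtest / kurtosistest / ttest_ind on
# the same inputs) and brute-force enumeration computed in-test.

test_that("D'Agostino-Pearson matches the reference implementation", {
  x <- (1:20)^1.5
  dp <- dagostino_pearson(x)
  expect_equal(dp$K2, 2.879711281344, tolerance = 1e-10)
  expect_equal(dp$p, 0.236961963883, tolerance = 1e-9)
  expect_equal(dp$z_skew, 0.757580386130, tolerance = 1e-10)
  expect_equal(dp$z_kurt, -1.518480569483, tolerance = 1e-10)
  expect_error(dagostino_pearson(1:5), class = "zfcardio_sample_too_small")
})

test_that("normality test calibrates on normal and rejects skewed data", {
  set.seed(101)
  pnorm_ok <- vapply(1:100, function(i)
    dagostino_pearson(rnorm(2000))$p > 0.05, logical(1))
  expect_gte(mean(pnorm_ok), 0.90)
  pexp <- vapply(1:5, function(i) dagostino_pearson(rexp(2000))$p, numeric(1))
  expect_true(all(pexp < 0.001))
})

test_that("pooled-variance t-test matches the closed form", {
  # hand evaluation: means 2 and 3, pooled variance 1, se = sqrt(2/3)
  cmp <- compare_groups(c(1, 2, 3), c(2, 3, 4), policy = "t")
  expect_equal(cmp$statistic, -1 / sqrt(2 / 3))
  expect_equal(cmp$p_two_tailed, 2 * pt(-sqrt(3 / 2), df = 4))
  expect_equal(cmp$p_two_tailed, 0.287864134727, tolerance = 1e-9)
  # independent route: base R
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(cmp$statistic, unname(ref$statistic))
  expect_equal(cmp$p_two_tailed, ref$p.value)

  # identical samples: degenerate convention
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_true(same$degenerate)
})

test_that("exact Mann-Whitney matches brute-force enumeration", {
  # enumeration oracle: all assignments of ranks to group 1
  enum_p <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    r <- rank(c(a, b))
    U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- combn(n1 + n2, n1)
    us <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    min(1, 2 * mean(us <= min(U1, n1 * n2 - U1)))
  }
  set.seed(7)
  for (rep in 1:10) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    a <- round(rnorm(n1), 3); b <- round(rnorm(n2, 0.5), 3)
    if (any(duplicated(c(a, b)))) next
    got <- zfcardio:::mwu_test(a, b)
    expect_true(got$exact)
    expect_equal(got$p, enum_p(a, b))
    expect_equal(got$p, wilcox.test(a, b, exact = TRUE)$p.value)
    # U + U' = n1 n2
    expect_equal(got$U + got$U_prime, n1 * n2)
  }
  # exact distribution sums to choose(m + n, m)
  expect_equal(sum(zfcardio:::mwu_exact_counts(5, 6)), choose(11, 5))
  expect_equal(zfcardio:::mwu_exact_counts(3, 3) / choose(6, 3),
               dwilcox(0:9, 3, 3))
})

test_that("tied or large samples use the corrected normal approximation", {
  set.seed(21)
  a <- sample(1:10, 25, TRUE); b <- sample(3:12, 25, TRUE)  # ties, n1n2 > 400
  got <- zfcardio:::mwu_test(a, b)
  expect_false(got$exact)
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("group comparison is symmetric and policy-gated", {
  set.seed(33)
  a <- rnorm(15); b <- rnorm(15, 1)
  c1 <- compare_groups(a, b)
  c2 <- compare_groups(b, a)
  expect_equal(c1$t$statistic, -c2$t$statistic)
  expect_equal(c1$p_two_tailed, c2$p_two_tailed)
  expect_equal(c1$test_used, "t")           # both normal
  # a clearly skewed group trips the gate to Mann-Whitney
  sk <- compare_groups(rexp(50)^3, rnorm(50, 2))
  expect_equal(sk$test_used, "mannwhitney")
  # groups too small to test normality fall back to t
  small <- compare_groups(c(1, 2, 3.5), c(2, 3, 4.5))
  expect_true(all(is.na(small$normality_p)))
  expect_equal(small$test_used, "t")
})

test_that("screening efficiency rounds half-up to one decimal", {
  e1 <- screening_efficiency(21, 28)
  expect_equal(e1$percent, 75.0)
  expect_equal(screening_efficiency(20, 28)$percent, 71.4)
  expect_equal(screening_efficiency(0, 10)$percent, 0.0)
  expect_equal(screening_efficiency(1, 16)$percent, 6.3)   # 6.25 rounds up
  expect_error(screening_efficiency(5, 4), "exceed")
  expect_output(print(e1), "21/28 \\(75.0%\\)")
})
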