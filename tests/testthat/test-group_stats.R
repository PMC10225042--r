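# Descriptive statistics and nonparametric tests.

test_that("descriptives report order statistics and a seeded bootstrap CI", {
  d <- descriptives(c(1, 2, 3, 4, 5), seed = 1)
  expect_equal(d$median, 3)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  expect_equal(d$q1, 2)
  expect_equal(d$q3, 4)
  expect_true(d$ci_low <= d$median && d$median <= d$ci_high)

  # constant data: degenerate CI
  d <- descriptives(rep(7, 20), seed = 1)
  expect_equal(c(d$ci_low, d$ci_high), c(7, 7))

  # same seed -> identical CI; CI brackets the sample median
  set.seed(30)
  x <- stats::rnorm(200)
  d1 <- descriptives(x, seed = 5)
  d2 <- descriptives(x, seed = 5)
  expect_identical(d1, d2)
  expect_true(d1$ci_low <= stats::median(x) && stats::median(x) <= d1$ci_high)
  expect_error(descriptives(numeric(0)), "empty")
})

test_that("signed-rank exact p equals exhaustive enumeration", {
  # shifted pairs, n = 12: most extreme ranking, p = 2 * 2^-12
  y <- stats::rnorm(12)
  res <- wilcoxon_signed_rank(y + 3, y)
  expect_equal(res$p_value, 2 * 2^-12, tolerance = 1e-12)
  expect_equal(res$statistic, 12 * 13 / 2)

  set.seed(31)
  for (i in 1:10) {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 wilcoxon_enumeration_p(x, y), tolerance = 1e-12)
  }
  # with ties in |d| (enumeration handles midranks identically)
  x <- c(1, 2, 3, 4, 6, 8)
  y <- c(2, 1, 1, 6, 4, 4)   # |d| = 1,1,2,2,2,4
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_enumeration_p(x, y), tolerance = 1e-12)

  # agreement with stats::wilcox.test on tie-free exact cases
  set.seed(32)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "equal length")
})

test_that("Mann-Whitney exact p equals exhaustive enumeration", {
  # identical groups: U = n1 n2 / 2
  res <- mann_whitney_u(1:6, 1:6)
  expect_equal(res$statistic, 18)
  # complete separation: U = n1 n2, minimal two-sided p = 2 / C(12, 6)
  res <- mann_whitney_u(7:12, 1:6)
  expect_equal(res$statistic, 36)
  expect_equal(res$p_value, 2 / choose(12, 6), tolerance = 1e-12)

  set.seed(33)
  for (i in 1:10) {
    x <- stats::rnorm(6)
    y <- stats::rnorm(6)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 mann_whitney_enumeration_p(x, y), tolerance = 1e-12)
  }
  # agreement with stats::wilcox.test exact path
  x <- stats::rnorm(8); y <- stats::rnorm(9)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate p agree near the enumeration boundary", {
  set.seed(34)
  for (i in 1:20) {
    x <- stats::rnorm(25)
    y <- stats::rnorm(25)
    p_exact <- wilcoxon_signed_rank(x, y, exact_max = 25)$p_value
    p_approx <- wilcoxon_signed_rank(x, y, exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
    x2 <- stats::rnorm(10); y2 <- stats::rnorm(10)
    p_exact <- mann_whitney_u(x2, y2, exact_max = 20)$p_value
    p_approx <- mann_whitney_u(x2, y2, exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(35)
  x <- stats::rlnorm(15)
  y <- stats::rlnorm(18)
  f <- function(v) v^3 + 2 * log(v)   # strictly increasing on (0, Inf)
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(f(x), f(y))$p_value, tolerance = 1e-12)
  # signed-rank: invariance needs a transform preserving difference ranks,
  # e.g. scaling
  xp <- stats::rnorm(12); yp <- stats::rnorm(12)
  expect_equal(wilcoxon_signed_rank(xp, yp)$p_value,
               wilcoxon_signed_rank(3 * xp, 3 * yp)$p_value,
               tolerance = 1e-12)
  # W+ and its complement sum to n(n+1)/2 after zero-dropping
  res <- wilcoxon_signed_rank(xp, yp)
  res_flip <- wilcoxon_signed_rank(yp, xp)
  n <- res$n1
  expect_equal(res$statistic + res_flip$statistic, n * (n + 1) / 2)
})

test_that("compare_groups routes pairing and handles degenerate features", {
  set.seed(36)
  n_sub <- 6; tok <- 3
  cohort <- cohort_table(expand.grid(
    token = 1:tok, subject = 1:n_sub,
    class = c("voluntary_cough", "throat_clearing"),
    stringsAsFactors = FALSE) |>
      transform(file_id = sprintf("f%d", seq_len(tok * n_sub * 2)),
                microphone = "free_standing", induction = "none"))
  features <- data.frame(file_id = cohort$file_id,
                         good = stats::rnorm(nrow(cohort)) +
                           2 * (cohort$class == "voluntary_cough"),
                         flat = 1)
  ctr <- list(variable = "class",
              levels = c("voluntary_cough", "throat_clearing"))
  res <- compare_groups(features, cohort, ctr)
  expect_setequal(res$feature, c("good", "flat"))
  expect_true(all(res$test == "wilcoxon"))          # same subjects -> paired
  expect_equal(res$p_value[res$feature == "flat"], 1)  # degenerate -> p = 1
  expect_lt(res$p_value[res$feature == "good"], 0.05)

  # forcing unpaired uses Mann-Whitney
  res2 <- compare_groups(features, cohort, ctr, paired = FALSE)
  expect_true(all(res2$test == "mann_whitney"))

  # unmatched pairing keys are reported
  cohort2 <- cohort[-1, ]
  feats2 <- features[-1, ]
  expect_error(compare_groups(feats2, cohort2, ctr, paired = TRUE),
               "unpaired")
  expect_error(compare_groups(features, cohort,
                              list(variable = "class",
                                   levels = c("voluntary_cough", "zzz"))),
               "absent")
})
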