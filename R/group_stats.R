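# Descriptive statistics and nonparametric group comparisons.
#
# Feature distributions are summarized by medians, quartiles, minima,
# maxima, and bootstrapped 95% confidence intervals for the medians
# (percentile method). Contrasts are tested with the Wilcoxon signed-rank
# test when tokens are paired within subject and the Mann-Whitney U test
# for independent groups; p-values are exact (full enumeration of the null
# distribution, ties midranked) for small samples and tie- and
# continuity-corrected normal approximations otherwise. No multiplicity
# correction is applied: raw per-feature p-values are reported and flagged
# at alpha = 0.05.

#' Descriptive statistics with a bootstrap CI for the median
#'
#' Quartiles use linear interpolation of order statistics
#' (`stats::quantile` type 7). The 95% CI for the median is the 2.5/97.5
#' percentile of `B` bootstrap resamples of the data.
#'
#' @param values numeric vector, n >= 1.
#' @param B number of bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap (local to this call).
#' @return list with `q1`, `median`, `q3`, `min`, `max`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
descriptives <- function(values, B = 2000L, conf = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  meds <- local_seed(seed, {
    vapply(seq_len(B),
           function(i) stats::median(sample(values, n, replace = TRUE)),
           numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(meds, c(a, 1 - a), type = 7))
  list(q1 = q[1], median = q[2], q3 = q[3],
       min = min(values), max = max(values),
       ci_low = ci[1], ci_high = ci[2], n = n)
}

# Evaluate `expr` under a temporary RNG state when seed is non-NULL.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

comparison_result <- function(feature, test, statistic, p, n1, n2,
                              alpha = 0.05) {
  data.frame(feature = feature, test = test, statistic = statistic,
             p_value = p, n1 = n1, n2 = n2,
             significant = is.finite(p) & p < alpha,
             stringsAsFactors = FALSE)
}

# Exact null distribution of the signed-rank statistic W+ for midranked
# absolute differences: generating function over all 2^n sign assignments,
# computed by polynomial convolution on doubled ranks (midranks are
# multiples of 1/2, so doubled ranks are integers).
signed_rank_exact_p <- function(w_plus, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)     # counts[s + 1] = #assignments with 2*W+ = s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  s <- as.integer(round(2 * w_plus))
  lower <- sum(probs[seq_len(s + 1L)])
  upper <- sum(probs[(s + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Zero differences are dropped; tied absolute differences receive
#' midranks. For n <= `exact_max` retained pairs the p-value is exact over
#' all sign assignments (valid with ties); otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @param feature label carried into the result.
#' @param alpha significance threshold for the flag.
#' @return One-row data.frame: feature, test, statistic (W+), p_value,
#'   n1, n2 (= retained pairs), significant.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L,
                                 feature = NA_character_, alpha = 0.05) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate pairing: all differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(w_plus, r)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w_plus - mu) * 0.5
    z <- (w_plus - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  comparison_result(feature, "wilcoxon", w_plus, p, n, n, alpha)
}

# Exact null distribution of the rank sum of group 1 for untied pooled
# ranks 1..N: dynamic program counting subsets of size n1 by rank sum.
rank_sum_exact_p <- function(u, n1, n2) {
  N <- n1 + n2
  smax <- sum((N - n1 + 1L):N)
  # ways[k + 1, s + 1] = number of size-k subsets of {1..r} with sum s
  ways <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, n1)
    for (k in kmax:1L) {
      cols <- (r + 1L):(smax + 1L)
      ways[k + 1L, cols] <- ways[k + 1L, cols] + ways[k, cols - r]
    }
  }
  counts <- ways[n1 + 1L, ]
  probs <- counts / choose(N, n1)
  # U = rank sum - n1(n1+1)/2; shift index accordingly
  offset <- n1 * (n1 + 1L) / 2
  s <- as.integer(round(u + offset))
  lower <- sum(probs[seq_len(s + 1L)])
  upper <- sum(probs[(s + 1L):(smax + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Mann-Whitney U test (independent groups, two-sided)
#'
#' The statistic is `U = sum over pairs of [x_i > y_j] + 1/2 [x_i = y_j]`.
#' For `n1 + n2 <= exact_max` with no ties across the pooled sample the
#' p-value is exact by enumeration of all group labelings; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max largest pooled size for which the exact distribution is
#'   used.
#' @inheritParams wilcoxon_signed_rank
#' @return One-row data.frame as in [wilcoxon_signed_rank()], with
#'   `test = "mann_whitney"` and statistic U.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20L,
                           feature = NA_character_, alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (n1 + n2 <= exact_max && !has_ties) {
    p <- rank_sum_exact_p(u, n1, n2)
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(comparison_result(feature, "mann_whitney", u, 1,
                                              n1, n2, alpha))
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  comparison_result(feature, "mann_whitney", u, p, n1, n2, alpha)
}

#' Compare feature distributions between two cohort groups
#'
#' Joins a feature table (one row per segment, `file_id` column) with a
#' cohort table, splits on a contrast, and tests every numeric feature.
#' The test is paired (Wilcoxon signed-rank, pairing tokens by
#' `(subject, token)`) when both contrast levels are produced by the same
#' subjects, and independent (Mann-Whitney U) otherwise; `paired` overrides
#' the heuristic. Degenerate features (all paired differences zero, or both
#' groups constant and equal) are reported with `p_value = 1` rather than
#' an error.
#'
#' @param features data.frame with `file_id` plus numeric feature columns.
#' @param cohort a [cohort_table()].
#' @param contrast list with `variable` (a cohort column, e.g. `"class"` or
#'   `"induction"`) and `levels` (length-2 character: level1 vs level2).
#' @param paired logical or NULL (auto).
#' @param alpha significance threshold.
#' @return data.frame of one comparison per feature.
#' @export
compare_groups <- function(features, cohort, contrast, paired = NULL,
                           alpha = 0.05) {
  stopifnot(is.list(contrast), length(contrast$levels) == 2L)
  v <- contrast$variable
  if (!v %in% names(cohort)) stop("contrast variable not in cohort: ", v)
  lv <- contrast$levels
  present <- lv %in% cohort[[v]]
  if (!all(present))
    stop("contrast level(s) absent from cohort: ",
         paste(lv[!present], collapse = ", "))
  df <- merge(cohort, features, by = "file_id")
  g1 <- df[df[[v]] == lv[1L], , drop = FALSE]
  g2 <- df[df[[v]] == lv[2L], , drop = FALSE]
  k1 <- paste(g1$subject, g1$token, sep = "\r")
  k2 <- paste(g2$subject, g2$token, sep = "\r")
  if (is.null(paired)) paired <- setequal(k1, k2)

  feat_cols <- setdiff(names(features), "file_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]

  if (paired) {
    orphans <- c(setdiff(k1, k2), setdiff(k2, k1))
    if (length(orphans))
      stop("unpaired (subject, token) keys: ",
           paste(gsub("\r", "/", orphans), collapse = ", "))
    g2 <- g2[match(k1, k2), , drop = FALSE]
  }

  res <- lapply(feat_cols, function(fc) {
    x <- g1[[fc]]
    y <- g2[[fc]]
    out <- try(if (paired) wilcoxon_signed_rank(x, y, feature = fc,
                                                alpha = alpha)
               else mann_whitney_u(x, y, feature = fc, alpha = alpha),
               silent = TRUE)
    if (inherits(out, "try-error"))
      out <- comparison_result(fc, if (paired) "wilcoxon" else "mann_whitney",
                               NA_real_, 1, length(x), length(y), alpha)
    out
  })
  do.call(rbind, res)
}

#' Descriptive table for every feature in one group
#'
#' @param features data.frame with `file_id` plus numeric feature columns.
#' @param B,conf,seed passed to [descriptives()].
#' @return data.frame: one row per feature with q1/median/q3/min/max and
#'   the bootstrap CI of the median.
#' @export
describe_features <- function(features, B = 2000L, conf = 0.95, seed = NULL) {
  feat_cols <- setdiff(names(features), "file_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  rows <- lapply(seq_along(feat_cols), function(i) {
    d <- descriptives(features[[feat_cols[i]]], B = B, conf = conf,
                      seed = if (is.null(seed)) NULL else seed + i)
    data.frame(feature = feat_cols[i], q1 = d$q1, median = d$median,
               q3 = d$q3, min = d$min, max = d$max,
               ci_low = d$ci_low, ci_high = d$ci_high, n = d$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
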