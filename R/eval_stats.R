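# Evaluation-statistics toolkit: a-priori power analysis for the
# two-independent-sample t test via the noncentral t distribution,
# Mann-Whitney U with mean ranks and tie correction, and Likert-scale
# interpretation bins.

#' Power-analysis specification
#'
#' @param effect_size_d Cohen's d (standardized mean difference).
#' @param alpha Type-I error rate in (0, 1).
#' @param target_power Required power in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @param allocation_ratio n2/n1 (positive; 1 = equal groups).
#' @return A `power_spec` list.
#' @export
power_spec <- function(effect_size_d, alpha = 0.05, target_power = 0.80,
                       tails = c("one", "two"), allocation_ratio = 1) {
  tails <- match.arg(tails)
  stopifnot(alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            allocation_ratio > 0)
  structure(list(effect_size_d = effect_size_d, alpha = alpha,
                 target_power = target_power, tails = tails,
                 allocation_ratio = allocation_ratio),
            class = "power_spec")
}

#' Noncentrality parameter of the two-sample t test
#'
#' `delta = d * sqrt(n1 * n2 / (n1 + n2))`.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes (>= 2).
#' @return The noncentrality parameter delta.
#' @examples
#' noncentrality(0.8, 15, 15)  # 2.19 to 2 decimals
#' @export
noncentrality <- function(d, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  d * sqrt(n1 * n2 / (n1 + n2))
}

#' Critical t value
#'
#' Upper quantile of the central t distribution at `alpha` (one-tailed) or
#' `alpha/2` (two-tailed).
#'
#' @param alpha Significance level.
#' @param df Degrees of freedom (>= 1).
#' @param tails `"one"` or `"two"`.
#' @return The rejection threshold on the t scale.
#' @examples
#' critical_t(0.10, 28, "one")  # 1.31 to 2 decimals
#' @export
critical_t <- function(alpha, df, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(df >= 1)
  qt(if (tails == "one") alpha else alpha / 2, df, lower.tail = FALSE)
}

#' Achieved power of the two-sample t test
#'
#' Power under the noncentral t distribution with `df = n1 + n2 - 2` and
#' noncentrality [noncentrality()]: the probability that the t statistic
#' exceeds [critical_t()]; the two-tailed case adds the lower-tail
#' rejection mass.
#'
#' @param spec A [power_spec()].
#' @param n1,n2 Group sizes.
#' @return Power in (0, 1).
#' @export
achieved_power <- function(spec, n1, n2) {
  stopifnot(inherits(spec, "power_spec"))
  df <- n1 + n2 - 2
  delta <- noncentrality(spec$effect_size_d, n1, n2)
  tc <- critical_t(spec$alpha, df, spec$tails)
  upper <- pt(tc, df, ncp = delta, lower.tail = FALSE)
  if (spec$tails == "one") upper
  else upper + pt(-tc, df, ncp = delta)
}

#' A-priori sample size for the two-sample t test
#'
#' Finds the smallest `n1` (with `n2 = ceiling(allocation_ratio * n1)`)
#' whose [achieved_power()] reaches `spec$target_power`, and reports the
#' full set of derived quantities: group sizes, degrees of freedom,
#' noncentrality parameter, critical t, and the achieved (actual) power.
#'
#' @param spec A [power_spec()] with non-zero effect size.
#' @param n_max Search ceiling for n1 (safety stop).
#' @return A `power_result` list: `n1`, `n2`, `df`, `noncentrality_delta`,
#'   `critical_t`, `achieved_power`, plus the input `spec`.
#' @examples
#' required_sample_size(power_spec(0.8, alpha = 0.10, target_power = 0.80,
#'                                 tails = "one"))
#' @export
required_sample_size <- function(spec, n_max = 1e5) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$effect_size_d == 0)
    stop("target power is unreachable with a zero effect size")
  for (n1 in 2:n_max) {
    n2 <- as.integer(ceiling(spec$allocation_ratio * n1))
    if (n2 < 2) next
    pw <- achieved_power(spec, n1, n2)
    if (pw >= spec$target_power) {
      return(structure(list(
        n1 = as.integer(n1), n2 = n2, df = as.integer(n1 + n2 - 2),
        noncentrality_delta = noncentrality(spec$effect_size_d, n1, n2),
        critical_t = critical_t(spec$alpha, n1 + n2 - 2, spec$tails),
        achieved_power = pw, spec = spec), class = "power_result"))
    }
  }
  stop("no sample size up to n_max reaches the target power")
}

#' @exportS3Method base::print
print.power_result <- function(x, ...) {
  cat("A-priori two-sample t-test sample size\n")
  cat(sprintf("  d = %.2f, alpha = %.2f, tails = %s, target power = %.2f\n",
              x$spec$effect_size_d, x$spec$alpha, x$spec$tails,
              x$spec$target_power))
  cat(sprintf("  n1 = %d, n2 = %d, df = %d\n", x$n1, x$n2, x$df))
  cat(sprintf("  noncentrality delta = %.2f, critical t = %.2f, actual power = %.2f\n",
              x$noncentrality_delta, x$critical_t, x$achieved_power))
  invisible(x)
}

# exact null distribution of the group-1 rank sum by enumeration of all
# choose(n1+n2, n1) group assignments over the pooled midranks
exact_mwu_p <- function(ranks, n1, u_obs) {
  n <- length(ranks)
  combos <- utils::combn(n, n1)
  r1 <- colSums(matrix(ranks[combos], nrow = n1))
  u_all <- r1 - n1 * (n1 + 1) / 2
  n2 <- n - n1
  mu <- n1 * n2 / 2
  # two-sided: probability of a U at least as far from the mean
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test with mean ranks
#'
#' Rank-sum test for two independent samples, reported the way survey
#' studies tabulate it: the U statistic, per-group mean ranks over the
#' pooled midranks, the tie-corrected z statistic, and the p value. Small
#' problems (`n1 * n2 <= 64`) use the exact permutation null distribution
#' of U (midranks respected); larger ones use the normal approximation
#' with tie-corrected variance and no continuity correction.
#'
#' @param group1,group2 Non-empty numeric vectors.
#' @param tails `"two"` (default) or `"one"` (direction: group1 tends
#'   larger).
#' @return A `rank_test_result` list: `u_statistic` (group 1's U),
#'   `mean_rank_1`, `mean_rank_2`, `z`, `p_value`, `method`
#'   (`"exact"`/`"normal"`), `tie_correction_applied`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(group1, group2, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(group1, group2)
  r <- rank(pooled)  # midranks
  R1 <- sum(r[seq_len(n1)])
  u <- R1 - n1 * (n1 + 1) / 2
  mean_rank_1 <- R1 / n1
  mean_rank_2 <- sum(r[n1 + seq_len(n2)]) / n2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  N <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  degenerate <- length(ties) == 1  # every pooled value identical
  z <- if (sigma2 > 0) (u - n1 * n2 / 2) / sqrt(sigma2) else 0
  if (degenerate) {
    p <- 1
    method <- "degenerate"
    warning("all values identical across both groups; p = 1")
  } else if (n1 * n2 <= 64) {
    method <- "exact"
    p <- exact_mwu_p(r, n1, u)
    if (tails == "one") {
      combos <- utils::combn(N, n1)
      u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
      p <- mean(u_all >= u - 1e-9)
    }
  } else {
    method <- "normal"
    p <- if (tails == "two") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
  }
  structure(list(u_statistic = u, mean_rank_1 = mean_rank_1,
                 mean_rank_2 = mean_rank_2, z = z, p_value = p,
                 method = method, tails = tails,
                 tie_correction_applied = has_ties && method == "normal",
                 n1 = n1, n2 = n2),
            class = "rank_test_result")
}

#' @exportS3Method base::print
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s-tailed)\n", x$method, x$tails))
  cat(sprintf("  n1 = %d (mean rank %.2f), n2 = %d (mean rank %.2f)\n",
              x$n1, x$mean_rank_1, x$n2, x$mean_rank_2))
  cat(sprintf("  U = %g, z = %.3f, p = %.4g\n", x$u_statistic, x$z, x$p_value))
  invisible(x)
}

likert_bins <- tibble::tibble(
  lower = c(1.00, 1.81, 2.61, 3.41, 4.21),
  upper = c(1.80, 2.60, 3.40, 4.20, 5.00),
  label = c("Very Poor", "Poor", "Moderate", "Good", "Very Good"))

# deterministic half-up rounding at 2 decimals (base round() is half-even);
# the tiny epsilon absorbs binary representation error, e.g. 4.205
round2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

#' Interpret a mean Likert score
#'
#' Maps a mean 1-5 Likert score, rounded half-up to 2 decimals, onto the
#' five interpretation bins: 1.00-1.80 Very Poor, 1.81-2.60 Poor,
#' 2.61-3.40 Moderate, 3.41-4.20 Good, 4.21-5.00 Very Good. The bins
#' partition the 2-decimal grid exactly.
#'
#' @param mean_score Numeric vector in [1, 5].
#' @return Character vector of interpretation labels.
#' @examples
#' interpret_likert(c(4.05, 4.28))
#' @export
interpret_likert <- function(mean_score) {
  if (any(mean_score < 1 - 1e-9 | mean_score > 5 + 1e-9))
    stop("mean Likert scores must lie in [1, 5]")
  x <- round2(mean_score)
  vapply(x, function(v) {
    likert_bins$label[which(v <= likert_bins$upper + 1e-9)[1]]
  }, character(1))
}
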