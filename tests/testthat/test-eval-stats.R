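test_that("noncentrality follows the closed form", {
  expect_equal(round(noncentrality(0.8, 15, 15), 2), 2.19)
  expect_equal(noncentrality(0, 10, 12), 0)
  expect_equal(noncentrality(1.0, 8, 8), 2.0)
  expect_equal(noncentrality(0.5, 10, 40), 0.5 * sqrt(400 / 50))
})

test_that("critical t is the upper central-t quantile for the tail convention", {
  expect_equal(round(critical_t(0.10, 28, "one"), 2), 1.31)
  expect_equal(critical_t(0.5, 17, "one"), 0)
  expect_equal(critical_t(0.05, 1e6, "one"), 1.645, tolerance = 1e-3)
  expect_gt(critical_t(0.05, 28, "two"), critical_t(0.05, 28, "one"))
})

test_that("achieved power matches the noncentral-t form and its limits", {
  spec <- power_spec(0.8, alpha = 0.10, target_power = 0.80, tails = "one")
  expect_equal(round(achieved_power(spec, 15, 15), 2), 0.81)
  # zero effect: power equals the nominal level (both tails)
  null1 <- power_spec(1e-12, alpha = 0.07, tails = "one")
  expect_equal(achieved_power(null1, 20, 20), 0.07, tolerance = 1e-6)
  null2 <- power_spec(1e-12, alpha = 0.07, tails = "two")
  expect_equal(achieved_power(null2, 20, 20), 0.07, tolerance = 1e-6)
  # independent cross-check: base R's power.t.test on a two-tailed design
  spec2 <- power_spec(0.5, alpha = 0.05, tails = "two")
  expect_equal(achieved_power(spec2, 64, 64),
               power.t.test(n = 64, delta = 0.5, sd = 1,
                            sig.level = 0.05)$power,
               tolerance = 1e-4)
  # Monte-Carlo oracle on the same design
  mc <- withr::with_seed(77, mean(replicate(4000, {
    t.test(rnorm(64, 0.5), rnorm(64), var.equal = TRUE)$p.value < 0.05
  })))
  expect_equal(achieved_power(spec2, 64, 64), mc, tolerance = 0.025)
})

test_that("power is monotone in effect size and sample size", {
  for (tails in c("one", "two")) {
    d <- seq(0.2, 1.2, by = 0.2)
    pw_d <- vapply(d, function(x)
      achieved_power(power_spec(x, alpha = 0.05, tails = tails), 20, 20),
      numeric(1))
    expect_true(all(diff(pw_d) > 0))
    ns <- seq(10, 60, by = 10)
    pw_n <- vapply(ns, function(n)
      achieved_power(power_spec(0.5, alpha = 0.05, tails = tails), n, n),
      numeric(1))
    expect_true(all(diff(pw_n) > 0))
  }
})

test_that("required sample size is minimal across a grid of specifications", {
  grid <- expand.grid(d = c(0.5, 0.8), alpha = c(0.05, 0.10),
                      power = c(0.80, 0.90), tails = c("one", "two"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    spec <- power_spec(grid$d[i], alpha = grid$alpha[i],
                       target_power = grid$power[i], tails = grid$tails[i])
    res <- required_sample_size(spec)
    expect_gte(res$achieved_power, spec$target_power)
    expect_equal(res$df, res$n1 + res$n2 - 2)
    if (res$n1 > 2)
      expect_lt(achieved_power(spec, res$n1 - 1, res$n1 - 1), spec$target_power)
  }
  # two-tailed medium-effect textbook case: 64 per group
  res64 <- required_sample_size(power_spec(0.5, alpha = 0.05,
                                           target_power = 0.80, tails = "two"))
  expect_equal(res64$n1, 64L)
  expect_error(required_sample_size(power_spec(0, alpha = 0.05)),
               "zero effect size")
})

test_that("unequal allocation ratios size the second group by the ratio", {
  spec <- power_spec(0.8, alpha = 0.05, target_power = 0.80, tails = "two",
                     allocation_ratio = 2)
  res <- required_sample_size(spec)
  expect_equal(res$n2, as.integer(ceiling(2 * res$n1)))
  expect_gte(res$achieved_power, 0.80)
})

test_that("Mann-Whitney U and mean ranks match the pairwise-count oracle", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$mean_rank_1, 1.5)
  expect_equal(r$mean_rank_2, 3.5)
  same <- mann_whitney_u(c(2, 4, 6), c(6, 2, 4))
  expect_equal(same$mean_rank_1, same$mean_rank_2)
  withr::with_seed(11, {
    for (rep in 1:15) {
      g1 <- sample(1:8, sample(3:20, 1), replace = TRUE)
      g2 <- sample(1:8, sample(3:20, 1), replace = TRUE)
      res <- mann_whitney_u(g1, g2)
      expect_equal(res$u_statistic, oracle_u_pairwise(g1, g2))
      expect_true(res$u_statistic >= 0 && res$u_statistic <= length(g1) * length(g2))
    }
  })
})

test_that("exact p-values agree with exhaustive permutation for all sizes up to 6", {
  withr::with_seed(19, {
    for (n1 in 1:6) for (n2 in 1:6) {
      g1 <- sample(1:5, n1, replace = TRUE)
      g2 <- sample(1:5, n2, replace = TRUE)
      res <- mann_whitney_u(g1, g2)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, oracle_mwu_exact(g1, g2),
                   info = paste(n1, n2))
    }
  })
  # untied case cross-checked against the standard exact rank test
  g1 <- c(1, 5, 3, 7); g2 <- c(2, 8, 9, 10)
  expect_equal(mann_whitney_u(g1, g2)$p_value,
               wilcox.test(g1, g2, exact = TRUE)$p.value)
})

test_that("large tied samples use the tie-corrected normal approximation", {
  l <- generate_likert_responses(30, shift = 0.8, seed = 4)
  res <- mann_whitney_u(l$group1, l$group2)
  expect_equal(res$method, "normal")
  expect_true(res$tie_correction_applied)
  ref <- wilcox.test(l$group1, l$group2, correct = FALSE, exact = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_gt(res$mean_rank_1, res$mean_rank_2)  # group 2 shifted down
  # degenerate input: identical values everywhere
  expect_warning(flat <- mann_whitney_u(rep(3, 10), rep(3, 12)), "identical")
  expect_equal(flat$p_value, 1)
})

test_that("Likert bins reproduce the published interpretations and partition [1,5]", {
  expect_equal(interpret_likert(4.05), "Good")
  expect_equal(interpret_likert(4.28), "Very Good")
  expect_equal(interpret_likert(4.25), "Very Good")
  expect_equal(interpret_likert(4.205), "Very Good")  # half-up rounding to 4.21
  expect_equal(interpret_likert(c(1.0, 1.80, 1.81, 2.60, 2.61, 3.40, 3.41,
                                  4.20, 4.21, 5.00)),
               c("Very Poor", "Very Poor", "Poor", "Poor", "Moderate",
                 "Moderate", "Good", "Good", "Very Good", "Very Good"))
  grid <- seq(1, 5, by = 0.01)
  labels <- interpret_likert(grid)
  expect_true(all(labels %in% c("Very Poor", "Poor", "Moderate", "Good",
                                "Very Good")))
  expect_equal(length(labels), length(grid))
  # monotone non-decreasing across the grid
  ord <- match(labels, c("Very Poor", "Poor", "Moderate", "Good", "Very Good"))
  expect_true(all(diff(ord) >= 0))
  expect_error(interpret_likert(5.3), "1, 5")
})
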