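test_that("rank-sum: identical groups give p = 1, separated groups the exact minimum", {
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # complete separation at 13 vs 9: p = 2 / choose(22, 13)
  rs <- rank_sum(14:22 + 0.5, 1:13)
  expect_true(rs$exact)
  expect_equal(rs$p_value, 2 / choose(22, 13), tolerance = 1e-12)
  expect_error(rank_sum(1, c(1, 2)), "at least 2")
})

test_that("rank-sum agrees with a permutation oracle on small samples", {
  set.seed(61)
  for (rep in 1:3) {
    a <- rnorm(6)
    b <- rnorm(5, mean = 0.8)
    p_exact <- rank_sum(a, b)$p_value
    # permutation oracle: exhaustive reshuffles of the group labels
    pooled <- c(a, b)
    combs <- utils::combn(11, 6)
    w_obs <- sum(rank(pooled)[1:6]) - 6 * 7 / 2
    w_all <- apply(combs, 2, function(ii) sum(rank(pooled)[ii]) - 6 * 7 / 2)
    mu <- 6 * 5 / 2
    p_perm <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    expect_equal(p_exact, p_perm, tolerance = 0.005)
  }
})

test_that("Friedman consistency gate behaves on identical, trending, and toy data", {
  d_same <- tidyr::expand_grid(subject = letters[1:5], segment = 1:4)
  d_same$value <- rep(1:5, each = 4)   # identical columns per subject
  expect_equal(friedman_repeats(d_same)$p_value, 1)
  # strong monotone segment trend
  d_trend <- d_same
  d_trend$value <- d_trend$segment + rep(rnorm(5, sd = 0.01), each = 4)
  expect_lt(friedman_repeats(d_trend)$p_value, 0.05)
  # 3x3 toy against the hand-computed chi-square: ranks fixed by design
  d_toy <- tidyr::expand_grid(subject = c("s1", "s2", "s3"), segment = 1:3)
  d_toy$value <- c(1, 2, 3, 1, 2, 3, 2, 1, 3)
  # rank sums: R1 = 4, R2 = 5, R3 = 9; Q = 12/(3*3*4) * sum(Rj^2) - 3*3*4
  q_hand <- 12 / (3 * 3 * 4) * (16 + 25 + 81) - 3 * 3 * 4
  expect_equal(friedman_repeats(d_toy)$statistic, q_hand)
  # incomplete block dropped with a warning
  expect_warning(friedman_repeats(d_same[-1, ]), "dropped")
})

test_that("Kruskal-Wallis per-subject consistency matches hand ranks on a toy", {
  expect_equal(kruskal_wallis_per_subject(rep(c(1, 2, 3), 3),
                                          rep(1:3, each = 3))$p_value,
               1, tolerance = 1e-12)
  shifted <- c(rnorm(8), rnorm(8, 5), rnorm(8, 10))
  expect_lt(kruskal_wallis_per_subject(shifted, rep(1:3, each = 8))$p_value,
            0.01)
  # 3-group toy with no ties: H = 12/(N(N+1)) sum nj (Rbar_j - Rbar)^2
  vals <- c(1, 2, 9, 3, 7, 8, 4, 5, 6)
  grp <- rep(1:3, each = 3)
  rbar <- tapply(rank(vals), grp, mean)
  h_hand <- 12 / (9 * 10) * sum(3 * (rbar - 5)^2)
  expect_equal(kruskal_wallis_per_subject(vals, grp)$statistic, h_hand)
})

test_that("Cohen's d follows the pooled-SD convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(62)
  a <- rnorm(4000, 1, 1)
  b <- rnorm(4000, 0, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.08)
  expect_warning(d0 <- cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  expect_true(is.na(d0))
  # relation to Hedges g on a toy: g = d * (1 - 3 / (4 (n1 + n2) - 9))
  a <- c(2.1, 3.4, 4.0, 2.8)
  b <- c(1.0, 1.9, 1.4)
  d <- cohens_d(a, b)
  g <- d * (1 - 3 / (4 * 7 - 9))
  expect_lt(abs(g), abs(d))
})

test_that("shuffled-segment test is reproducible and degenerates correctly", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:8), segment = 1:3)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:4), "a", "b")
  set.seed(63)
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "a", 3, 0)
  r1 <- shuffled_segment_test(d, n_shuffles = 200, seed = 99)
  r2 <- shuffled_segment_test(d, n_shuffles = 200, seed = 99)
  expect_identical(r1, r2)
  # deterministic segments: identical per subject -> shuffling is vacuous,
  # the result equals the single-segment test exactly (0% or 100%)
  d2 <- d
  d2$value <- rep(stats::ave(d$value, d$subject)[d$segment == 1], each = 3)
  single_p <- rank_sum(unique(d2[d2$group == "a", c("subject", "value")])$value,
                       unique(d2[d2$group == "b", c("subject", "value")])$value)$p_value
  r3 <- shuffled_segment_test(d2, n_shuffles = 50, seed = 1)
  expect_equal(r3$percent_significant, if (single_p < 0.05) 100 else 0)
})

test_that("shuffle-significance percentage rises with the group effect", {
  pct_for_effect <- function(delta, seed) {
    d <- tidyr::expand_grid(subject = sprintf("s%d", 1:10), segment = 1:4)
    d$group <- ifelse(d$subject %in% sprintf("s%d", 1:5), "a", "b")
    set.seed(seed)
    d$value <- rnorm(nrow(d)) + ifelse(d$group == "a", delta, 0)
    mean(replicate(8, shuffled_segment_test(d, n_shuffles = 60)$percent_significant))
  }
  p0 <- pct_for_effect(0, 64)
  p1 <- pct_for_effect(1.5, 65)
  p2 <- pct_for_effect(3, 66)
  expect_lt(p0, p1)
  expect_lt(p1, p2)
})

test_that("sensitivity analysis reproduces the printed minimum detectable effect size", {
  expect_equal(sensitivity_mdes(13, 9, 0.05, 0.80), 1.387, tolerance = 0.02 / 1.387)
  # normal-approximation closed form lower-bounds the noncentral-t answer
  z_form <- (qnorm(0.975) + qnorm(0.80)) * sqrt(1 / 13 + 1 / 9)
  expect_lt(z_form, sensitivity_mdes(13, 9, 0.05, 0.80, parent = "uniform_are"))
  # at power = 0.5 and large n the z-based closed form is approached
  big <- sensitivity_mdes(4000, 4000, 0.05, 0.5, parent = "uniform_are")
  expect_equal(big, qnorm(0.975) * sqrt(2 / 4000), tolerance = 1e-3)
})

test_that("sensitivity_mdes is monotone in sample sizes, alpha and power", {
  base <- sensitivity_mdes(13, 9, 0.05, 0.80)
  expect_lt(sensitivity_mdes(20, 9, 0.05, 0.80), base)
  expect_lt(sensitivity_mdes(13, 15, 0.05, 0.80), base)
  expect_lt(sensitivity_mdes(13, 9, 0.10, 0.80), base)
  expect_gt(sensitivity_mdes(13, 9, 0.05, 0.90), base)
  expect_error(sensitivity_mdes(13, 9, alpha = 1.2), "alpha")
})

test_that("age regression handles constant, perfectly linear, and toy inputs", {
  ages <- c(40, 45, 50, 55, 60)
  expect_equal(age_regression(rep(2, 5), ages)$r, 0)
  lin <- age_regression(2 * ages + 1, ages)
  expect_equal(abs(lin$r), 1)
  expect_equal(lin$slope, 2)
  set.seed(67)
  v <- rnorm(5)
  tr <- age_regression(v, ages)
  ct <- stats::cor.test(ages, v)
  expect_equal(tr$r, unname(ct$estimate))
  expect_equal(tr$p_value, ct$p.value)
})

test_that("Bonferroni reporting mode scales pair-wise p-values by the pair count", {
  stats <- tibble::tibble(
    measure = "wpc", pair = c("Fp1-Fp2", "F3-Fp2", "Fp1-F4", "F3-F4"),
    min_p = c(0.004, 0.01, 0.02, 0.2),
    median_p = c(0.01, 0.03, 0.04, 0.5)
  )
  adj <- adjust_group_stats(stats)
  expect_equal(adj$min_p, pmin(stats$min_p * 4, 1))
  expect_equal(adj$min_p_raw, stats$min_p)
  # four frontal pairs: the 0.05 threshold becomes 0.0125 equivalently
  expect_identical(adj$min_p < 0.05, stats$min_p < 0.05 / 4)
})
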