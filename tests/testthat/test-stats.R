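test_that("the KS normality gate accepts normal and rejects discrete samples", {
  set.seed(31)
  a <- rnorm(500); b <- rnorm(500, 5, 2)
  expect_true(normality_gate(a, b))
  twopoint <- rep(c(0, 1), 250)
  expect_false(normality_gate(a, twopoint))
  expect_message(expect_false(normality_gate(a, rep(3, 50))),
                 "zero-variance")
  expect_error(normality_gate(a, c(1, 2)), "insufficient")
})

test_that("gated comparison routes to the right branch and records it", {
  set.seed(7)
  a <- rnorm(15); b <- rnorm(15, 0.2)
  res <- compare_groups(a, b)
  expect_match(res$test_used, "t-test")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # heavy-tailed data route to the rank-sum branch
  set.seed(8)
  h1 <- rlnorm(60, sdlog = 2.5); h2 <- rlnorm(60, sdlog = 2.5)
  res2 <- compare_groups(h1, h2)
  expect_equal(res2$test_used, "wilcoxon")
  # identical samples: no effect, maximal p
  res3 <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(res3$p_value, 0.99)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient")
})

test_that("exact rank-sum p-values match brute-force enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compare_groups(a, b, test = "wilcoxon")
  expect_equal(res$test_used, "wilcoxon")
  expect_equal(res$p_value, 0.1)
  # independent oracle: enumerate all C(6,3) = 20 rank assignments
  pooled <- c(a, b)
  combos <- combn(6, 3)
  stat_obs <- sum(rank(pooled)[1:3])
  stats_all <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- mean(stats_all)
  p_exact <- mean(abs(stats_all - mu) >= abs(stat_obs - mu))
  expect_equal(res$p_value, p_exact)
  # a second asymmetric case against the same oracle
  a2 <- c(1.3, 2.1, 9.5); b2 <- c(0.4, 3.2, 4.1, 7.7)
  r2 <- suppressMessages(compare_groups(a2, b2, test = "wilcoxon"))
  pooled2 <- c(a2, b2)
  combos2 <- combn(7, 3)
  s_obs <- sum(rank(pooled2)[1:3])
  s_all <- apply(combos2, 2, function(ix) sum(rank(pooled2)[ix]))
  mu2 <- mean(s_all)
  p2 <- mean(abs(s_all - mu2) >= abs(s_obs - mu2))
  expect_equal(r2$p_value, p2)
})

test_that("the gated procedure has power against a clear shift", {
  set.seed(99)
  rej <- 0
  for (i in 1:300) {
    p <- compare_groups(rnorm(20), rnorm(20, 2))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / 300, 0.95)
})

test_that("cohort analysis formats group summaries and validates inputs", {
  set.seed(12)
  tab <- data.frame(
    subject = sprintf("s%02d", 1:13),
    group = rep(c("wt", "ko"), c(7, 6)),
    metric = "cow_width_mm",
    value = c(rnorm(7, 2.82, 0.19), rnorm(6, 2.56, 0.08)))
  res <- run_cohort_analysis(tab)
  expect_s3_class(res, "test_result")
  expect_equal(nrow(res), 1L)
  summ <- attr(res, "group_summary")
  expect_true(grepl("±", summ$formatted[1]))
  expect_error(run_cohort_analysis(tab, metrics = "diameter"),
               "config error")
  expect_error(run_cohort_analysis(tab, comparisons = list(c("wt", "xx"))),
               "config error")
  expect_equal(nrow(run_cohort_analysis(tab, metrics = character())), 0L)
  # Holm option annotates adjusted p-values
  res2 <- run_cohort_analysis(tab, holm = TRUE)
  expect_true("p_adj_holm" %in% names(res2))
})

test_that("Monte-Carlo calibration table behaves as a power function should", {
  tp <- type1_power_table(effect_sizes = c(0, 2), n_per_group = 12,
                          n_replicates = 300, seed = 4)
  expect_lt(abs(tp$rejection_rate[tp$effect == 0] - 0.05), 0.04)
  expect_gt(tp$rejection_rate[tp$effect == 2], 0.9)
  # reproducible given the seed
  tp2 <- type1_power_table(effect_sizes = c(0, 2), n_per_group = 12,
                           n_replicates = 300, seed = 4)
  expect_identical(tp, tp2)
  expect_error(type1_power_table(n_replicates = 50), "100")
})
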