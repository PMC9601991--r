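test_that("pearson_r matches its definition and bounds", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, x[1:3]), "equal length")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("pearson_r is affine invariant and bounded on random data", {
  withr::with_seed(42, {
    for (i in 1:10) {
      x <- rnorm(20)
      y <- rnorm(20)
      r <- pearson_r(x, y)
      expect_true(r >= -1 && r <= 1)
      expect_equal(pearson_r(3 * x - 7, y), r, tolerance = 1e-8)
      expect_equal(pearson_r(x, 0.1 * y + 100), r, tolerance = 1e-8)
    }
  })
})

test_that("ANOVA flags separated groups and not identical ones", {
  same <- data.frame(v = rep(c(1, 2, 3, 4), 3),
                     g = rep(c("a", "b", "c"), each = 4))
  fit <- anova_bonferroni(same, v, g)
  expect_lt(fit$f_statistic, 1e-10)
  expect_gt(fit$p_value, 0.999)
  withr::with_seed(1, {
    far <- data.frame(v = c(rnorm(50), rnorm(50, 10)),
                      g = rep(c("a", "b"), each = 50))
  })
  expect_lt(anova_bonferroni(far, v, g)$p_value, 0.001)
  expect_error(anova_bonferroni(data.frame(v = 1:4, g = rep("a", 4)),
                                v, g), "2 groups")
})

test_that("pairwise p-values are raw p times m, capped at 1", {
  withr::with_seed(2, {
    d <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
  })
  fit <- anova_bonferroni(d, v, g)
  pw <- tidy(fit)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 3))
  # independent oracle: stats::pairwise.t.test with bonferroni
  ref <- pairwise.t.test(d$v, d$g, p.adjust.method = "bonferroni")
  ref_p <- ref$p.value[!is.na(ref$p.value)]
  expect_equal(sort(pw$p_adj), sort(ref_p), tolerance = 1e-12)
  # cap rule on a constructed raw p
  expect_equal(min(1, 0.6 * 3), 1)
  expect_true(all(pw$p_adj <= 1))
})

test_that("reader simulation is seeded and degrades with noise", {
  ors <- seq(0.2, 0.9, length.out = 149)
  perfect <- simulate_readers(ors, noise_sigma = 0, seed = 1)
  expect_equal(perfect$r, 1)
  sim <- simulate_readers(ors, noise_sigma = 0.05, seed = 1)
  expect_gte(sim$r, 0.9)
  expect_identical(sim$readings,
                   simulate_readers(ors, 0.05, seed = 1)$readings)
  expect_false(identical(sim$readings,
                         simulate_readers(ors, 0.05, seed = 2)$readings))
})

test_that("overestimation reproduces the worked example", {
  ov <- overestimation(56.9, 31.1, 1, 0.472)
  expect_equal(ov$rv_pct, 54.7)
  expect_equal(ov$rs_pct, 47.2)
  expect_equal(ov$diff_pct, 7.5)
  expect_equal(ov$normalized_pct, 13.7)
  # full-precision chain
  expect_equal(ov$rv, 31.1 / 56.9, tolerance = 1e-12)
  expect_equal(ov$normalized, (ov$rv - 0.472) / ov$rv, tolerance = 1e-12)
})

test_that("overestimation identities hold", {
  none <- overestimation(50, 50, 300, 300)
  expect_equal(none$diff, 0)
  expect_equal(none$normalized, 0)
  half <- overestimation(100, 80, 1, 0.4)   # rs = rv / 2
  expect_equal(half$normalized, 0.5)
  expect_error(overestimation(0, 10, 1, 1), "positive")
})

test_that("group summaries do the cohort bookkeeping", {
  cohort <- tibble::tibble(
    group = factor(rep(c("intact", "partial", "full"), c(39, 75, 35)),
                   levels = c("intact", "partial", "full")),
    volume_cm3 = rep(c(57, 44, 31), c(39, 75, 35)),
    or_value = rep(c(0.7, 0.5, 0.3), c(39, 75, 35)))
  cohort$stage <- thomazeau_stage(cohort$or_value)
  gs <- summarize_groups(cohort)
  expect_equal(gs$pct[gs$group == "partial"], 50.3)
  expect_equal(sum(gs$n), 149)
  # percentages of the partition sum to 100 within rounding
  expect_lt(abs(sum(gs$pct) - 100), 0.1)
  # stage counts partition each group
  expect_equal(gs$stage_I + gs$stage_II + gs$stage_III, gs$n)
  # single subject: mean equals value, range collapses
  one <- summarize_groups(cohort[1, , drop = FALSE])
  expect_equal(one$volume_mean, 57)
  expect_equal(one$volume_min, one$volume_max)
  expect_error(summarize_groups(cohort[0, ]), "empty")
  bad <- cohort; bad$group[1] <- NA
  expect_error(summarize_groups(bad), "unknown")
})
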