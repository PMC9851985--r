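test_that("delta summaries are equal-tailed quantiles of the draws", {
  const <- fake_samples(list(it = matrix(2, 500, 3)))
  s <- summarize_deltas(const)
  expect_true(all(s$median == 2 & s$ci_low == 2 & s$ci_high == 2))

  set.seed(1)
  perm <- matrix(sample(1:1000), ncol = 1)
  s2 <- summarize_deltas(fake_samples(list(it = cbind(perm, perm))))
  expect_equal(s2$median, c(500.5, 500.5))
  expect_equal(s2$ci_low, rep(quantile(1:1000, 0.025, names = FALSE), 2))
  expect_equal(s2$ci_high, rep(quantile(1:1000, 0.975, names = FALSE), 2))
  expect_equal(s2$ci_low[1], 25.975)
  expect_equal(s2$ci_high[1], 975.025)

  # median sits inside its interval; symmetric draws have median ~ mean
  set.seed(2)
  sym <- matrix(rnorm(2000, mean = 5), ncol = 2)
  s3 <- summarize_deltas(fake_samples(list(it = sym)))
  expect_true(all(s3$ci_low <= s3$median & s3$median <= s3$ci_high))
  expect_lt(abs(s3$median[1] - mean(sym[, 1])), 0.1)
  expect_error(summarize_deltas(fake_samples(list(it = sym[1:50, ]))),
               "100")
})

test_that("linearity flag is calibrated under an equal-delta null", {
  set.seed(7)
  flags <- replicate(50, {
    d <- matrix(rnorm(400 * 3, mean = 2, sd = 0.3), ncol = 3)
    test_linearity(fake_samples(list(it = d)), "it")$nonlinear
  })
  expect_lte(mean(flags), 0.20)
})

test_that("linearity flags a strongly shifted delta and reports max-min", {
  set.seed(8)
  d <- matrix(rnorm(400 * 3, mean = 2, sd = 0.3), ncol = 3)
  d[, 2] <- d[, 2] + 10 * 0.3       # one delta shifted by 10 posterior SDs
  res <- test_linearity(fake_samples(list(it = d)), "it")
  expect_true(res$nonlinear)
  expect_gt(res$max_diff$median, 2)
  expect_true(any(res$pairs$excludes_zero))

  # identical draw vectors: degenerate zero-width difference, linear
  d0 <- matrix(rnorm(300, 2, 0.2), ncol = 1)
  res0 <- test_linearity(fake_samples(list(it = cbind(d0, d0))), "it")
  expect_false(res0$nonlinear)
  expect_equal(c(res0$pairs$ci_low, res0$pairs$ci_high), c(0, 0))

  # invariant to permuting the iterations
  idx <- sample(nrow(d))
  res_p <- test_linearity(fake_samples(list(it = d[idx, ])), "it")
  expect_equal(res_p$nonlinear, res$nonlinear)
  expect_equal(res_p$max_diff$median, res$max_diff$median)
  expect_error(
    test_linearity(fake_samples(list(it = d[, 1, drop = FALSE])), "it"),
    "single")
})

test_that("item speeds summarize per-draw mean deltas consistently", {
  const <- fake_samples(list(it = matrix(2, 300, 3)))
  sp <- item_speeds(const)
  expect_equal(sp$mean_delta_median, 2)
  expect_equal(sp$iqr, 0)

  set.seed(9)
  fast <- matrix(rnorm(500 * 2, 3, 0.2), ncol = 2)
  slow <- matrix(rnorm(500 * 2, 10, 0.4), ncol = 2)
  s <- fake_samples(list(fast = fast, slow = slow))
  sp2 <- item_speeds(s)
  expect_lt(sp2$mean_delta_median[1], sp2$mean_delta_median[2])
  diff_draws <- mean_delta_draws(s, "slow") - mean_delta_draws(s, "fast")
  qs <- quantile(diff_draws, c(0.025, 0.975))
  expect_gt(qs[[1]], 0)   # non-overlapping speeds: difference CI excludes 0

  # consistency with the underlying draws to numerical precision
  expect_equal(mean(mean_delta_draws(s, "fast")),
               mean(rowMeans(fast)), tolerance = 1e-12)
})

test_that("group dynamics summarize per-iteration group means", {
  set.seed(10)
  n_draw <- 400
  subjects <- sprintf("s%02d", 1:40)
  xi <- matrix(rnorm(n_draw * 40, 0, 0.05), n_draw,
               dimnames = list(NULL, subjects))
  tau <- matrix(rnorm(n_draw * 40, 35, 0.5), n_draw,
                dimnames = list(NULL, subjects))
  tau[, 21:40] <- tau[, 21:40] + 18   # late-onset group (SCA6-like)
  s <- fake_samples(list(it = matrix(1, n_draw, 2)), xi = xi, tau = tau)
  grouping <- setNames(rep(c("early", "late"), each = 20), subjects)
  g <- group_dynamics(s, grouping)
  gap <- g$tau_median[g$group == "late"] - g$tau_median[g$group == "early"]
  expect_lt(abs(gap - 18), 2)
  # centred xi: acceleration factor close to 1
  expect_lt(abs(g$accel_median[1] - 1), 0.05)
  expect_error(group_dynamics(s, grouping[1:10]), "missing")

  # permuted labels on an exchangeable population: group differences
  # cover zero in most replicates
  tau_h <- matrix(rnorm(n_draw * 40, 35, 0.5), n_draw,
                  dimnames = list(NULL, subjects))
  s_h <- fake_samples(list(it = matrix(1, n_draw, 2)), xi = xi,
                      tau = tau_h)
  covers <- replicate(20, {
    gp <- setNames(sample(grouping), subjects)
    gg <- group_dynamics(s_h, gp)
    lo <- gg$tau_low[1] - gg$tau_high[2]
    hi <- gg$tau_high[1] - gg$tau_low[2]
    lo <= 0 && hi >= 0
  })
  expect_gte(mean(covers), 0.9)
})

test_that("onset/CAG correlation follows the Pearson log-CAG analysis", {
  cag <- 40:80
  tau <- 100 - 20 * log(cag)          # exactly linear in log(CAG)
  res <- cag_onset_correlation(tau, cag)
  expect_equal(res$r, -1)
  expect_lt(res$p, 1e-10)

  set.seed(11)
  cover <- replicate(50, {
    t2 <- rnorm(1000, 40, 8); c2 <- round(runif(1000, 30, 80))
    r <- cag_onset_correlation(t2, c2)
    abs(r$r) < 0.1 && r$ci_low <= 0 && r$ci_high >= 0
  })
  expect_gte(mean(cover), 0.9)
  expect_error(cag_onset_correlation(c(1, 2, 3), c(40, 41, 42)), "4")
  expect_error(cag_onset_correlation(rep(40, 10), 41:50), "variance")
})

test_that("published-style progression rate ratios compute directly", {
  expect_equal(round(progression_rate_ratio(2.11, 0.8), 2), 2.64)
  expect_equal(round(progression_rate_ratio(1.11, 0.99), 2), 1.12)
  expect_error(progression_rate_ratio(1, 0), "rate_slow")
})

test_that("analysis tables export as tidy CSV plus JSON", {
  set.seed(12)
  d <- list(gait = matrix(rnorm(300 * 2, 3, 0.2), ncol = 2),
            stance = matrix(rnorm(300 * 2, 4, 0.2), ncol = 2))
  s <- fake_samples(d)
  dir <- tempfile()
  out <- export_analysis(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("delta_summary.csv", "item_speeds.csv", "linearity.csv",
      "analysis.json")))))
  expect_equal(nrow(out$delta_summary), 4L)
  expect_equal(nrow(out$item_speeds), 2L)
})
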