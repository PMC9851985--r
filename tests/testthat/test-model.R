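test_that("time reparameterization follows psi = exp(xi) (age - tau)", {
  expect_equal(reparameterize(40, individual_params(0.7, 40)), 0)
  expect_equal(reparameterize(45, individual_params(0, 40)), 5)
  expect_equal(reparameterize(43, individual_params(log(2), 40)), 6)
  expect_equal(reparameterize(c(40, 45), individual_params(0, 40)),
               c(0, 5))
})

test_that("exceedance curves are logistic in reparameterized time", {
  pop <- toy_pop(steepness = 0.5)
  cc <- c(0, 2, 5)  # thresholds of item a: offset 0, deltas 2, 3
  expect_equal(exceedance(cc[2], "a", 2, pop), 0.5)
  expect_equal(exceedance(cc[1] + 0.5, "a", 1, pop), 1 / (1 + exp(-1)))
  expect_lt(exceedance(-1e6, "a", 1, pop), 1e-12)
  expect_error(exceedance(0, "a", 4, pop), "out of range")
  # strictly decreasing in level, increasing in psi
  psi <- seq(-5, 12, by = 0.5)
  e1 <- exceedance(psi, "a", 1, pop)
  e2 <- exceedance(psi, "a", 2, pop)
  expect_true(all(e1 > e2))
  expect_true(all(diff(e1) > 0))
})

test_that("level distributions are proper and match hand evaluation", {
  pop <- toy_pop(steepness = 1)
  p_lo <- level_distribution(-1e6, "a", pop)
  expect_gt(p_lo["0"], 1 - 1e-12)
  p_hi <- level_distribution(1e6, "a", pop)
  expect_gt(p_hi["3"], 1 - 1e-12)
  # hand evaluation at the midpoint of the first two thresholds
  psi <- 1; cc <- c(0, 2, 5); s <- 1
  hand <- c(1 - plogis((psi - cc[1]) / s),
            plogis((psi - cc[1]) / s) - plogis((psi - cc[2]) / s),
            plogis((psi - cc[2]) / s) - plogis((psi - cc[3]) / s),
            plogis((psi - cc[3]) / s))
  expect_equal(unname(level_distribution(psi, "a", pop)), hand,
               tolerance = 1e-12)
  # normalization along a dense sweep
  sweep <- level_distribution(seq(-30, 30, length.out = 401), "a", pop)
  expect_true(all(sweep >= 0))
  expect_true(all(abs(rowSums(sweep) - 1) < 1e-12))
})

test_that("most likely level is the argmax and non-decreasing in psi", {
  pop <- toy_pop(steepness = 0.4)
  expect_identical(most_likely_level(-100, "a", pop), 0L)
  expect_identical(most_likely_level(100, "a", pop), 3L)
  psi <- seq(-10, 15, by = 0.05)
  lev <- most_likely_level(psi, "a", pop)
  brute <- vapply(psi, function(x) {
    which.max(level_distribution(x, "a", pop)) - 1L
  }, integer(1L))
  expect_identical(lev, brute)
  expect_true(all(diff(lev) >= 0L))
})

test_that("population trajectory composes per-item most likely levels", {
  pop <- toy_pop(steepness = 0.3)
  ages <- seq(20, 39, by = 1)   # entirely before tau_pop = 40
  tr <- population_trajectory(ages, pop)
  expect_true(all(tr$a == 0L & tr$b == 0L & tr$total == 0L))

  ages2 <- seq(30, 60, by = 0.25)
  tr2 <- population_trajectory(ages2, pop)
  psi <- ages2 - 40
  expect_identical(tr2$a, most_likely_level(psi, "a", pop))
  expect_identical(tr2$total, tr2$a + tr2$b)
  expect_true(all(diff(tr2$total) >= 0L))

  # single item with equal deltas d: one step every d years on psi axis
  sc1 <- total_score_scale(4, "single", "s")
  pop1 <- population_params(deltas = list(s = rep(2, 3)),
                            steepness = c(s = 0.05),
                            tau_pop = 0, sigma_tau = 1, sigma_xi = 0.1,
                            scale = sc1)
  grid <- c(-1, 1, 3, 5, 7)  # midpoints between the 2-year thresholds
  lev <- most_likely_level(grid, "s", pop1)
  expect_identical(lev, 0:4)
})

test_that("calendar time at a level scales by exp(-xi)", {
  # with xi = ln 2 the plateaus of the most likely level halve in width
  sc1 <- total_score_scale(3, "single", "s")
  pop1 <- population_params(deltas = list(s = c(4, 4)),
                            steepness = c(s = 0.05),
                            tau_pop = 50, sigma_tau = 1, sigma_xi = 0.1,
                            scale = sc1)
  ages <- seq(50, 70, by = 0.01)
  plateau <- function(xi) {
    psi <- reparameterize(ages, individual_params(xi, 50))
    lev <- most_likely_level(psi, "s", pop1)
    sum(lev == 1L) * 0.01
  }
  expect_equal(plateau(log(2)), plateau(0) / 2, tolerance = 0.02)
})

test_that("cohort log-likelihood equals an independent per-observation sum", {
  pop <- toy_pop(steepness = 0.8)
  df <- data.frame(
    subject_id = c("p1", "p1", "p2", "p3"),
    age = c(41, 44, 50, 39),
    a = c(1L, 2L, 3L, NA),
    b = c(0L, NA, 2L, 1L))
  cohort <- as_cohort(df, toy_scale())
  inds <- data.frame(subject_id = c("p1", "p2", "p3"),
                     xi = c(0.2, -0.1, 0),
                     tau = c(40, 42, 38))
  ll <- log_likelihood(cohort, pop, inds)
  # naive loop oracle
  oracle <- 0
  for (i in seq_len(nrow(df))) {
    j <- match(df$subject_id[i], inds$subject_id)
    psi <- exp(inds$xi[j]) * (df$age[i] - inds$tau[j])
    for (item in c("a", "b")) {
      y <- df[[item]][i]
      if (is.na(y)) next
      oracle <- oracle +
        unname(log(level_distribution(psi, item, pop)[y + 1L]))
    }
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
  # missing entries contribute exactly zero
  df2 <- df; df2$b[1] <- NA
  ll2 <- log_likelihood(as_cohort(df2, toy_scale()), pop, inds)
  psi1 <- exp(0.2) * (41 - 40)
  expect_equal(ll - ll2,
               unname(log(level_distribution(psi1, "b", pop)[1L])),
               tolerance = 1e-10)
  # a single observation with model probability p gives log p
  df3 <- data.frame(subject_id = c("p1", "p2"), age = c(41, 42),
                    a = c(1L, NA), b = c(NA, 0L))
  df3 <- df3[1, ]
  cohort3 <- as_cohort(df3, toy_scale())
  p <- level_distribution(exp(0.2) * 1, "a", pop)[2L]
  expect_equal(
    log_likelihood(cohort3, pop, inds[1, ]), unname(log(p)),
    tolerance = 1e-12)
  expect_error(log_likelihood(cohort, pop, inds[1:2, ]), "missing")
})

test_that("population parameters validate and round-trip through JSON", {
  pop <- toy_pop()
  path <- tempfile(fileext = ".json")
  write_population_params(pop, path)
  back <- read_population_params(path)
  expect_equal(back$deltas, pop$deltas)
  expect_equal(back$offsets, pop$offsets)
  expect_equal(back$tau_pop, pop$tau_pop)
  expect_error(population_params(deltas = list(a = c(2, -1), b = 4),
                                 tau_pop = 40, sigma_tau = 5,
                                 sigma_xi = 0.3, scale = toy_scale()),
               "strictly positive")
  expect_error(population_params(deltas = list(a = c(2), b = 4),
                                 tau_pop = 40, sigma_tau = 5,
                                 sigma_xi = 0.3, scale = toy_scale()),
               "needs 2 deltas")
  expect_error(population_params(deltas = list(a = c(2, 3), b = 4),
                                 offsets = c(a = 1, b = 0),
                                 tau_pop = 40, sigma_tau = 5,
                                 sigma_xi = 0.3, scale = toy_scale()),
               "first item")
})
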