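test_that("population parameters are drawn inside the configured bands", {
  cfg <- generator_config()
  pop <- generate_population_params(sara_scale(), cfg, seed = 1)
  expect_gte(mean(pop$deltas$gait), 2.5)
  expect_lte(mean(pop$deltas$gait), 5)
  expect_gte(mean(pop$deltas$finger_chase), 9)
  expect_lte(mean(pop$deltas$heel_shin), 12.5)
  expect_equal(pop$offsets[["gait"]], 0)
  # degenerate band pins every delta
  cfg2 <- generator_config(delta_bands = list(total = c(3, 3)))
  pop2 <- generate_population_params(total_score_scale(5, "t", "total"),
                                     cfg2, seed = 2)
  expect_equal(unname(pop2$deltas$total), rep(3, 4))
  # same seed, same draw
  expect_equal(generate_population_params(sara_scale(), cfg, seed = 1),
               pop)
})

test_that("cohorts regenerate bit-identically from a fixed seed", {
  cfg <- generator_config(n_subjects = 60)
  pop <- generate_population_params(sara_scale(), cfg, seed = 3)
  a <- generate_cohort(pop, cfg, seed = 4)
  b <- generate_cohort(pop, cfg, seed = 4)
  expect_identical(a$cohort$visits, b$cohort$visits)
  expect_identical(a$truth$individuals, b$truth$individuals)
  c2 <- generate_cohort(pop, cfg, seed = 5)
  expect_false(identical(a$cohort$visits, c2$cohort$visits))
  # every generated cohort passes its own validation and round-trips
  path <- tempfile(fileext = ".csv")
  write_cohort(a$cohort, path)
  expect_equal(load_cohort(path)$visits, a$cohort$visits)
})

test_that("generated structure matches the configured cohort shape", {
  cfg <- generator_config(n_subjects = 1000)
  pop <- generate_population_params(sara_scale(), cfg, seed = 6)
  gen <- generate_cohort(pop, cfg, seed = 7)
  v <- gen$cohort$visits
  expect_equal(length(unique(v$subject_id)), 1000L)
  # visit-count distribution consistent with the configured probabilities
  counts <- table(factor(tapply(v$age, v$subject_id, length),
                         levels = 1:6))
  gof <- suppressWarnings(chisq.test(counts, p = cfg$visit_probs))
  expect_gt(gof$p.value, 0.01)
  # intervals centred on one year
  gaps <- unlist(tapply(v$age, v$subject_id, diff))
  expect_lt(abs(mean(gaps) - 1), 0.05)
  # per-item missingness near its configured rate
  miss <- mean(is.na(as.matrix(v[names(sara_scale()$items)])))
  expect_lt(abs(miss - cfg$missing_rate), 0.01)
  # pre-ataxic subjects are RISCA-labelled and start before onset
  tr <- gen$truth$individuals
  expect_true(all(tr$cohort[tr$preataxic] == "RISCA"))
  first_age <- tapply(v$age, v$subject_id, min)[tr$subject_id]
  expect_true(all(first_age[tr$preataxic] < tr$tau[tr$preataxic]))
})

test_that("onset ages correlate with log CAG at the configured strength", {
  cfg <- generator_config(n_subjects = 300)
  pop <- generate_population_params(sara_scale(), cfg, seed = 8)
  gen <- generate_cohort(pop, cfg, seed = 9)
  tr <- gen$truth$individuals
  for (g in c("SCA2", "SCA3")) {
    i <- tr$sca_type == g
    r <- cor(tr$tau[i], log(tr$cag[i]))
    expect_lt(abs(r - (-0.7)), 0.15)
  }
  # genotype-specific onset means are respected
  mu <- tapply(tr$tau, tr$sca_type, mean)
  expect_gt(mu[["SCA6"]], mu[["SCA1"]] + 12)
})

test_that("sharp-transition cohorts first score near the true onset age", {
  cfg <- generator_config(
    n_subjects = 80, missing_rate = 0, steepness = 0.02,
    delta_bands = list(total = c(1.5, 1.5)), sigma_tau = 4, sigma_xi = 0.05,
    duration_range = c(0, 0), preataxic_fraction = 0,
    visit_probs = c(0, 0, 0, 0, 0, 1))
  sc <- total_score_scale(6, "t", "total")
  pop <- generate_population_params(sc, cfg, seed = 10)
  gen <- generate_cohort(pop, cfg, seed = 11)
  v <- gen$cohort$visits
  tr <- gen$truth$individuals
  first_nz <- tapply(seq_len(nrow(v)), v$subject_id, function(i) {
    nz <- i[v$total[i] >= 1L]
    if (length(nz)) v$age[nz[1L]] else NA_real_
  })
  gap <- first_nz[tr$subject_id] - tr$tau
  expect_lt(median(abs(gap), na.rm = TRUE), 1.2)
})

test_that("simulated trial changes track the generative progression rate", {
  # equal deltas d: roughly 1/d points per year in the linear regime
  cfg <- generator_config(
    n_subjects = 2000, missing_rate = 0, steepness = 0.5,
    delta_bands = list(total = c(1, 1)), sigma_tau = 5, sigma_xi = 0.2,
    duration_range = c(2, 6), preataxic_fraction = 0)
  sc <- total_score_scale(12, "t", "total")
  pop <- generate_population_params(sc, cfg, seed = 12)
  res <- generate_trial_changes(pop, cfg, months = 12, seed = 13)
  expect_lt(abs(res$mean_change - 1), 0.15)
  # effectively static disease: near-zero change
  cfg0 <- generator_config(
    n_subjects = 500, missing_rate = 0, steepness = 0.5,
    delta_bands = list(total = c(500, 500)), sigma_tau = 5, sigma_xi = 0.2,
    preataxic_fraction = 0)
  pop0 <- generate_population_params(sc, cfg0, seed = 14)
  res0 <- generate_trial_changes(pop0, cfg0, months = 12, seed = 15)
  expect_lt(abs(res0$mean_change), 0.05)
  # determinism
  res2 <- generate_trial_changes(pop, cfg, months = 12, seed = 13)
  expect_identical(res$changes, res2$changes)
})

test_that("configs round-trip through YAML with nested fields", {
  cfg <- generator_config(n_subjects = 40, missing_rate = 0.1,
                          cag_correlation = -0.6)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 40, missing_rate = 0.1,
                        cag_correlation = -0.6,
                        tau_means = as.list(cfg$tau_means)), path)
  back <- read_generator_config(path)
  expect_equal(back$n_subjects, 40)
  expect_equal(back$missing_rate, 0.1)
  expect_equal(back$cag_correlation, -0.6)
  expect_equal(back$tau_means, cfg$tau_means)
})

test_that("a full multivariate fit recovers the item speed ordering", {
  cfg <- generator_config(n_subjects = 300)
  pop <- generate_population_params(sara_scale(), cfg, seed = 16)
  gen <- generate_cohort(pop, cfg, seed = 17)
  s <- fit(gen$cohort, mcmc_config(profile = "test", n_chains = 1L,
                                   seed = 18))
  sp <- item_speeds(s)
  fast <- sp$mean_delta_median[sp$item %in% c("gait", "stance")]
  slow <- sp$mean_delta_median[sp$item %in%
    c("finger_chase", "finger_nose", "hand_fast", "heel_shin")]
  expect_true(all(outer(fast, slow, "<")))
})
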