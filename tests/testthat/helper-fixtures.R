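# Shared fixtures: tiny cohorts, toy model parameters and hand-rolled
# posterior-sample objects, all built in code.

toy_scale <- function() scale_definition("toy", c(a = 3, b = 2))

toy_pop <- function(steepness = 0.5) {
  population_params(
    deltas = list(a = c(2, 3), b = 4),
    offsets = c(a = 0, b = 1),
    steepness = c(a = steepness, b = steepness),
    tau_pop = 40, sigma_tau = 5, sigma_xi = 0.3,
    scale = toy_scale())
}

toy_cohort_df <- function() {
  data.frame(
    subject_id = c("p1", "p1", "p2", "p2"),
    age = c(40, 41, 50, 52),
    a = c(0L, 1L, 2L, 3L),
    b = c(0L, 0L, 1L, 2L),
    stringsAsFactors = FALSE)
}

write_sara_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  path
}

# Minimal SARA visit row with all items zero
sara_row <- function(subject_id = "s1", age = 40, ...) {
  row <- data.frame(subject_id = subject_id, age = age,
                    gait = 0L, stance = 0L, sitting = 0L, speech = 0L,
                    finger_chase = 0L, finger_nose = 0L, hand_fast = 0L,
                    heel_shin = 0L, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# Hand-built posterior_samples object from explicit draw matrices.
# `deltas` is a named list (per item) of draws x levels matrices.
fake_samples <- function(deltas, xi = NULL, tau = NULL,
                         subjects = NULL, scale = NULL) {
  items <- names(deltas)
  maxima <- vapply(deltas, function(d) ncol(d) + 1L, integer(1L))
  if (is.null(scale)) {
    scale <- scale_definition("fake", stats::setNames(maxima, items))
  }
  n_draw <- nrow(deltas[[1L]])
  pop_cols <- list()
  for (k in seq_along(items)) {
    d <- deltas[[k]]
    colnames(d) <- sprintf("delta[%s,%d]", items[k], seq_len(ncol(d)))
    pop_cols[[k]] <- d
  }
  population <- do.call(cbind, pop_cols)
  extras <- matrix(
    rep(c(rep(0, length(items)), rep(0.5, length(items)), 40, 5, 0.3),
        each = n_draw),
    nrow = n_draw)
  colnames(extras) <- c(sprintf("offset[%s]", items),
                        sprintf("steepness[%s]", items),
                        "tau_pop", "sigma_tau", "sigma_xi")
  population <- cbind(population, extras)
  if (is.null(xi)) {
    if (is.null(subjects)) subjects <- c("s1", "s2")
    xi <- matrix(0, n_draw, length(subjects),
                 dimnames = list(NULL, subjects))
    tau <- matrix(40, n_draw, length(subjects),
                  dimnames = list(NULL, subjects))
  } else {
    subjects <- colnames(xi)
  }
  structure(
    list(population = population, xi = xi, tau = tau,
         chain = rep(1L, n_draw),
         acceptance = c(xi = 0.3, tau = 0.3, delta = 0.3,
                        steepness = 0.3, offset = 0.3),
         subjects = subjects, scale = scale, mode = "multivariate",
         config = mcmc_config(n_burnin = 10, n_samples = n_draw,
                              n_chains = 1L),
         seed = 1L),
    class = "posterior_samples")
}

# Study conditions for the univariate recovery experiments: 10-level
# pseudo-item, equal one-year level durations, exogenous entry ages
# (visit times independent of tau, the condition under which
# likelihood-based recovery is consistent), single genotype so the
# model's normal onset prior is well-specified.
recovery_config <- function(n_subjects = 300) {
  generator_config(
    n_subjects = n_subjects, missing_rate = 0,
    genotype_probs = c(SCA1 = 0, SCA2 = 1, SCA3 = 0, SCA6 = 0),
    delta_bands = list(total = c(1, 1)), steepness = 0.5,
    entry_model = "age", entry_age_mean = 37, entry_age_sd = 5,
    visit_probs = c(0, 0, 0, 1, 0, 0),
    preataxic_fraction = 0, sigma_tau = 5, sigma_xi = 0.3)
}

recovery_scale <- function() total_score_scale(10, "pseudo", "total")
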