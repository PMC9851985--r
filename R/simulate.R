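#' Synthetic cohort generator configuration
#'
#' Defaults emulate the structure of the pooled SCA natural-history
#' cohorts: ~1200 subjects across four genotypes with genotype-specific
#' mean start-of-progression ages (32.7 / 33.0 / 37.2 / 51.0 years for
#' SCA1/2/3/6), 1-6 visits at roughly yearly intervals, per-item
#' missingness, faster progression on gait/stance than on the kinetic
#' items, CAG repeat lengths centred on the genotype medians and
#' negatively correlated with the start age on the log scale (target
#' r = -0.7 within genotype), and a pre-ataxic subset observed before
#' their start of progression (RISCA-like).
#'
#' @param n_subjects Number of subjects.
#' @param genotype_probs Named mixture proportions over SCA1/2/3/6.
#' @param tau_means Named per-genotype mean start-of-progression ages (y).
#' @param sigma_tau Within-genotype SD of the start age (years).
#' @param sigma_xi SD of the log acceleration factor.
#' @param delta_bands Named list of `c(lo, hi)` bands (years) for each
#'   item's level durations; each delta is drawn uniformly in its band, so
#'   the item's mean delta lies in the band.
#' @param steepness Transition width s (years) shared by all items.
#' @param offset_range Range (years) for onset offsets of items after the
#'   first.
#' @param visit_probs Probabilities of 1..6 visits per subject.
#' @param visit_interval_mean,visit_interval_sd Mean and jitter SD (years)
#'   of between-visit intervals (floored at 0.3 y so ages stay increasing).
#' @param missing_rate Per-item, per-visit missingness probability (at
#'   least one item is always kept per visit).
#' @param duration_range Uniform range (years) of disease duration at the
#'   baseline visit for affected subjects (`entry_model = "duration"`).
#' @param entry_model `"duration"` (default) draws the baseline visit at
#'   `tau + U(duration_range)`, emulating enrolment a variable time after
#'   clinical onset — realistic, but it makes observation times informative
#'   about tau, which biases any likelihood that ignores the enrolment
#'   process.  `"age"` draws the baseline age independently of the
#'   subject's tau (Normal(`entry_age_mean`, `entry_age_sd`)), giving
#'   exogenous visit times under which likelihood-based estimation is
#'   consistent; use it for estimator-validation studies.
#' @param entry_age_mean,entry_age_sd Entry-age distribution for
#'   `entry_model = "age"` (default mean: mixture mean of `tau_means` plus
#'   the midpoint of `duration_range`).
#' @param preataxic_fraction Fraction of subjects observed starting before
#'   their start of progression (assigned to the RISCA cohort label).
#' @param preataxic_lead Maximum years before tau at which a pre-ataxic
#'   subject's baseline falls.
#' @param cag_medians Named per-genotype median CAG repeat lengths.
#' @param cag_log_sd Named per-genotype SDs of log(CAG).
#' @param cag_correlation Target correlation between tau and log(CAG)
#'   within genotype.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 300L,
    genotype_probs = c(SCA1 = 267, SCA2 = 331, SCA3 = 410,
                       SCA6 = 202) / 1210,
    tau_means = c(SCA1 = 32.7, SCA2 = 33.0, SCA3 = 37.2, SCA6 = 51.0),
    sigma_tau = 8, sigma_xi = 0.4,
    delta_bands = list(
      gait = c(2.5, 5), stance = c(2.5, 5),
      sitting = c(5, 7.5), speech = c(5, 7.5),
      finger_chase = c(9, 12.5), finger_nose = c(9, 12.5),
      hand_fast = c(9, 12.5), heel_shin = c(9, 12.5)),
    steepness = 1.0,
    offset_range = c(0, 3),
    visit_probs = c(0.10, 0.20, 0.22, 0.18, 0.16, 0.14),
    visit_interval_mean = 1.0, visit_interval_sd = 0.2,
    missing_rate = 0.03,
    duration_range = c(0, 15),
    entry_model = c("duration", "age"),
    entry_age_mean = NULL, entry_age_sd = 7,
    preataxic_fraction = 0.12, preataxic_lead = 10,
    cag_medians = c(SCA1 = 46.5, SCA2 = 39, SCA3 = 70, SCA6 = 22),
    cag_log_sd = c(SCA1 = 0.09, SCA2 = 0.08, SCA3 = 0.05, SCA6 = 0.02),
    cag_correlation = -0.7) {
  stopifnot(n_subjects >= 0,
            abs(sum(genotype_probs) - 1) < 1e-8,
            sigma_tau > 0, sigma_xi > 0, steepness > 0,
            missing_rate >= 0, missing_rate <= 1,
            preataxic_fraction >= 0, preataxic_fraction < 1,
            abs(sum(visit_probs) - 1) < 1e-8,
            cag_correlation >= -1, cag_correlation <= 1)
  if (any(vapply(delta_bands, function(b) b[1L] <= 0 || b[2L] < b[1L],
                 logical(1L)))) {
    stop("delta bands must be positive with lo <= hi")
  }
  entry_model <- match.arg(entry_model)
  if (is.null(entry_age_mean)) {
    entry_age_mean <- sum(genotype_probs * tau_means) +
      mean(duration_range)
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file whose keys are
#'   [generator_config()] arguments; missing keys keep their defaults.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (nm in c("genotype_probs", "tau_means", "cag_medians", "cag_log_sd")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$delta_bands)) {
    raw$delta_bands <- lapply(raw$delta_bands, as.numeric)
  }
  do.call(generator_config, raw)
}

#' Draw population parameters for a synthetic cohort
#'
#' Level durations are drawn uniformly within each item's configured band,
#' onset offsets uniformly in `offset_range` (first item fixed at 0), and
#' the population start age is the genotype-mixture mean.
#'
#' @param scale A `scale_definition` (items must match the config's
#'   `delta_bands`; a single-item scale uses the first band).
#' @param config A `generator_config`.
#' @param seed Integer seed.
#' @return A `population_params`.
#' @export
generate_population_params <- function(scale, config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(seed, {
    items <- names(scale$items)
    deltas <- lapply(seq_along(items), function(k) {
      band <- config$delta_bands[[items[k]]]
      if (is.null(band)) band <- config$delta_bands[[1L]]
      stats::runif(scale$items[[k]] - 1L, band[1L], band[2L])
    })
    names(deltas) <- items
    offsets <- c(0, stats::runif(length(items) - 1L,
                                 config$offset_range[1L],
                                 config$offset_range[2L]))
    population_params(
      deltas = deltas,
      offsets = stats::setNames(offsets, items),
      steepness = stats::setNames(rep(config$steepness, length(items)),
                                  items),
      tau_pop = sum(config$genotype_probs * config$tau_means),
      sigma_tau = config$sigma_tau,
      sigma_xi = config$sigma_xi,
      scale = scale)
  })
}

# Draw per-subject individual parameters and cofactors.
draw_subjects <- function(config) {
  n <- config$n_subjects
  geno <- sample(names(config$genotype_probs), n, replace = TRUE,
                 prob = config$genotype_probs)
  tau <- stats::rnorm(n, config$tau_means[geno], config$sigma_tau)
  xi <- stats::rnorm(n, 0, config$sigma_xi)
  r <- config$cag_correlation
  sd_lc <- config$cag_log_sd[geno]
  zres <- stats::rnorm(n)
  log_cag <- log(config$cag_medians[geno]) +
    r * sd_lc * (tau - config$tau_means[geno]) / config$sigma_tau +
    sqrt(1 - r^2) * sd_lc * zres
  cag <- pmax(round(exp(log_cag)), 1)
  pre <- stats::runif(n) < config$preataxic_fraction
  src <- ifelse(pre, "RISCA",
                sample(c("EUROSCA", "CRC-SCA", "SPATAX"), n, replace = TRUE,
                       prob = c(0.45, 0.25, 0.30)))
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sca_type = geno, xi = xi, tau = tau, cag = as.integer(cag),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cohort = src,
    continent = ifelse(src == "CRC-SCA", "America", "Europe"),
    preataxic = pre,
    stringsAsFactors = FALSE)
}

# Inverse-CDF sampling of levels from the ordinal model, vectorized over
# visits for one item.
sample_levels <- function(psi, item, pop) {
  p <- level_distribution(psi, item, pop)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  cum <- t(apply(p, 1L, cumsum))
  u <- stats::runif(nrow(p))
  as.integer(rowSums(cum < u))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subjects (genotype, xi, tau, CAG, cofactors), a visit schedule
#' (1-6 visits at jittered yearly intervals, baseline at tau plus a
#' uniform disease duration, or before tau for the pre-ataxic subset),
#' item scores from the ordinal model at each subject's reparameterized
#' times, and per-item missingness.  Deterministic given the seed.
#'
#' @param pop A `population_params` (e.g. from
#'   [generate_population_params()]).
#' @param config A `generator_config`.
#' @param seed Integer seed.
#' @return List with `cohort` (a validated `sara_cohort`) and `truth`
#'   (the generating `population_params` and per-subject individual
#'   parameters, genotype and pre-ataxic flag).
#' @export
generate_cohort <- function(pop, config, seed = 1L) {
  stopifnot(inherits(pop, "population_params"),
            inherits(config, "generator_config"))
  if (config$n_subjects == 0L) stop("n_subjects must be positive")
  local_seed(seed, {
    subj <- draw_subjects(config)
    items <- names(pop$scale$items)
    visit_rows <- lapply(seq_len(nrow(subj)), function(i) {
      nv <- sample(seq_along(config$visit_probs), 1L,
                   prob = config$visit_probs)
      base_age <- if (subj$preataxic[i]) {
        subj$tau[i] - stats::runif(1L, 0, config$preataxic_lead)
      } else if (config$entry_model == "age") {
        stats::rnorm(1L, config$entry_age_mean, config$entry_age_sd)
      } else {
        subj$tau[i] + stats::runif(1L, config$duration_range[1L],
                                   config$duration_range[2L])
      }
      gaps <- pmax(stats::rnorm(nv - 1L, config$visit_interval_mean,
                                config$visit_interval_sd), 0.3)
      ages <- base_age + cumsum(c(0, gaps))
      ages <- ages + max(0, 1 - ages[1L])  # keep ages positive, gaps intact
      data.frame(subject_id = subj$subject_id[i], age = ages,
                 stringsAsFactors = FALSE)
    })
    visits <- do.call(rbind, visit_rows)
    idx <- match(visits$subject_id, subj$subject_id)
    psi <- exp(subj$xi[idx]) * (visits$age - subj$tau[idx])
    for (item in items) visits[[item]] <- sample_levels(psi, item, pop)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(nrow(visits) * length(items)) <
                       config$missing_rate,
                     nrow(visits), length(items))
      all_gone <- rowSums(!mask) == 0L
      if (any(all_gone)) {  # keep at least one item per visit
        keep_col <- sample.int(length(items), sum(all_gone), replace = TRUE)
        mask[cbind(which(all_gone), keep_col)] <- FALSE
      }
      for (k in seq_along(items)) {
        visits[[items[k]]][mask[, k]] <- NA_integer_
      }
    }
    meta_cols <- c("sca_type", "sex", "cag", "cohort", "continent")
    for (col in meta_cols) visits[[col]] <- subj[[col]][idx]
    cohort <- suppressMessages(as_cohort(visits, pop$scale))
    list(cohort = cohort,
         truth = list(pop = pop,
                      individuals = subj,
                      config = config, seed = as.integer(seed)))
  })
}

#' Simulate trial change scores from the generative model
#'
#' Draws a cohort of subjects and scores each at baseline and again
#' `months` later; the change in total score (complete items only; no
#' missingness is applied) feeds the trial-design module.  The summary
#' mean/SD excludes pre-ataxic (RISCA-like) subjects, whose near-floor
#' scores would dilute the progression estimate.
#'
#' @param pop A `population_params`.
#' @param config A `generator_config`.
#' @param months Horizon between the two visits.
#' @param seed Integer seed.
#' @return List: `changes` (per-subject data frame with `baseline_total`,
#'   `change`, `preataxic`), `mean_change`, `sd_change` (affected subjects
#'   only).
#' @export
generate_trial_changes <- function(pop, config, months = 12, seed = 1L) {
  local_seed(seed, {
    subj <- draw_subjects(config)
    items <- names(pop$scale$items)
    base_age <- ifelse(
      subj$preataxic,
      subj$tau - stats::runif(nrow(subj), 0, config$preataxic_lead),
      if (config$entry_model == "age") {
        stats::rnorm(nrow(subj), config$entry_age_mean, config$entry_age_sd)
      } else {
        subj$tau + stats::runif(nrow(subj), config$duration_range[1L],
                                config$duration_range[2L])
      })
    totals <- function(ages) {
      psi <- exp(subj$xi) * (ages - subj$tau)
      tot <- 0L
      for (item in items) tot <- tot + sample_levels(psi, item, pop)
      tot
    }
    t0 <- totals(base_age)
    t1 <- totals(base_age + months / 12)
    changes <- data.frame(subject_id = subj$subject_id,
                          baseline_total = t0,
                          change = t1 - t0,
                          preataxic = subj$preataxic,
                          stringsAsFactors = FALSE)
    affected <- changes[!changes$preataxic, ]
    list(changes = changes,
         mean_change = mean(affected$change),
         sd_change = stats::sd(affected$change))
  })
}

#' Write generator ground truth as JSON
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    pop = list(
      deltas_years = lapply(truth$pop$deltas, as.numeric),
      offsets_years = as.list(truth$pop$offsets),
      steepness_years = as.list(truth$pop$steepness),
      tau_pop_years = truth$pop$tau_pop,
      sigma_tau_years = truth$pop$sigma_tau,
      sigma_xi_log = truth$pop$sigma_xi),
    individuals = truth$individuals,
    seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
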