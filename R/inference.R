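#' MCMC configuration
#'
#' Controls the Metropolis-within-Gibbs sampler with stochastic-
#' approximation hyperparameter updates.  The default budget (5500 warm-up
#' iterations discarded, 3500 retained, no thinning) matches the analysis
#' profile; `profile = "test"` is a reduced desk-scale budget (1000 + 500)
#' for simulation studies and the test-suite.
#'
#' @param n_burnin Warm-up iterations (adaptive proposals, stochastic-
#'   approximation updates of the hyperparameters, all discarded).
#' @param n_samples Retained iterations per chain.
#' @param n_chains Number of independent chains; draws are pooled.
#' @param proposal_scales Named list of initial random-walk SDs:
#'   `xi`, `tau` (individual blocks), `delta`, `steepness` (log scale),
#'   `offset` (years).
#' @param saem_exponent Step-size exponent a: steps are 1 for the first
#'   half of the burn-in, then k^(-a), satisfying the usual stochastic-
#'   approximation conditions for 1/2 < a <= 1.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param profile Shortcut: `"analysis"` (5500 + 3500) or `"test"`
#'   (1000 + 500).  Explicit arguments override the profile.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burnin = NULL, n_samples = NULL, n_chains = 2L,
                        proposal_scales = list(), saem_exponent = 0.65,
                        seed = 1L, profile = c("analysis", "test")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "test") c(1000L, 500L) else c(5500L, 3500L)
  if (is.null(n_burnin)) n_burnin <- defaults[1L]
  if (is.null(n_samples)) n_samples <- defaults[2L]
  stopifnot(n_burnin >= 10L, n_samples >= 1L, n_chains >= 1L,
            saem_exponent > 0.5, saem_exponent <= 1)
  ps <- utils::modifyList(
    list(xi = 0.15, tau = 1.5, delta = 0.15, steepness = 0.25,
         offset = 0.8), proposal_scales)
  if (any(unlist(ps) <= 0)) stop("proposal scales must be positive")
  structure(list(n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 n_chains = as.integer(n_chains),
                 proposal_scales = ps,
                 saem_exponent = saem_exponent,
                 seed = as.integer(seed),
                 profile = profile),
            class = "mcmc_config")
}

#' Fit the ordinal disease-course model
#'
#' Joint estimation of population and individual parameters by Markov chain
#' Monte Carlo with stochastic approximation (MCMC-SAEM).  Individual
#' parameters (xi_i, tau_i) are updated by vectorized per-subject
#' Metropolis steps; population level durations, onset offsets and
#' steepness by per-parameter Metropolis on unconstrained transforms (log
#' deltas, log steepness) under diffuse Normal(0, 1e6) priors; the
#' hyperparameters tau_pop, sigma_tau and sigma_xi by decreasing-step
#' stochastic approximation of the empirical mean/SD of the current
#' individual draws during warm-up (frozen during sampling).  After every
#' iteration the xi are recentred to mean zero and the compensation is
#' absorbed into the deltas, offsets and steepness, which enforces the
#' identifiability constraint that individual effects average to zero.
#'
#' @param cohort A `sara_cohort`.
#' @param config An `mcmc_config`.
#' @param mode `"multivariate"` models every item jointly;
#'   `"univariate"` collapses visits to the total score and models it as a
#'   single pseudo-item (visits with any missing item are dropped).
#' @return A `posterior_samples` object: pooled population draw matrix,
#'   per-subject xi/tau draw matrices, chain index, acceptance rates, the
#'   posterior-median `population_params` (`pop_hat`), and the
#'   configuration and seed used.
#' @export
fit <- function(cohort, config = mcmc_config(), mode = c("multivariate",
                                                          "univariate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "sara_cohort"), inherits(config, "mcmc_config"))
  if (mode == "univariate" && length(cohort$scale$items) > 1L) {
    cohort <- collapse_to_total(cohort)
  }
  scale <- cohort$scale
  obs <- flatten_observations(cohort)
  subjects <- unique(cohort$visits$subject_id)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  maxima <- unname(scale$items)[obs$item]
  if (all(obs$level == 0L) || all(obs$level == maxima)) {
    stop("non-identifiable cohort: all scores constant at a scale bound")
  }
  if (length(unique(obs$level)) < 2L) {
    stop("non-identifiable cohort: scores show no variation")
  }
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    local_seed(child_seed(config$seed, ch),
               run_chain(cohort, obs, subjects, config, chain_id = ch))
  })
  pool <- function(field) do.call(rbind, lapply(chains, `[[`, field))
  population <- pool("population")
  xi <- pool("xi"); tau <- pool("tau")
  chain_id <- rep(seq_len(config$n_chains),
                  each = config$n_samples)
  acc <- Reduce(`+`, lapply(chains, `[[`, "acceptance")) / length(chains)
  samples <- structure(
    list(population = population, xi = xi, tau = tau,
         chain = chain_id, acceptance = acc,
         subjects = subjects, scale = scale, mode = mode,
         config = config, seed = config$seed),
    class = "posterior_samples")
  samples$pop_hat <- posterior_median_params(samples)
  samples
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "<posterior_samples> %s model, scale %s: %d draws (%d chains), %d subjects\n",
    x$mode, x$scale$name, nrow(x$population), x$config$n_chains,
    length(x$subjects)))
  cat("acceptance rates:",
      paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

# Collapse a multi-item cohort to its total score as one pseudo-item.
collapse_to_total <- function(cohort) {
  v <- cohort$visits
  total <- sum_score(v[names(cohort$scale$items)], cohort$scale)
  keep <- !is.na(total)
  tot_scale <- total_score_scale(cohort$scale$maximum,
                                 paste0(cohort$scale$name, "-total"))
  df <- data.frame(subject_id = v$subject_id[keep], age = v$age[keep],
                   total = total[keep], stringsAsFactors = FALSE)
  for (col in c("sca_type", "sex", "cag", "cohort", "continent")) {
    if (col %in% names(v)) df[[col]] <- v[[col]][keep]
  }
  suppressMessages(as_cohort(df, tot_scale))
}

# One MCMC-SAEM chain.  Returns draw matrices for the retained iterations.
run_chain <- function(cohort, obs, subjects, config, chain_id) {
  scale <- cohort$scale
  items <- names(scale$items)
  n <- length(subjects)
  si <- match(obs$subject_id, subjects)
  obs_by_item <- split(seq_len(nrow(obs)), obs$item)

  init <- initialize_state(cohort, obs, subjects)
  log_deltas <- lapply(init$deltas, log)
  offsets <- init$offsets
  log_steep <- log(init$steepness)
  tau_pop <- init$tau_pop; sigma_tau <- init$sigma_tau
  sigma_xi <- init$sigma_xi
  xi <- rep(0, n); tau <- init$tau_i

  thresholds <- function() {
    lapply(seq_along(items), function(k) {
      cumsum(c(offsets[k], exp(log_deltas[[k]])))
    })
  }
  steep_vec <- function() exp(log_steep)

  thr <- thresholds(); sv <- steep_vec()
  psi <- exp(xi)[si] * (obs$age - tau[si])
  llvec <- obs_loglik(psi, obs, NULL, thresholds = thr, steep = sv)

  # adaptive proposal scales
  ps <- config$proposal_scales
  sc_delta <- lapply(log_deltas, function(v) rep(ps$delta, length(v)))
  sc_steep <- rep(ps$steepness, length(items))
  sc_off <- rep(ps$offset, length(items))
  sc_xi <- ps$xi; sc_tau <- ps$tau
  prior_sd <- 1e6

  n_iter <- config$n_burnin + config$n_samples
  half_burn <- config$n_burnin %/% 2L
  adapt_win <- 40L
  acc_cnt <- c(xi = 0, tau = 0, delta = 0, steepness = 0, offset = 0)
  try_cnt <- c(xi = 0, tau = 0, delta = 0, steepness = 0, offset = 0)
  win_acc <- list(delta = lapply(sc_delta, function(v) numeric(length(v))),
                  steep = numeric(length(items)),
                  off = numeric(length(items)), xi = 0, tau = 0)

  pop_names <- c(
    unlist(lapply(seq_along(items), function(k) {
      sprintf("delta[%s,%d]", items[k], seq_along(log_deltas[[k]]))
    })),
    sprintf("offset[%s]", items),
    sprintf("steepness[%s]", items),
    "tau_pop", "sigma_tau", "sigma_xi")
  keep_pop <- matrix(NA_real_, config$n_samples, length(pop_names),
                     dimnames = list(NULL, pop_names))
  keep_xi <- matrix(NA_real_, config$n_samples, n,
                    dimnames = list(NULL, subjects))
  keep_tau <- keep_xi

  for (iter in seq_len(n_iter)) {
    burnin <- iter <= config$n_burnin

    ## -- population parameters: per-delta Metropolis ---------------------
    for (k in seq_along(items)) {
      idx <- obs_by_item[[as.character(k)]]
      if (is.null(idx)) next
      obs_k <- obs[idx, , drop = FALSE]
      for (j in seq_along(log_deltas[[k]])) {
        prop <- log_deltas[[k]]
        prop[j] <- prop[j] + sc_delta[[k]][j] * stats::rnorm(1L)
        try_cnt["delta"] <- try_cnt["delta"] + 1
        if (abs(prop[j]) > 8) next  # delta support bounded in (e^-8, e^8) y
        thr_k <- cumsum(c(offsets[k], exp(prop)))
        new_ll <- obs_loglik(psi[idx], obs_k, NULL,
                             thresholds = rep(list(thr_k), k),
                             steep = sv)
        logr <- sum(new_ll) - sum(llvec[idx]) +
          stats::dnorm(prop[j], 0, prior_sd, log = TRUE) -
          stats::dnorm(log_deltas[[k]][j], 0, prior_sd, log = TRUE)
        if (log(stats::runif(1L)) < logr) {
          log_deltas[[k]] <- prop
          thr[[k]] <- thr_k
          llvec[idx] <- new_ll
          acc_cnt["delta"] <- acc_cnt["delta"] + 1
          win_acc$delta[[k]][j] <- win_acc$delta[[k]][j] + 1
        }
      }
      ## steepness
      prop_s <- log_steep
      prop_s[k] <- prop_s[k] + sc_steep[k] * stats::rnorm(1L)
      try_cnt["steepness"] <- try_cnt["steepness"] + 1
      if (abs(prop_s[k]) > 8) next
      sv_p <- exp(prop_s)
      new_ll <- obs_loglik(psi[idx], obs_k, NULL,
                           thresholds = rep(list(thr[[k]]), k),
                           steep = sv_p)
      logr <- sum(new_ll) - sum(llvec[idx]) +
        stats::dnorm(prop_s[k], 0, prior_sd, log = TRUE) -
        stats::dnorm(log_steep[k], 0, prior_sd, log = TRUE)
      if (log(stats::runif(1L)) < logr) {
        log_steep <- prop_s; sv <- exp(log_steep)
        llvec[idx] <- new_ll
        acc_cnt["steepness"] <- acc_cnt["steepness"] + 1
        win_acc$steep[k] <- win_acc$steep[k] + 1
      }
      ## onset offset (items after the first; >= 0)
      if (k > 1L) {
        off_p <- offsets[k] + sc_off[k] * stats::rnorm(1L)
        try_cnt["offset"] <- try_cnt["offset"] + 1
        if (off_p >= 0 && off_p <= 200) {
          thr_k <- cumsum(c(off_p, exp(log_deltas[[k]])))
          new_ll <- obs_loglik(psi[idx], obs_k, NULL,
                               thresholds = rep(list(thr_k), k),
                               steep = sv)
          logr <- sum(new_ll) - sum(llvec[idx]) +
            stats::dnorm(off_p, 0, prior_sd, log = TRUE) -
            stats::dnorm(offsets[k], 0, prior_sd, log = TRUE)
          if (log(stats::runif(1L)) < logr) {
            offsets[k] <- off_p
            thr[[k]] <- thr_k
            llvec[idx] <- new_ll
            acc_cnt["offset"] <- acc_cnt["offset"] + 1
            win_acc$off[k] <- win_acc$off[k] + 1
          }
        }
      }
    }

    ## -- individual parameters: vectorized per-subject Metropolis --------
    ll_subj <- subject_sums(llvec, si, n)
    ## xi block
    xi_p <- xi + sc_xi * stats::rnorm(n)
    psi_p <- exp(xi_p)[si] * (obs$age - tau[si])
    llvec_p <- obs_loglik(psi_p, obs, NULL, thresholds = thr, steep = sv)
    llp_subj <- subject_sums(llvec_p, si, n)
    logr <- (llp_subj - ll_subj) +
      stats::dnorm(xi_p, 0, sigma_xi, log = TRUE) -
      stats::dnorm(xi, 0, sigma_xi, log = TRUE)
    accept <- log(stats::runif(n)) < logr
    if (any(accept)) {
      xi[accept] <- xi_p[accept]
      swap <- accept[si]
      llvec[swap] <- llvec_p[swap]
      psi[swap] <- psi_p[swap]
      ll_subj[accept] <- llp_subj[accept]
    }
    acc_cnt["xi"] <- acc_cnt["xi"] + mean(accept)
    try_cnt["xi"] <- try_cnt["xi"] + 1
    win_acc$xi <- win_acc$xi + mean(accept)
    ## tau block
    tau_p <- tau + sc_tau * stats::rnorm(n)
    psi_p <- exp(xi)[si] * (obs$age - tau_p[si])
    llvec_p <- obs_loglik(psi_p, obs, NULL, thresholds = thr, steep = sv)
    llp_subj <- subject_sums(llvec_p, si, n)
    logr <- (llp_subj - ll_subj) +
      stats::dnorm(tau_p, tau_pop, sigma_tau, log = TRUE) -
      stats::dnorm(tau, tau_pop, sigma_tau, log = TRUE)
    accept <- log(stats::runif(n)) < logr
    if (any(accept)) {
      tau[accept] <- tau_p[accept]
      swap <- accept[si]
      llvec[swap] <- llvec_p[swap]
      psi[swap] <- psi_p[swap]
    }
    acc_cnt["tau"] <- acc_cnt["tau"] + mean(accept)
    try_cnt["tau"] <- try_cnt["tau"] + 1
    win_acc$tau <- win_acc$tau + mean(accept)

    ## -- identifiability: recentre xi, compensate in the time scale ------
    ## (warm-up only: the joint rescaling is likelihood-invariant, so in
    ## the sampling phase the mean-zero constraint is left to the xi prior
    ## and the chain remains a valid MCMC)
    m <- if (burnin) mean(xi) else 0
    if (m != 0) {
      xi <- xi - m
      fac <- exp(-m)
      log_deltas <- lapply(log_deltas, function(v) v - m)
      offsets <- offsets * fac
      log_steep <- log_steep - m
      thr <- lapply(thr, function(v) v * fac)
      sv <- exp(log_steep)
      psi <- fac * psi   # llvec invariant under the joint rescaling
    }

    ## -- stochastic approximation of hyperparameters (warm-up only) ------
    ## Frozen for the first quarter of the warm-up so the individual draws
    ## can disperse before their empirical spread is trusted (otherwise
    ## sigma_xi collapses onto the initial point mass and pins xi at 0).
    if (burnin) {
      if (iter > config$n_burnin %/% 4L) {
        g <- if (iter <= half_burn) 0.5 else
          (iter - half_burn)^(-config$saem_exponent)
        tau_pop <- (1 - g) * tau_pop + g * mean(tau)
        sigma_tau <- sqrt(max((1 - g) * sigma_tau^2 +
                                g * mean((tau - tau_pop)^2), 0.5^2))
        sigma_xi <- sqrt(max((1 - g) * sigma_xi^2 + g * mean(xi^2), 0.05^2))
      }
      ## proposal adaptation in windows, warm-up only
      if (iter %% adapt_win == 0L) {
        tune <- function(scale, rate, cap = 2) {
          pmin(pmax(scale * exp(rate - 0.3), 1e-4), cap)
        }
        for (k in seq_along(items)) {
          sc_delta[[k]] <- tune(sc_delta[[k]],
                                win_acc$delta[[k]] / adapt_win)
          win_acc$delta[[k]][] <- 0
        }
        sc_steep <- tune(sc_steep, win_acc$steep / adapt_win)
        sc_off <- tune(sc_off, win_acc$off / adapt_win, cap = 5)
        sc_xi <- tune(sc_xi, win_acc$xi / adapt_win)
        sc_tau <- tune(sc_tau, win_acc$tau / adapt_win, cap = 8)
        win_acc$steep[] <- 0; win_acc$off[] <- 0
        win_acc$xi <- 0; win_acc$tau <- 0
        acc_cnt[] <- 0; try_cnt[] <- 0   # report sampling-phase rates
      }
    } else {
      ## sampling phase: Gibbs draws of the hyperparameters (conjugate
      ## updates under flat/Jeffreys priors) so their uncertainty
      ## propagates into the population posteriors
      tau_pop <- stats::rnorm(1L, mean(tau), sigma_tau / sqrt(n))
      sigma_tau <- sqrt(max(sum((tau - tau_pop)^2) /
                              stats::rchisq(1L, n - 1L), 0.5^2))
      sigma_xi <- sqrt(max(sum(xi^2) / stats::rchisq(1L, n), 0.05^2))
      s <- iter - config$n_burnin
      keep_pop[s, ] <- c(exp(unlist(log_deltas)), offsets, exp(log_steep),
                         tau_pop, sigma_tau, sigma_xi)
      keep_xi[s, ] <- xi
      keep_tau[s, ] <- tau
    }
    if (any(!is.finite(llvec))) stop("NaN in likelihood during sampling")
  }

  list(population = keep_pop, xi = keep_xi, tau = keep_tau,
       acceptance = acc_cnt / pmax(try_cnt, 1))
}

subject_sums <- function(x, si, n) {
  out <- numeric(n)
  agg <- rowsum(x, si)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Crude data-driven initialization: pooled total-score slope gives the
# time-scale of progression; per-subject intercepts give start ages.
initialize_state <- function(cohort, obs, subjects) {
  scale <- cohort$scale
  v <- cohort$visits
  total <- rowSums(as.matrix(v[names(scale$items)]), na.rm = TRUE)
  slopes <- unlist(lapply(split(seq_len(nrow(v)), v$subject_id), function(i) {
    if (length(i) < 2L) return(NULL)
    a <- v$age[i]; t <- total[i]
    if (stats::var(t) == 0) return(NULL)
    stats::cov(a, t) / stats::var(a)
  }))
  b <- if (length(slopes)) max(stats::median(slopes), 0.05) else 0.5
  course_years <- scale$maximum / b
  ## spread each item's full course over the scale's overall time span
  deltas <- lapply(seq_along(scale$items), function(k) {
    rep(course_years / scale$items[[k]], scale$items[[k]] - 1L)
  })
  names(deltas) <- names(scale$items)
  tau_i <- unlist(lapply(split(seq_len(nrow(v)), v$subject_id), function(i) {
    a <- v$age[i]; t <- total[i]
    if (t[1L] > 0) a[1L] - t[1L] / b else {
      nz <- which(t > 0)
      if (length(nz)) a[nz[1L]] else a[length(a)] + 2
    }
  }))
  tau_i <- tau_i[subjects]
  offsets <- stats::setNames(c(0, rep(1, length(scale$items) - 1L)),
                             names(scale$items))
  d0 <- min(unlist(deltas))
  list(deltas = deltas, offsets = offsets,
       steepness = stats::setNames(rep(max(0.3 * d0, 0.1),
                                       length(scale$items)),
                                   names(scale$items)),
       tau_pop = mean(tau_i),
       sigma_tau = max(stats::sd(tau_i), 1),
       sigma_xi = 0.3,
       tau_i = tau_i)
}

#' Posterior-median population parameters
#'
#' @param samples A `posterior_samples` object.
#' @return A `population_params` built from the per-parameter posterior
#'   medians (deltas, offsets, steepness, hyperparameters).
#' @export
posterior_median_params <- function(samples) {
  med <- apply(samples$population, 2L, stats::median)
  items <- names(samples$scale$items)
  deltas <- lapply(seq_along(items), function(k) {
    unname(med[sprintf("delta[%s,%d]", items[k],
                       seq_len(samples$scale$items[[k]] - 1L))])
  })
  names(deltas) <- items
  population_params(
    deltas = deltas,
    offsets = stats::setNames(unname(med[sprintf("offset[%s]", items)]),
                              items),
    steepness = stats::setNames(unname(med[sprintf("steepness[%s]", items)]),
                                items),
    tau_pop = unname(med["tau_pop"]),
    sigma_tau = unname(med["sigma_tau"]),
    sigma_xi = unname(med["sigma_xi"]),
    scale = samples$scale)
}

#' Delta draw matrix for one item
#'
#' @param samples A `posterior_samples` object.
#' @param item Item name or index.
#' @return Matrix of retained draws (rows) by level durations (columns).
#' @export
delta_draws <- function(samples, item) {
  items <- names(samples$scale$items)
  k <- if (is.character(item)) match(item, items) else item
  if (is.na(k)) stop("unknown item: ", item)
  cols <- sprintf("delta[%s,%d]", items[k],
                  seq_len(samples$scale$items[[k]] - 1L))
  samples$population[, cols, drop = FALSE]
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early and a late segment of a chain,
#' standardized by spectral-density-at-zero variance estimates (AR-fit
#' estimator) of each segment; |z| < 2 is conventionally read as
#' consistent with convergence.
#'
#' @param chain Numeric vector of draws of one scalar parameter.
#' @param first_frac Fraction of the chain in the early segment.
#' @param last_frac Fraction in the late segment.
#' @return A list with `z`, segment means, and `converged` (|z| < 2).
#' @export
geweke <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 100L) stop("chain too short for a Geweke diagnostic (need >= 100)")
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("constant chain segment: Geweke variance undefined")
  }
  s0 <- function(x) {
    fit <- stats::ar(x, aic = TRUE,
                     order.max = min(20L, length(x) - 1L),
                     demean = TRUE)
    v <- fit$var.pred / (1 - sum(fit$ar))^2
    if (!is.finite(v) || v <= 0) stats::var(x) else v
  }
  z <- (mean(a) - mean(b)) / sqrt(s0(a) / length(a) + s0(b) / length(b))
  list(z = z, mean_first = mean(a), mean_last = mean(b),
       converged = abs(z) < 2)
}

#' Personalize the model to a new subject
#'
#' With population parameters fixed, finds the posterior mode of (xi, tau)
#' for one subject's visits — maximizing the observation log-likelihood
#' plus the Gaussian priors N(0, sigma_xi) and N(tau_pop, sigma_tau) — and
#' draws from the conditional posterior by random-walk Metropolis.
#'
#' @param visits Data frame of the subject's visits (`age` plus item
#'   columns of the scale), or a one-subject `sara_cohort`.
#' @param pop A `population_params`.
#' @param n_draws Number of retained Metropolis draws.
#' @param n_burnin Discarded draws.
#' @param seed Integer seed.
#' @return List with `xi`, `tau` (posterior modes), `draws` (matrix with
#'   columns xi, tau), and `logpost` at the mode.
#' @export
personalize <- function(visits, pop, n_draws = 500L, n_burnin = 200L,
                        seed = 1L) {
  if (inherits(visits, "sara_cohort")) visits <- visits$visits
  visits <- as.data.frame(visits)
  if (!"subject_id" %in% names(visits)) visits$subject_id <- "subject"
  if (length(unique(visits$subject_id)) != 1L) {
    stop("personalize expects visits from a single subject")
  }
  cohort <- suppressMessages(as_cohort(visits, pop$scale))
  obs <- flatten_observations(cohort)
  if (nrow(obs) == 0L) stop("no non-missing observations")
  thr <- lapply(names(pop$scale$items), function(it) {
    item_thresholds(pop, it)
  })
  sv <- unname(unlist(pop$steepness))
  logpost <- function(par) {
    psi <- exp(par[1L]) * (obs$age - par[2L])
    sum(obs_loglik(psi, obs, NULL, thresholds = thr, steep = sv)) +
      stats::dnorm(par[1L], 0, pop$sigma_xi, log = TRUE) +
      stats::dnorm(par[2L], pop$tau_pop, pop$sigma_tau, log = TRUE)
  }
  opt <- stats::optim(c(0, pop$tau_pop), function(p) -logpost(p),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-10))
  draws <- local_seed(seed, {
    par <- opt$par
    lp <- logpost(par)
    sc <- c(0.3, 1.5)
    out <- matrix(NA_real_, n_draws, 2L,
                  dimnames = list(NULL, c("xi", "tau")))
    for (it in seq_len(n_burnin + n_draws)) {
      prop <- par + sc * stats::rnorm(2L)
      lp_p <- logpost(prop)
      if (log(stats::runif(1L)) < lp_p - lp) {
        par <- prop; lp <- lp_p
      }
      if (it > n_burnin) out[it - n_burnin, ] <- par
    }
    out
  })
  list(xi = opt$par[1L], tau = opt$par[2L], draws = draws,
       logpost = -opt$value)
}

#' Persist posterior samples to a directory
#'
#' Writes `population.csv` (one row per retained draw), `individual_xi.csv`
#' and `individual_tau.csv` (one column per subject), `config.json`
#' (configuration, seed, mode, scale) and `diagnostics.json` (acceptance
#' rates and Geweke z per population parameter, first chain).
#'
#' @param samples A `posterior_samples` object.
#' @param dir Output directory (created if needed).
#' @export
write_posterior <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(samples$population),
                   file.path(dir, "population.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(samples$xi),
                   file.path(dir, "individual_xi.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(samples$tau),
                   file.path(dir, "individual_tau.csv"), row.names = FALSE)
  first <- samples$chain == 1L
  gw <- vapply(colnames(samples$population), function(p) {
    ch <- samples$population[first, p]
    if (length(ch) >= 100L && stats::var(ch) > 0) {
      tryCatch(geweke(ch)$z, error = function(e) NA_real_)
    } else NA_real_
  }, numeric(1L))
  jsonlite::write_json(
    list(config = unclass(samples$config), seed = samples$seed,
         mode = samples$mode,
         scale = list(name = samples$scale$name,
                      items = as.list(samples$scale$items)),
         chain = samples$chain),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(acceptance = as.list(samples$acceptance),
         geweke_z = as.list(gw)),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read posterior samples from a directory written by [write_posterior()]
#'
#' @param dir Directory path.
#' @return A `posterior_samples` object.
#' @export
read_posterior <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  diag <- jsonlite::read_json(file.path(dir, "diagnostics.json"),
                              simplifyVector = TRUE)
  population <- as.matrix(utils::read.csv(file.path(dir, "population.csv"),
                                          check.names = FALSE))
  xi <- as.matrix(utils::read.csv(file.path(dir, "individual_xi.csv"),
                                  check.names = FALSE))
  tau <- as.matrix(utils::read.csv(file.path(dir, "individual_tau.csv"),
                                   check.names = FALSE))
  scale <- scale_definition(meta$scale$name, unlist(meta$scale$items))
  cfg <- mcmc_config(n_burnin = meta$config$n_burnin,
                     n_samples = meta$config$n_samples,
                     n_chains = meta$config$n_chains,
                     proposal_scales = meta$config$proposal_scales,
                     saem_exponent = meta$config$saem_exponent,
                     seed = meta$config$seed,
                     profile = meta$config$profile)
  samples <- structure(
    list(population = population, xi = xi, tau = tau,
         chain = as.integer(meta$chain),
         acceptance = unlist(diag$acceptance),
         subjects = colnames(xi), scale = scale, mode = meta$mode,
         config = cfg, seed = meta$config$seed),
    class = "posterior_samples")
  samples$pop_hat <- posterior_median_params(samples)
  samples
}
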