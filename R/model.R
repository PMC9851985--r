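#' Population parameters of the ordinal disease-course model
#'
#' The model describes each scale item as an ordered sequence of logistic
#' exceedance curves on a common population disease clock.  For item k with
#' maximum level \eqn{L_k}, the thresholds are cumulative level durations:
#' \deqn{c_{k,1} = \theta_k, \quad c_{k,l+1} = c_{k,l} + \delta_{k,l}}
#' where \eqn{\delta_{k,l} > 0} is the average time in years spent at level
#' l before moving to l+1, and \eqn{\theta_k \ge 0} is the delay from the
#' individual start of progression to the first point on item k (0 for the
#' first item, so the start of progression is the age at which the first
#' item moves from 0 to 1).
#'
#' @param deltas Named list (one element per item, in scale order) of
#'   positive numeric vectors; element k holds the \eqn{L_k - 1} durations
#'   for levels \eqn{1..L_k - 1} of that item.
#' @param offsets Named numeric vector of onset offsets \eqn{\theta_k}
#'   (years, >= 0; first item must be 0).  Defaults to all zero.
#' @param steepness Named positive numeric vector of transition widths
#'   \eqn{s_k} (years).  Smaller values make level changes sharper.
#' @param tau_pop Population mean start-of-progression age (years).
#' @param sigma_tau SD of individual start-of-progression ages (years).
#' @param sigma_xi SD of the individual log acceleration factors.
#' @param scale The `scale_definition` the parameters refer to.
#' @return An object of class `population_params`.
#' @export
population_params <- function(deltas, offsets = NULL, steepness = NULL,
                              tau_pop, sigma_tau, sigma_xi,
                              scale) {
  stopifnot(inherits(scale, "scale_definition"))
  items <- names(scale$items)
  if (!identical(sort(names(deltas)), sort(items))) {
    stop("deltas must be a named list covering every scale item")
  }
  deltas <- deltas[items]
  for (k in seq_along(items)) {
    lk <- scale$items[[k]]
    dk <- deltas[[k]]
    if (length(dk) != lk - 1L) {
      stop(sprintf("item '%s' needs %d deltas (levels 1..%d), got %d",
                   items[k], lk - 1L, lk - 1L, length(dk)))
    }
    if (any(!is.finite(dk)) || any(dk <= 0)) {
      stop(sprintf("deltas for item '%s' must be strictly positive",
                   items[k]))
    }
  }
  if (is.null(offsets)) offsets <- stats::setNames(rep(0, length(items)), items)
  offsets <- offsets[items]
  if (any(!is.finite(offsets)) || any(offsets < 0) || offsets[[1L]] != 0) {
    stop("offsets must be >= 0 with the first item fixed at 0")
  }
  if (is.null(steepness)) {
    s0 <- 0.3 * min(unlist(deltas))
    steepness <- stats::setNames(rep(s0, length(items)), items)
  }
  steepness <- steepness[items]
  if (any(!is.finite(steepness)) || any(steepness <= 0)) {
    stop("steepness must be strictly positive")
  }
  stopifnot(is.finite(tau_pop), sigma_tau > 0, sigma_xi > 0)
  structure(
    list(deltas = deltas, offsets = offsets, steepness = steepness,
         tau_pop = tau_pop, sigma_tau = sigma_tau, sigma_xi = sigma_xi,
         scale = scale),
    class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population_params> scale %s, tau_pop %.1f y (sigma_tau %.2f), sigma_xi %.2f\n",
              x$scale$name, x$tau_pop, x$sigma_tau, x$sigma_xi))
  for (item in names(x$deltas)) {
    cat(sprintf("  %s: mean delta %.2f y, offset %.2f, steepness %.2f\n",
                item, mean(x$deltas[[item]]), x$offsets[[item]],
                x$steepness[[item]]))
  }
  invisible(x)
}

# Threshold vector c_{k,1..L_k} for one item.
item_thresholds <- function(pop, item) {
  k <- if (is.character(item)) item else names(pop$scale$items)[item]
  cumsum(c(pop$offsets[[k]], pop$deltas[[k]]))
}

#' Individual parameters
#'
#' Two numbers characterise each subject: `xi`, the log acceleration factor
#' (exp(xi) multiplies the population progression speed; population mean 0
#' by the identifiability constraint), and `tau`, the start-of-progression
#' age in years.
#'
#' @param xi Log acceleration factor.
#' @param tau Start-of-progression age (years).
#' @return An object of class `individual_params`.
#' @export
individual_params <- function(xi, tau) {
  stopifnot(is.finite(xi), is.finite(tau))
  structure(list(xi = xi, tau = tau), class = "individual_params")
}

#' Individual-to-population time reparameterization
#'
#' Maps a subject's age onto the population disease clock:
#' \eqn{\psi = e^{\xi}(t - \tau)}.  Negative values precede the subject's
#' start of progression.
#'
#' @param age Age(s) in years.
#' @param ind An `individual_params` object (or list with `xi`, `tau`).
#' @return Reparameterized time(s) in years on the population clock.
#' @export
reparameterize <- function(age, ind) {
  exp(ind$xi) * (age - ind$tau)
}

#' Exceedance probability of a score level
#'
#' \eqn{P(Y_k \ge l \mid \psi) = \mathrm{logistic}((\psi - c_{k,l})/s_k)};
#' strictly increasing in psi and decreasing in the level.
#'
#' @param psi Reparameterized time(s), years.
#' @param item Item name or index.
#' @param level Level l in 1..L_k.
#' @param pop A `population_params` object.
#' @return Probability vector the length of `psi`.
#' @export
exceedance <- function(psi, item, level, pop) {
  cc <- item_thresholds(pop, item)
  if (level < 1L || level > length(cc)) {
    stop(sprintf("level %d out of range 1..%d", level, length(cc)))
  }
  k <- if (is.character(item)) item else names(pop$scale$items)[item]
  stats::plogis((psi - cc[level]) / pop$steepness[[k]])
}

#' Probability distribution over an item's levels
#'
#' Adjacent differences of the exceedance curves:
#' \eqn{P(Y=l) = P(Y \ge l) - P(Y \ge l+1)} with \eqn{P(Y\ge0)=1} and
#' \eqn{P(Y \ge L_k + 1) = 0}.  Rows are non-negative and sum to one.
#'
#' @inheritParams exceedance
#' @return If `psi` has length one, a probability vector over levels
#'   0..L_k; otherwise a matrix with one row per psi.
#' @export
level_distribution <- function(psi, item, pop) {
  k <- if (is.character(item)) item else names(pop$scale$items)[item]
  cc <- item_thresholds(pop, k)
  s <- pop$steepness[[k]]
  ge <- cbind(1, stats::plogis(outer(psi, cc, "-") / s), 0)
  p <- ge[, seq_len(ncol(ge) - 1L), drop = FALSE] - ge[, -1L, drop = FALSE]
  colnames(p) <- as.character(0:length(cc))
  if (length(psi) == 1L) p[1L, ] else p
}

#' Most likely level at a time point
#'
#' Argmax of [level_distribution()]; ties break toward the lower level, and
#' the result is a non-decreasing step function of psi.
#'
#' @inheritParams level_distribution
#' @return Integer level(s) in 0..L_k.
#' @export
most_likely_level <- function(psi, item, pop) {
  p <- level_distribution(psi, item, pop)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  as.integer(max.col(p, ties.method = "first") - 1L)
}

#' Population-average trajectory
#'
#' The idealized course of a typical subject (`xi = 0`,
#' `tau = tau_pop`): per-item most likely level along an age grid, plus the
#' total-score curve.
#'
#' @param ages Sorted numeric vector of ages (years).
#' @param pop A `population_params` object.
#' @return Data frame with `age`, one column per item, and `total`.
#' @export
population_trajectory <- function(ages, pop) {
  stopifnot(!is.unsorted(ages))
  ind <- individual_params(0, pop$tau_pop)
  psi <- reparameterize(ages, ind)
  out <- data.frame(age = ages)
  for (item in names(pop$scale$items)) {
    out[[item]] <- most_likely_level(psi, item, pop)
  }
  out$total <- as.integer(rowSums(out[names(pop$scale$items)]))
  out
}

#' Observation log-likelihood of a cohort
#'
#' Sum over all non-missing item observations of the log probability of the
#' observed level under [level_distribution()] at each subject's
#' reparameterized visit times.  Missing entries contribute zero, making
#' the likelihood robust to per-item missingness.
#'
#' @param cohort A `sara_cohort`.
#' @param pop A `population_params` for the cohort's scale.
#' @param inds Data frame with columns `subject_id`, `xi`, `tau` covering
#'   every subject.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(cohort, pop, inds) {
  obs <- flatten_observations(cohort)
  if (nrow(obs) == 0L) return(0)
  idx <- match(obs$subject_id, inds$subject_id)
  if (anyNA(idx)) {
    stop("individual parameters missing for subject ",
         obs$subject_id[which(is.na(idx))[1L]])
  }
  psi <- exp(inds$xi[idx]) * (obs$age - inds$tau[idx])
  sum(obs_loglik(psi, obs, pop))
}

# Long table of non-missing single-item observations:
# subject_id, age, item (index), level.
flatten_observations <- function(cohort) {
  v <- cohort$visits
  items <- names(cohort$scale$items)
  pieces <- lapply(seq_along(items), function(k) {
    keep <- which(!is.na(v[[items[k]]]))
    data.frame(subject_id = v$subject_id[keep], age = v$age[keep],
               item = rep.int(k, length(keep)),
               level = v[[items[k]]][keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# Per-observation log P(Y = level | psi), vectorized over a flat
# observation table.  Uses only the two bracketing thresholds per
# observation; probabilities are floored to keep logs finite.
obs_loglik <- function(psi, obs, pop, thresholds = NULL, steep = NULL) {
  if (is.null(thresholds)) {
    thresholds <- lapply(names(pop$scale$items), function(it) {
      item_thresholds(pop, it)
    })
  }
  if (is.null(steep)) steep <- unname(unlist(pop$steepness))
  lo <- hi <- numeric(length(psi))
  s <- steep[obs$item]
  for (k in unique(obs$item)) {
    sel <- obs$item == k
    cc <- thresholds[[k]]
    y <- obs$level[sel]
    lmax <- length(cc)
    if (any(y < 0L | y > lmax)) stop("observation exceeds item maximum")
    lo[sel] <- ifelse(y == 0L, -Inf, cc[pmax(y, 1L)])
    hi[sel] <- ifelse(y == lmax, Inf, cc[pmin(y + 1L, lmax)])
  }
  p <- stats::plogis((psi - lo) / s) - stats::plogis((psi - hi) / s)
  log(pmax(p, 1e-300))
}

#' Write population parameters to JSON
#'
#' Field names and units are explicit: deltas, offsets and steepness in
#' years per item, `tau_pop`/`sigma_tau` in years, `sigma_xi` on the log
#' scale, plus the scale definition for round-tripping.
#'
#' @param pop A `population_params` object.
#' @param path Output path.
#' @export
write_population_params <- function(pop, path) {
  obj <- list(
    scale = list(name = pop$scale$name,
                 items = as.list(pop$scale$items)),
    deltas_years = lapply(pop$deltas, as.numeric),
    offsets_years = as.list(pop$offsets),
    steepness_years = as.list(pop$steepness),
    tau_pop_years = pop$tau_pop,
    sigma_tau_years = pop$sigma_tau,
    sigma_xi_log = pop$sigma_xi)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read population parameters from JSON
#'
#' @param path Path written by [write_population_params()].
#' @return A `population_params` object.
#' @export
read_population_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scale <- scale_definition(obj$scale$name, unlist(obj$scale$items))
  population_params(
    deltas = lapply(obj$deltas_years, as.numeric),
    offsets = unlist(obj$offsets_years),
    steepness = unlist(obj$steepness_years),
    tau_pop = obj$tau_pop_years,
    sigma_tau = obj$sigma_tau_years,
    sigma_xi = obj$sigma_xi_log,
    scale = scale)
}
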