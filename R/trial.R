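#' Define a two-arm trial scenario
#'
#' Change-score design: both arms are followed for `duration_months`, the
#' endpoint is the change in total score, the placebo arm progresses by
#' `placebo_mean_change` points (SD `sd_change`), and treatment removes a
#' fraction `effect_fraction` of that progression.
#'
#' @param placebo_mean_change Mean placebo-arm change in points (e.g. 1.08
#'   SARA points over 12 months).
#' @param sd_change SD of the change score in points (common to both arms).
#' @param effect_fraction Fraction of progression removed by treatment
#'   (0 < f <= 1); 0.5 is the conventional 50% slowing.
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @param duration_months Trial duration (descriptive; the change
#'   statistics must already refer to this horizon).
#' @param allocation Allocation ratio treated:placebo (only 1 supported).
#' @return A list of class `trial_scenario`.
#' @export
trial_scenario <- function(placebo_mean_change, sd_change,
                           effect_fraction = 0.5, alpha = 0.05,
                           power = 0.90, duration_months = 12,
                           allocation = 1) {
  stopifnot(sd_change > 0, effect_fraction > 0, effect_fraction <= 1,
            alpha > 0, alpha < 1, power > alpha, power < 1,
            duration_months > 0)
  if (allocation != 1) stop("only 1:1 allocation is supported")
  structure(list(placebo_mean_change = placebo_mean_change,
                 sd_change = sd_change,
                 effect_fraction = effect_fraction,
                 alpha = alpha, power = power,
                 duration_months = duration_months,
                 allocation = allocation),
            class = "trial_scenario")
}

#' Sample size for a two-arm change-score trial
#'
#' Normal-approximation (z) formula for a two-sided two-sample comparison
#' of means with equal arms:
#' \deqn{n_{arm} = \lceil (z_{1-\alpha/2} + z_{power})^2 \,
#'   2\sigma^2 / (f\,\mu)^2 \rceil}
#' where \eqn{\mu} is the placebo mean change, \eqn{\sigma} its SD and
#' \eqn{f} the treatment effect fraction.
#'
#' @param scenario A `trial_scenario`.
#' @return List of class `sample_size_result`: `n_per_arm`, `n_total`.
#' @export
sample_size <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  diff <- scenario$effect_fraction * scenario$placebo_mean_change
  if (diff == 0) stop("zero treatment effect: required sample size is infinite")
  z <- stats::qnorm(1 - scenario$alpha / 2) + stats::qnorm(scenario$power)
  n_arm <- ceiling(z^2 * 2 * scenario$sd_change^2 / diff^2)
  structure(list(n_per_arm = as.integer(n_arm),
                 n_total = as.integer(2L * n_arm)),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("n = %d per arm (%d total)\n", x$n_per_arm, x$n_total))
  invisible(x)
}

#' Monte-Carlo power of a two-arm z-test
#'
#' Simulates `n_sims` trials with normally distributed change scores whose
#' arm means differ by `mean_diff` (common SD `sd`) and reports the fraction
#' rejecting a two-sided two-sample z-test (pooled-SD estimate, normal
#' critical value) at level `alpha`.  Deterministic given the seed.
#'
#' @param n_per_arm Subjects per arm (>= 2).
#' @param mean_diff Difference between arm means, in points.
#' @param sd Common SD of the change score.
#' @param alpha Two-sided level.
#' @param n_sims Number of simulated trials.
#' @param seed Integer seed.
#' @return Proportion of significant trials.
#' @export
empirical_power <- function(n_per_arm, mean_diff, sd, alpha = 0.05,
                            n_sims = 20000L, seed = 1L) {
  stopifnot(n_per_arm >= 2L, sd > 0, n_sims >= 1L)
  local_seed(seed, {
    crit <- stats::qnorm(1 - alpha / 2)
    reject <- logical(n_sims)
    block <- 2000L  # simulate in blocks to bound memory
    done <- 0L
    while (done < n_sims) {
      b <- min(block, n_sims - done)
      x <- matrix(stats::rnorm(b * n_per_arm, mean = mean_diff, sd = sd),
                  nrow = b)
      y <- matrix(stats::rnorm(b * n_per_arm, mean = 0, sd = sd), nrow = b)
      mx <- rowMeans(x); my <- rowMeans(y)
      vx <- (rowSums(x^2) - n_per_arm * mx^2) / (n_per_arm - 1L)
      vy <- (rowSums(y^2) - n_per_arm * my^2) / (n_per_arm - 1L)
      se <- sqrt((vx + vy) / n_per_arm)
      reject[done + seq_len(b)] <- abs(mx - my) / se > crit
      done <- done + b
    }
    mean(reject)
  })
}

#' Sample-size grid over groups, scale variants and inclusion windows
#'
#' One sample-size computation per combination of subject group, scale
#' variant and baseline-score inclusion window.  Change statistics (mean
#' and SD of the change over the trial horizon) are supplied per cell —
#' either directly, or derived from per-subject change scores filtered by
#' baseline total score within the closed window.
#'
#' @param change_stats Data frame with columns `group`, `variant`, and
#'   either `mean` + `sd`, or list-columns are not supported — supply
#'   per-cell statistics, one row per (group, variant).
#' @param windows Named list of inclusion windows, each `c(lo, hi)` on the
#'   baseline total score; statistics for a window must be supplied via
#'   `filtered_stats` or computed upstream.  When `change_data` is given
#'   (per-subject `group`, `variant`, `baseline`, `change`), the window
#'   filter and the mean/SD are computed here.
#' @param change_data Optional per-subject data frame (`group`, `variant`,
#'   `baseline`, `change`); supersedes `change_stats`.
#' @param scenario_args Further arguments passed to [trial_scenario()]
#'   (effect fraction, alpha, power, duration).
#' @return Data frame: `group`, `variant`, `window`, `mean_change`,
#'   `sd_change`, `n_excluded`, `n_per_arm`, `n_total`.
#' @export
scenario_grid <- function(change_stats = NULL, windows = list(all = NULL),
                          change_data = NULL, scenario_args = list()) {
  if (is.null(change_stats) && is.null(change_data)) {
    stop("supply change_stats or change_data")
  }
  rows <- list()
  size_for <- function(mu, sdv, group, variant, win_name, n_excluded) {
    sc <- do.call(trial_scenario,
                  c(list(placebo_mean_change = mu, sd_change = sdv),
                    scenario_args))
    n <- sample_size(sc)
    data.frame(group = group, variant = variant, window = win_name,
               mean_change = mu, sd_change = sdv, n_excluded = n_excluded,
               n_per_arm = n$n_per_arm, n_total = n$n_total,
               stringsAsFactors = FALSE)
  }
  if (!is.null(change_data)) {
    cells <- unique(change_data[c("group", "variant")])
    for (i in seq_len(nrow(cells))) {
      cell <- change_data[change_data$group == cells$group[i] &
                            change_data$variant == cells$variant[i], ]
      for (win_name in names(windows)) {
        w <- windows[[win_name]]
        keep <- if (is.null(w)) rep(TRUE, nrow(cell)) else {
          cell$baseline >= w[1L] & cell$baseline <= w[2L]
        }
        sub <- cell[keep, , drop = FALSE]
        if (nrow(sub) < 2L) {
          stop(sprintf("window '%s' leaves fewer than 2 subjects in cell %s/%s",
                       win_name, cells$group[i], cells$variant[i]))
        }
        rows[[length(rows) + 1L]] <- size_for(
          mean(sub$change), stats::sd(sub$change),
          cells$group[i], cells$variant[i], win_name,
          n_excluded = sum(!keep))
      }
    }
  } else {
    for (i in seq_len(nrow(change_stats))) {
      for (win_name in names(windows)) {
        rows[[length(rows) + 1L]] <- size_for(
          change_stats$mean[i], change_stats$sd[i],
          change_stats$group[i], change_stats$variant[i], win_name,
          n_excluded = NA_integer_)
      }
    }
  }
  do.call(rbind, rows)
}
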