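#' Summarize level-duration posteriors
#'
#' Median and equal-tailed 95% credible interval of every delta (years
#' spent at each level), from the pooled retained draws.
#'
#' @param samples A `posterior_samples` object (>= 100 retained draws).
#' @return Data frame: `item`, `level`, `median`, `ci_low`, `ci_high`.
#' @export
summarize_deltas <- function(samples) {
  if (nrow(samples$population) < 100L) {
    stop("need at least 100 retained draws")
  }
  items <- names(samples$scale$items)
  do.call(rbind, lapply(seq_along(items), function(k) {
    d <- delta_draws(samples, k)
    do.call(rbind, lapply(seq_len(ncol(d)), function(l) {
      s <- ci_summary(d[, l])
      data.frame(item = items[k], level = l, median = s["median"],
                 ci_low = s["low"], ci_high = s["high"],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
}

#' Linearity test for one item's progression
#'
#' An item progresses linearly when the time spent at every level is the
#' same.  For each pair of levels the posterior of the delta difference is
#' formed draw-by-draw; the progression is flagged nonlinear when any
#' pairwise 95% credible interval excludes zero.  The headline effect is
#' the per-draw difference between the largest and smallest delta
#' ("maximum difference in progression").  No multiplicity correction is
#' applied across pairs: the intervals are raw posterior 95% CIs.
#'
#' @param samples A `posterior_samples` object.
#' @param item Item name or index (must have at least two deltas).
#' @return List of class `linearity_result`: `item`, `nonlinear` flag,
#'   `max_diff` (median/CI of max-min), and `pairs` (data frame of level
#'   pairs with difference medians and CIs).
#' @export
test_linearity <- function(samples, item) {
  d <- delta_draws(samples, item)
  if (ncol(d) < 2L) stop("item has a single delta; linearity is undefined")
  items <- names(samples$scale$items)
  k <- if (is.character(item)) match(item, items) else item
  pairs <- utils::combn(ncol(d), 2L)
  pair_rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    s <- ci_summary(d[, j] - d[, i])
    data.frame(level_a = i, level_b = j, median = s["median"],
               ci_low = s["low"], ci_high = s["high"],
               excludes_zero = s["low"] > 0 || s["high"] < 0,
               row.names = NULL)
  })
  pair_df <- do.call(rbind, pair_rows)
  range_diff <- apply(d, 1L, max) - apply(d, 1L, min)
  md <- ci_summary(range_diff)
  structure(
    list(item = items[k],
         nonlinear = any(pair_df$excludes_zero),
         max_diff = list(median = unname(md["median"]),
                         ci_low = unname(md["low"]),
                         ci_high = unname(md["high"])),
         pairs = pair_df),
    class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf(
    "item %s: progression %s; max-min delta %.2f y [%.2f; %.2f]\n",
    x$item, if (x$nonlinear) "NONLINEAR" else "consistent with linear",
    x$max_diff$median, x$max_diff$ci_low, x$max_diff$ci_high))
  invisible(x)
}

#' Per-item speed and variability of progression
#'
#' For each item, the per-draw mean of its deltas is the average time for
#' a one-point increase on that item.  The posterior of that mean is
#' summarized by its median, 95% credible interval, and interquartile
#' range (the variability measure used to compare items).
#'
#' @param samples A `posterior_samples` object.
#' @return Data frame: `item`, `mean_delta_median`, `ci_low`, `ci_high`,
#'   `iqr`.
#' @export
item_speeds <- function(samples) {
  items <- names(samples$scale$items)
  do.call(rbind, lapply(seq_along(items), function(k) {
    per_draw <- rowMeans(delta_draws(samples, k))
    s <- ci_summary(per_draw)
    q <- stats::quantile(per_draw, c(0.25, 0.75), names = FALSE, type = 7)
    data.frame(item = items[k],
               mean_delta_median = s["median"],
               ci_low = s["low"], ci_high = s["high"],
               iqr = q[2L] - q[1L],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Per-draw mean delta of one item
#'
#' @param samples A `posterior_samples` object.
#' @param item Item name or index.
#' @return Numeric vector: the posterior draws of the item's mean delta.
#' @export
mean_delta_draws <- function(samples, item) {
  rowMeans(delta_draws(samples, item))
}

#' Group-level dynamics of the individual parameters
#'
#' At each retained iteration, the mean acceleration factor exp(xi) and
#' mean start-of-progression age tau are computed within each subject
#' group (e.g. SCA genotype); the resulting posteriors are summarized by
#' median and 95% credible interval.
#'
#' @param samples A `posterior_samples` object.
#' @param grouping Named character vector or factor mapping every subject
#'   id to a group label.
#' @return Data frame: `group`, `n_subjects`, and median/CI columns for
#'   the mean acceleration factor and mean tau.
#' @export
group_dynamics <- function(samples, grouping) {
  g <- as.character(grouping)[match(samples$subjects, names(grouping))]
  if (anyNA(g)) {
    stop("grouping missing for subject ",
         samples$subjects[which(is.na(g))[1L]])
  }
  do.call(rbind, lapply(unique(g), function(lev) {
    idx <- which(g == lev)
    if (!length(idx)) stop("empty group: ", lev)
    accel <- rowMeans(exp(samples$xi[, idx, drop = FALSE]))
    tau <- rowMeans(samples$tau[, idx, drop = FALSE])
    sa <- ci_summary(accel); st <- ci_summary(tau)
    data.frame(group = lev, n_subjects = length(idx),
               accel_median = sa["median"], accel_low = sa["low"],
               accel_high = sa["high"],
               tau_median = st["median"], tau_low = st["low"],
               tau_high = st["high"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Per-subject posterior medians of the individual parameters
#'
#' @param samples A `posterior_samples` object.
#' @return Data frame: `subject_id`, `xi`, `tau` (posterior medians).
#' @export
individual_estimates <- function(samples) {
  data.frame(subject_id = samples$subjects,
             xi = apply(samples$xi, 2L, stats::median),
             tau = apply(samples$tau, 2L, stats::median),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between start of progression and CAG repeat length
#'
#' Pearson correlation between estimated start-of-progression ages and the
#' logarithm of the expanded CAG repeat length, with a Fisher-z 95%
#' confidence interval and two-sided p-value.
#'
#' @param tau_estimates Numeric vector of per-subject start ages (years),
#'   e.g. posterior medians from [individual_estimates()].
#' @param cag Numeric vector of CAG repeat counts (> 0), same length.
#' @return List: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
cag_onset_correlation <- function(tau_estimates, cag) {
  ok <- is.finite(tau_estimates) & is.finite(cag)
  tau <- tau_estimates[ok]; cag <- cag[ok]
  if (length(tau) < 4L) stop("need at least 4 complete pairs")
  if (any(cag <= 0)) stop("cag must be positive")
  if (stats::sd(tau) == 0 || stats::sd(log(cag)) == 0) {
    stop("zero variance in tau or log(CAG)")
  }
  ct <- stats::cor.test(tau, log(cag), method = "pearson",
                        conf.level = 0.95)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1L],
       ci_high = ct$conf.int[2L], p = ct$p.value, n = length(tau))
}

#' Ratio of two progression rates
#'
#' Utility for comparing group progression speeds expressed as points per
#' year (e.g. the fastest genotype's annual score increase over the
#' slowest's).
#'
#' @param rate_fast,rate_slow Progression rates in points per year.
#' @return The ratio `rate_fast / rate_slow`.
#' @export
progression_rate_ratio <- function(rate_fast, rate_slow) {
  stopifnot(rate_slow > 0)
  rate_fast / rate_slow
}

#' Export posterior analyses as tidy tables
#'
#' Writes delta summaries, per-item linearity results, item speeds and
#' (when a grouping is given) group dynamics to CSV files in `dir`, plus a
#' combined JSON.
#'
#' @param samples A `posterior_samples` object.
#' @param dir Output directory.
#' @param grouping Optional subject-to-group mapping for
#'   [group_dynamics()].
#' @return Invisibly, the list of computed tables.
#' @export
export_analysis <- function(samples, dir, grouping = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  deltas <- summarize_deltas(samples)
  speeds <- item_speeds(samples)
  items <- names(samples$scale$items)
  lin <- do.call(rbind, lapply(items, function(it) {
    if (samples$scale$items[[it]] < 3L) return(NULL)
    r <- test_linearity(samples, it)
    data.frame(item = it, nonlinear = r$nonlinear,
               max_diff_median = r$max_diff$median,
               max_diff_low = r$max_diff$ci_low,
               max_diff_high = r$max_diff$ci_high,
               stringsAsFactors = FALSE)
  }))
  out <- list(delta_summary = deltas, item_speeds = speeds, linearity = lin)
  if (!is.null(grouping)) out$group_dynamics <- group_dynamics(samples, grouping)
  for (nm in names(out)) {
    utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(out, file.path(dir, "analysis.json"),
                       dataframe = "rows", digits = NA)
  invisible(out)
}
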