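#' Cronbach's alpha with bootstrap confidence interval
#'
#' Internal consistency of a multi-item scale:
#' \deqn{\alpha = \frac{K}{K-1}\left(1 -
#'   \frac{\sum_k \mathrm{Var}(x_k)}{\mathrm{Var}(\sum_k x_k)}\right)}
#' with unbiased (n-1) variances.  The confidence interval is the 2.5/97.5
#' percentile of alpha over `n_boot` resamples of rows (subjects) with
#' replacement.  Rows with any missing item are excluded (their count is
#' reported in the result).
#'
#' @param item_matrix Numeric matrix or data frame, subjects in rows, items
#'   in columns.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A list of class `reliability_result`: `alpha`, `ci_low`,
#'   `ci_high`, `n_boot`, `n_used`, `n_dropped`.
#' @export
cronbach_alpha <- function(item_matrix, n_boot = 1000L, seed = 1L) {
  m <- as.matrix(as.data.frame(item_matrix))
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("need at least 2 items")
  keep <- !apply(m, 1L, anyNA)
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete rows")
  if (n_dropped > 0L) {
    message(sprintf("cronbach_alpha: excluded %d rows with missing items",
                    n_dropped))
  }
  alpha <- alpha_stat(m)
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      alpha_stat(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE],
                 strict = FALSE)
    }, numeric(1L))
  })
  boots <- boots[is.finite(boots)]
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  structure(
    list(alpha = alpha, ci_low = ci[1L], ci_high = ci[2L],
         n_boot = as.integer(n_boot), n_used = nrow(m),
         n_dropped = n_dropped),
    class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha: %.3f (95%% bootstrap CI [%.3f; %.3f], %d resamples, n = %d)\n",
              x$alpha, x$ci_low, x$ci_high, x$n_boot, x$n_used))
  invisible(x)
}

# alpha on a complete matrix; degenerate resamples (zero total variance)
# yield NA under strict = FALSE so the bootstrap can skip them
alpha_stat <- function(m, strict = TRUE) {
  k <- ncol(m)
  item_var <- apply(m, 2L, stats::var)
  tot_var <- stats::var(rowSums(m))
  if (tot_var == 0) {
    if (strict) stop("zero variance of the total score")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(item_var) / tot_var)
}

#' Alpha when each item is deleted in turn
#'
#' Recomputes Cronbach's alpha on the K-1 remaining items after removing
#' each item; an item whose removal raises alpha is a candidate for
#' exclusion, while decreases across the board indicate every item
#' contributes to internal consistency.
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector of length K.
#' @export
alpha_if_deleted <- function(item_matrix) {
  m <- as.matrix(as.data.frame(item_matrix))
  storage.mode(m) <- "double"
  if (ncol(m) < 3L) stop("need at least 3 items")
  keep <- !apply(m, 1L, anyNA)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete rows")
  out <- vapply(seq_len(ncol(m)), function(k) {
    alpha_stat(m[, -k, drop = FALSE])
  }, numeric(1L))
  stats::setNames(out, colnames(m))
}
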