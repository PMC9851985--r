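#' Construct and validate a longitudinal cohort
#'
#' A cohort is a long table of visits (one row per subject visit) holding an
#' age in years and one ordinal score per scale item, plus optional
#' subject-level cofactors (SCA genotype, sex, CAG repeat length, source
#' cohort, continent).
#'
#' @param visits Data frame with columns `subject_id`, `age`, one column per
#'   scale item, and optionally `sca_type`, `sex`, `cag`, `cohort`,
#'   `continent` (constant within subject).
#' @param scale A `scale_definition`.
#' @return An object of class `sara_cohort` with elements `visits` (the
#'   validated long table, ordered by subject then age), `scale`, and
#'   `n_dropped` (visits removed because every item was missing).
#' @details Validation enforces: ages positive and strictly increasing
#'   within subject (duplicate subject/age rows are an error, not merged);
#'   every score an integer within its item's range or `NA`; cofactor
#'   categories within their closed sets.  Visits with all items missing are
#'   dropped with a message.
#' @export
as_cohort <- function(visits, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  df <- as.data.frame(visits, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", names(scale$items))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  extra_scores <- setdiff(
    grep("^(sara_|fsara_)", names(df), value = TRUE), names(scale$items))
  if (length(extra_scores)) {
    stop("unknown item columns: ", paste(extra_scores, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("ages must be positive finite numbers")
  }
  for (k in seq_along(scale$items)) {
    item <- names(scale$items)[k]
    x <- suppressWarnings(as.numeric(df[[item]]))
    bad <- which(!is.na(x) & (x < 0 | x > scale$items[k] | x != round(x)))
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(
        "subject %s, age %.2f: score %g out of range for item %d '%s' (maximum %d)",
        df$subject_id[i], df$age[i], x[i], k, item, scale$items[k]))
    }
    df[[item]] <- as.integer(x)
  }
  all_missing <- rowSums(!is.na(as.matrix(df[names(scale$items)]))) == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped > 0L) {
    message(sprintf("dropped %d visits with all items missing", n_dropped))
    df <- df[!all_missing, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("cohort has no usable visits")
  df <- df[order(df$subject_id, df$age), , drop = FALSE]
  rownames(df) <- NULL
  dup <- duplicated(df[c("subject_id", "age")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate visit for subject %s at age %.4g",
                 df$subject_id[i], df$age[i]))
  }
  check_categories(df)
  structure(list(visits = df, scale = scale, n_dropped = n_dropped),
            class = "sara_cohort")
}

sca_levels <- c("SCA1", "SCA2", "SCA3", "SCA6")
cohort_levels <- c("EUROSCA", "CRC-SCA", "RISCA", "SPATAX")

check_categories <- function(df) {
  check <- function(col, allowed) {
    if (!col %in% names(df)) return(invisible())
    v <- df[[col]]
    bad <- !is.na(v) & !(v %in% allowed)
    if (any(bad)) {
      stop(sprintf("unknown %s value '%s' (allowed: %s)",
                   col, v[bad][1L], paste(allowed, collapse = ", ")))
    }
  }
  check("sca_type", sca_levels)
  check("cohort", cohort_levels)
  if ("cag" %in% names(df)) {
    cag <- df$cag
    if (any(!is.na(cag) & (cag < 1 | cag != round(cag)))) {
      stop("cag must be a positive integer repeat count")
    }
  }
  for (col in c("sca_type", "sex", "cag", "cohort", "continent")) {
    if (!col %in% names(df)) next
    varies <- tapply(df[[col]], df$subject_id, function(v) {
      length(unique(v[!is.na(v)])) > 1L
    })
    if (any(varies, na.rm = TRUE)) {
      stop(sprintf("cofactor '%s' varies within subject %s",
                   col, names(varies)[which(varies)[1L]]))
    }
  }
  invisible()
}

#' Read a cohort from long-format CSV
#'
#' The CSV dialect is UTF-8, comma-separated with a header:
#' `subject_id, age`, one column per scale item (e.g. `sara_1..sara_8` or
#' named items), and optional cofactors `sca_type, sex, cag, cohort,
#' continent`.  Empty cells are missing scores (no numeric sentinels).
#'
#' @param path CSV file path.
#' @param scale A `scale_definition`; columns `sara_1..sara_8` (or
#'   `fsara_1..fsara_4`) are renamed to the scale's item names when present.
#' @return A validated `sara_cohort`.
#' @export
load_cohort <- function(path, scale = sara_scale()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  prefix <- if (identical(scale$name, "f-SARA")) "fsara_" else "sara_"
  numbered <- paste0(prefix, seq_along(scale$items))
  if (all(numbered %in% names(df)) &&
      !all(names(scale$items) %in% names(df))) {
    names(df)[match(numbered, names(df))] <- names(scale$items)
  }
  as_cohort(df, scale)
}

#' Write a cohort to long-format CSV
#'
#' Emits the same dialect as [load_cohort()] reads: missing scores as empty
#' cells, comma-separated, with a header.
#'
#' @param cohort A `sara_cohort`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "sara_cohort"))
  df <- cohort$visits
  scale <- cohort$scale
  if (scale$name %in% c("SARA", "f-SARA")) {
    prefix <- if (identical(scale$name, "f-SARA")) "fsara_" else "sara_"
    names(df)[match(names(scale$items), names(df))] <-
      paste0(prefix, seq_along(scale$items))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Number of subjects in a cohort
#' @param cohort A `sara_cohort`.
#' @return Integer count of distinct subjects.
#' @export
n_subjects <- function(cohort) length(unique(cohort$visits$subject_id))

#' @export
print.sara_cohort <- function(x, ...) {
  cat(sprintf("<sara_cohort> %d subjects, %d visits, scale %s\n",
              n_subjects(x), nrow(x$visits), x$scale$name))
  invisible(x)
}

#' Descriptive summary of a cohort
#'
#' Median and interquartile range of baseline age, number of visits,
#' follow-up years and baseline total score, plus counts for categorical
#' cofactors, overall and per group.  Available-case totals are used: a
#' visit's total score is missing when any item is missing.
#'
#' @param cohort A `sara_cohort`.
#' @param by Optional cofactor column to group by (e.g. `"sca_type"`).
#' @return A data frame with one row per group (plus `Overall`).
#' @export
summarize_cohort <- function(cohort, by = NULL) {
  stopifnot(inherits(cohort, "sara_cohort"))
  v <- cohort$visits
  if (nrow(v) == 0L) stop("empty cohort")
  v$total <- sum_score(v[names(cohort$scale$items)], cohort$scale)
  per_subj <- do.call(rbind, lapply(split(v, v$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1L],
               baseline_age = d$age[1L],
               n_visits = nrow(d),
               followup_years = max(d$age) - min(d$age),
               baseline_total = d$total[1L],
               group = if (!is.null(by)) as.character(d[[by]][1L]) else "Overall",
               stringsAsFactors = FALSE)
  }))
  groups <- if (is.null(by)) list(Overall = per_subj) else {
    c(split(per_subj, per_subj$group), list(Overall = per_subj))
  }
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  }
  do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    a <- med_iqr(d$baseline_age); n <- med_iqr(d$n_visits)
    f <- med_iqr(d$followup_years); t <- med_iqr(d$baseline_total)
    data.frame(group = g, n_subjects = nrow(d),
               age_median = a[1L], age_q1 = a[2L], age_q3 = a[3L],
               visits_median = n[1L], visits_q1 = n[2L], visits_q3 = n[3L],
               followup_median = f[1L], followup_q1 = f[2L],
               followup_q3 = f[3L],
               baseline_total_median = t[1L], baseline_total_q1 = t[2L],
               baseline_total_q3 = t[3L],
               stringsAsFactors = FALSE)
  }))
}

#' Baseline visit rows of a cohort
#'
#' @param cohort A `sara_cohort`.
#' @return Data frame with one row per subject (first visit by age).
#' @export
baseline_visits <- function(cohort) {
  v <- cohort$visits
  v[!duplicated(v$subject_id), , drop = FALSE]
}
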