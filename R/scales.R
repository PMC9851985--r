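#' Define an ordinal rating scale
#'
#' A scale is an ordered set of items, each scored on integer levels
#' `0..maximum`.  The scale total is the sum of item scores, so the scale
#' maximum is the sum of the item maxima.
#'
#' @param name Scale name.
#' @param items Named integer vector of per-item maximum levels, in item
#'   order.  Names are the item names used as CSV column headers.
#' @return An object of class `scale_definition` with elements `name`,
#'   `items` (named integer vector) and `maximum` (sum of maxima).
#' @examples
#' scale_definition("toy", c(a = 2, b = 3))
#' @export
scale_definition <- function(name, items) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(items)) || any(!nzchar(names(items)))) {
    stop("every item must be named")
  }
  maxima <- as.integer(items)
  if (any(is.na(maxima)) || any(maxima < 1L)) {
    stop("item maxima must be positive integers")
  }
  if (anyDuplicated(names(items))) stop("duplicate item names")
  structure(
    list(name = name,
         items = stats::setNames(maxima, names(items)),
         maximum = sum(maxima)),
    class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items, total 0-%d\n",
              x$name, length(x$items), x$maximum))
  cat(paste(sprintf("  %s (0-%d)", names(x$items), x$items), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Built-in SARA scale
#'
#' The Scale for the Assessment and Rating of Ataxia: eight items with
#' maxima 8 (gait), 6 (stance), 4 (sitting), 6 (speech) and 4 for each of
#' the four kinetic items, giving a total score of 0-40.
#'
#' @return A `scale_definition`.
#' @export
sara_scale <- function() {
  scale_definition("SARA", c(
    gait = 8L, stance = 6L, sitting = 4L, speech = 6L,
    finger_chase = 4L, finger_nose = 4L, hand_fast = 4L, heel_shin = 4L))
}

#' Built-in f-SARA scale
#'
#' The four-item functional variant used as a trial endpoint: gait, stance,
#' sitting and speech, each rescaled to 0-4, total 0-16.
#'
#' @return A `scale_definition`.
#' @export
fsara_scale <- function() {
  scale_definition("f-SARA", c(
    gait = 4L, stance = 4L, sitting = 4L, speech = 4L))
}

#' Single pseudo-item scale for a total score
#'
#' Univariate modelling treats the scale total as one ordinal pseudo-item
#' (e.g. SARA total with 40 levels and 39 level durations).
#'
#' @param maximum Maximum total score.
#' @param name Scale name.
#' @param item Item (column) name.
#' @return A `scale_definition` with a single item.
#' @export
total_score_scale <- function(maximum = 40L, name = "SARA-total",
                              item = "total") {
  scale_definition(name, stats::setNames(as.integer(maximum), item))
}

#' Sum score of one or more visits
#'
#' @param scores A numeric vector of per-item levels for one visit, or a
#'   matrix/data frame with one column per item.  Items must be in scale
#'   order (or named after the scale items).
#' @param scale A `scale_definition`.
#' @return Integer total per visit; `NA` where any item is missing.
#' @details Out-of-range scores are an error, naming the offending item.
#' @export
sum_score <- function(scores, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  m <- score_matrix(scores, scale)
  for (k in seq_along(scale$items)) {
    bad <- which(!is.na(m[, k]) & (m[, k] < 0 | m[, k] > scale$items[k] |
                                     m[, k] != round(m[, k])))
    if (length(bad)) {
      stop(sprintf("score %g out of range for item '%s' (0-%d)",
                   m[bad[1L], k], names(scale$items)[k], scale$items[k]))
    }
  }
  out <- as.integer(rowSums(m))
  out[apply(m, 1L, anyNA)] <- NA_integer_
  out
}

# Coerce a vector / data.frame / matrix of item scores to a numeric matrix
# with one column per scale item, matching by name when names are present.
score_matrix <- function(scores, scale) {
  k <- length(scale$items)
  if (is.null(dim(scores))) {
    if (length(scores) != k) {
      stop(sprintf("expected %d item scores, got %d", k, length(scores)))
    }
    m <- matrix(as.numeric(scores), nrow = 1L)
    colnames(m) <- names(scale$items)
    return(m)
  }
  m <- as.matrix(as.data.frame(scores))
  if (!is.null(colnames(m)) && all(names(scale$items) %in% colnames(m))) {
    m <- m[, names(scale$items), drop = FALSE]
  } else if (ncol(m) != k) {
    stop(sprintf("expected %d item columns, got %d", k, ncol(m)))
  }
  storage.mode(m) <- "double"
  colnames(m) <- names(scale$items)
  m
}

#' Default SARA to f-SARA level mapping
#'
#' Proportional collapse of the four retained SARA items onto 0-4:
#' gait (0-8) by pairs `0 / 1-2 / 3-4 / 5-6 / 7-8`; stance and speech (0-6)
#' by `0 / 1-2 / 3-4 / 5 / 6`; sitting (0-4) unchanged.  Endpoints are
#' preserved (0 maps to 0, the item maximum to 4) and each per-item map is
#' monotone.  Users may substitute their own table via
#' [read_mapping_json()].
#'
#' @return A named list of integer vectors; element `i` of each vector is
#'   the target level for source level `i - 1`.
#' @export
fsara_mapping_default <- function() {
  list(
    gait    = c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
    stance  = c(0L, 1L, 1L, 2L, 2L, 3L, 4L),
    sitting = c(0L, 1L, 2L, 3L, 4L),
    speech  = c(0L, 1L, 1L, 2L, 2L, 3L, 4L))
}

#' Read a level-mapping table from JSON
#'
#' The JSON format is `{"gait": {"0": 0, "1": 1, ...}, ...}`: one object per
#' source item mapping every source level to a target level.
#'
#' @param path Path to a JSON file.
#' @return A mapping table as returned by [fsara_mapping_default()].
#' @export
read_mapping_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(item) {
    lv <- as.integer(names(item))
    if (anyNA(lv) || !setequal(lv, 0:max(lv))) {
      stop("mapping must cover consecutive source levels 0..max")
    }
    as.integer(unlist(item))[order(lv)]
  })
  names(out) <- names(raw)
  out
}

#' Write a level-mapping table to JSON
#'
#' @param mapping A mapping table (named list of integer vectors).
#' @param path Output path.
#' @export
write_mapping_json <- function(mapping, path) {
  obj <- lapply(mapping, function(v) {
    stats::setNames(as.list(as.integer(v)), as.character(seq_along(v) - 1L))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

validate_mapping <- function(mapping, source_scale, target_scale) {
  for (item in names(target_scale$items)) {
    if (is.null(mapping[[item]])) {
      stop(sprintf("mapping missing source item '%s'", item))
    }
    v <- mapping[[item]]
    smax <- source_scale$items[[item]]
    tmax <- target_scale$items[[item]]
    if (length(v) != smax + 1L) {
      stop(sprintf("mapping for '%s' must cover levels 0..%d", item, smax))
    }
    if (any(diff(v) < 0L)) {
      stop(sprintf("mapping for '%s' is not monotone", item))
    }
    if (v[1L] != 0L || v[length(v)] != tmax) {
      stop(sprintf("mapping for '%s' must fix 0 -> 0 and %d -> %d",
                   item, smax, tmax))
    }
    if (any(v < 0L | v > tmax)) {
      stop(sprintf("mapping for '%s' leaves target range", item))
    }
  }
  invisible(mapping)
}

#' Map SARA item scores to f-SARA
#'
#' Applies a per-item level mapping to the four retained items (gait,
#' stance, sitting, speech); the four kinetic items are dropped.  Missing
#' source levels stay missing.
#'
#' @param scores Vector of eight SARA item levels, or a matrix/data frame
#'   with SARA item columns (extra columns are ignored).
#' @param mapping Mapping table, default [fsara_mapping_default()].
#' @return A matrix (or vector, if the input was a vector) of four f-SARA
#'   item levels in 0-4.
#' @export
map_to_fsara <- function(scores, mapping = fsara_mapping_default()) {
  sara <- sara_scale()
  fsara <- fsara_scale()
  validate_mapping(mapping, sara, fsara)
  vec_in <- is.null(dim(scores))
  m <- score_matrix(scores, sara)
  out <- matrix(NA_integer_, nrow(m), length(fsara$items),
                dimnames = list(NULL, names(fsara$items)))
  for (item in names(fsara$items)) {
    src <- m[, item]
    smax <- sara$items[[item]]
    bad <- which(!is.na(src) & (src < 0 | src > smax | src != round(src)))
    if (length(bad)) {
      stop(sprintf("score %g out of range for item '%s' (0-%d)",
                   src[bad[1L]], item, smax))
    }
    out[, item] <- mapping[[item]][src + 1L]
  }
  if (vec_in) out[1L, ] else out
}
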