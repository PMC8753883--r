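# Condition-based filters ("epi-tags").
#
# A filter marks features or windows whose field satisfies a comparison
# against one or two thresholds, e.g. highlight windows holding >= 5
# differentially expressed genes, or features with |logFC| >= 2. Filters never
# mutate values; they only produce a marked id set plus a highlight color and
# optional tag label. Multiple filters compose as independent mark layers —
# later layers paint over earlier ones at render time.

#' Construct a filter specification
#'
#' @param scope \code{"feature"} (predicate on each feature's own value) or
#'   \code{"window"} (predicate on a per-window quantity).
#' @param field \code{"value"} (feature scope), \code{"agg_value"} or
#'   \code{"count"} (window scope).
#' @param op comparator: \code{lt}, \code{le}, \code{gt}, \code{ge}, \code{eq},
#'   \code{between} (closed on both ends, 2 thresholds) or \code{abs_ge}
#'   (\code{|x| >= t}, covering "x >= t or x <= -t" as one filter).
#' @param thresholds numeric, length 1 (length 2 for \code{between}).
#' @param color highlight color for marked items.
#' @param label optional tag label shown in tooltips/legends.
#' @return object of class \code{filter_spec}.
#' @examples
#' filter_spec("window", "count", "ge", 5, color = "yellow")
#' filter_spec("feature", "value", "abs_ge", 2, color = "orange")
#' @export
filter_spec <- function(scope = c("feature", "window"),
                        field = c("value", "agg_value", "count"),
                        op = c("lt", "le", "gt", "ge", "eq", "between", "abs_ge"),
                        thresholds, color = "yellow", label = NULL) {
  scope <- match.arg(scope)
  field <- match.arg(field)
  op <- match.arg(op)
  if (scope == "feature" && field != "value") {
    stop("feature-scope filters use field 'value'", call. = FALSE)
  }
  if (scope == "window" && field == "value") {
    stop("window-scope filters use field 'agg_value' or 'count'", call. = FALSE)
  }
  need <- if (op == "between") 2L else 1L
  if (!is.numeric(thresholds) || length(thresholds) != need) {
    stop(sprintf("op '%s' requires exactly %d threshold(s)", op, need), call. = FALSE)
  }
  structure(list(scope = scope, field = field, op = op,
                 thresholds = as.numeric(thresholds),
                 color = color, label = label),
            class = "filter_spec")
}

filter_predicate <- function(spec, x) {
  t <- spec$thresholds
  ok <- switch(spec$op,
               lt = x < t[1], le = x <= t[1],
               gt = x > t[1], ge = x >= t[1],
               eq = x == t[1],
               between = x >= t[1] & x <= t[2],
               abs_ge = abs(x) >= t[1])
  ok & !is.na(x)
}

#' Apply a filter to features or aggregated windows
#'
#' @param spec a \code{\link{filter_spec}}.
#' @param items for feature scope, an annotation data.frame (with
#'   \code{value_num}); for window scope, an \code{\link{aggregate_windows}}
#'   result. Items whose field is missing (categorical feature value, window
#'   with no numeric member) are never marked.
#' @return character vector of marked item ids: element ids for features,
#'   \code{"chrom:index"} keys for windows. Marking never mutates values and
#'   is idempotent.
#' @export
apply_filter <- function(spec, items) {
  stopifnot(inherits(spec, "filter_spec"), is.data.frame(items))
  if (spec$scope == "feature") {
    if (!"value_num" %in% names(items)) {
      stop("feature filter needs an annotation table with a value column", call. = FALSE)
    }
    x <- items$value_num
    ids <- items$element_id
  } else {
    x <- switch(spec$field,
                agg_value = {
                  if (!"agg_value" %in% names(items)) {
                    stop("window filter on agg_value needs an aggregated window table",
                         call. = FALSE)
                  }
                  items$agg_value
                },
                count = {
                  if (!"n_members" %in% names(items)) {
                    stop("window filter on count needs an aggregated window table",
                         call. = FALSE)
                  }
                  as.numeric(items$n_members)
                })
    ids <- paste0(items$chrom, ":", items$index)
  }
  ids[filter_predicate(spec, x)]
}

#' Parse a filter from its command-line string form
#'
#' Grammar: \code{"SCOPE:FIELD OP THRESHOLD[,THRESHOLD] COLOR[:LABEL]"},
#' e.g. \code{"window:count ge 5 yellow:highDEG"} or
#' \code{"feature:value abs_ge 2 orange"}.
#'
#' @param s the filter string.
#' @return a \code{\link{filter_spec}}.
#' @export
parse_filter <- function(s) {
  parts <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  if (length(parts) != 4L) {
    stop(sprintf("cannot parse filter '%s': expected 'SCOPE:FIELD OP T[,T] COLOR[:LABEL]'", s),
         call. = FALSE)
  }
  sf <- strsplit(parts[1], ":", fixed = TRUE)[[1]]
  if (length(sf) != 2L) {
    stop(sprintf("cannot parse filter scope:field '%s'", parts[1]), call. = FALSE)
  }
  thr <- suppressWarnings(as.numeric(strsplit(parts[3], ",", fixed = TRUE)[[1]]))
  if (anyNA(thr)) {
    stop(sprintf("cannot parse filter thresholds '%s'", parts[3]), call. = FALSE)
  }
  cl <- strsplit(parts[4], ":", fixed = TRUE)[[1]]
  filter_spec(scope = sf[1], field = sf[2], op = parts[2], thresholds = thr,
              color = cl[1], label = if (length(cl) > 1L) cl[2] else NULL)
}
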