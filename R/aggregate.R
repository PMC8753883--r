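# Per-window aggregation of feature-associated data.
#
# A window encompassing more than one element shows one aggregated value
# (sum, mean, min, max or count); individual member values stay available for
# tooltips. Numeric and categorical values can be mixed in one annotation
# column: categorical members are excluded from arithmetic but still counted
# by op = "count" and tallied into per-category group counts. A segment
# feature contributes its full value to every window it overlaps — no
# length-proportional splitting — so tooltip values always equal input values.

#' Aggregate a numeric vector
#'
#' @param values numeric vector (may be empty only for \code{op = "count"}).
#' @param op one of \code{"sum"}, \code{"mean"}, \code{"min"}, \code{"max"},
#'   \code{"count"}.
#' @return single numeric; \code{mean = sum / n}.
#' @examples
#' aggregate_values(c(1, 2, 3), "mean")
#' aggregate_values(numeric(0), "count")
#' @export
aggregate_values <- function(values, op = c("sum", "mean", "min", "max", "count")) {
  op <- match.arg(op)
  if (op == "count") return(length(values))
  if (length(values) == 0L) {
    stop(sprintf("aggregation '%s' requires at least one value", op), call. = FALSE)
  }
  switch(op,
         sum = sum(values),
         mean = sum(values) / length(values),
         min = min(values),
         max = max(values))
}

#' Aggregate annotation data per window
#'
#' @param windows data.frame from \code{\link{build_windows_all}}.
#' @param assignments data.frame from \code{\link{assign_annotations}}.
#' @param annotations the kept annotations the assignments index into.
#' @param op aggregation operator, see \code{\link{aggregate_values}}.
#' @return the \code{windows} data.frame with added columns:
#'   \code{n_members} (membership cardinality), \code{agg_value} (numeric;
#'   \code{NA} when the window has no numeric member and \code{op != "count"}),
#'   and list-columns \code{members} (element ids), \code{member_values}
#'   (named numeric, \code{NA} for categorical members) and
#'   \code{group_counts} (named integer per category).
#' @export
aggregate_windows <- function(windows, assignments, annotations,
                              op = c("sum", "mean", "min", "max", "count")) {
  op <- match.arg(op)
  key <- paste(windows$chrom, windows$index)
  akey <- factor(paste(assignments$chrom, assignments$window), levels = key)
  rows_by_win <- split(assignments$ann_row, akey)

  out <- windows
  out$n_members <- vapply(rows_by_win, length, integer(1))
  out$members <- I(lapply(rows_by_win, function(r) annotations$element_id[r]))
  out$member_values <- I(lapply(rows_by_win, function(r) {
    v <- annotations$value_num[r]
    names(v) <- annotations$element_id[r]
    v
  }))
  out$group_counts <- I(lapply(rows_by_win, function(r) {
    cat_ <- annotations$value[r][is.na(annotations$value_num[r]) &
                                 !is.na(annotations$value[r])]
    if (length(cat_) == 0L) return(integer(0))
    tab <- table(cat_)
    stats::setNames(as.integer(tab), names(tab))
  }))
  out$agg_value <- vapply(rows_by_win, function(r) {
    v <- annotations$value_num[r]
    v <- v[!is.na(v)]
    if (op == "count") return(as.numeric(length(r)))
    if (length(v) == 0L) return(NA_real_)
    aggregate_values(v, op)
  }, numeric(1))
  attr(out, "agg_op") <- op
  out
}

#' Tooltip payload for one aggregated window
#'
#' Collects everything an interactive tooltip shows for a window: genomic
#' span, member ids with their individual values and hyperlinks, the
#' aggregated value, per-category counts, and any active filter tags.
#'
#' @param aw one row of an \code{\link{aggregate_windows}} result.
#' @param annotations the kept annotations (source of hyperlinks).
#' @param tags character vector of tag labels active on this window.
#' @param agg_op name of the aggregation operator used (defaults to the
#'   \code{"agg_op"} attribute if still present on \code{aw}).
#' @return a list: \code{chrom}, \code{index}, \code{span} (string
#'   \code{"start-end"}), \code{n}, \code{members} (list of
#'   \code{list(id, value, hyperlink)}), \code{agg_op}, \code{agg_value},
#'   \code{groups}, \code{tags}.
#' @export
build_tooltip_payload <- function(aw, annotations, tags = character(0),
                                  agg_op = attr(aw, "agg_op")) {
  ids <- aw$members[[1]]
  vals <- aw$member_values[[1]]
  href <- annotations$hyperlink[match(ids, annotations$element_id)]
  raw <- annotations$value[match(ids, annotations$element_id)]
  members <- lapply(seq_along(ids), function(j) {
    list(id = ids[j],
         value = if (!is.na(vals[j])) unname(vals[j])
                 else if (!is.na(raw[j])) raw[j] else NULL,
         hyperlink = if (!is.na(href[j])) href[j] else NULL)
  })
  gc <- aw$group_counts[[1]]
  list(chrom = aw$chrom, index = aw$index,
       span = sprintf("%g-%g", aw$span_start, aw$span_end),
       n = aw$n_members,
       members = members,
       agg_op = agg_op %||% NULL,
       agg_value = if (!is.na(aw$agg_value)) aw$agg_value else NULL,
       groups = if (length(gc)) as.list(gc) else NULL,
       tags = if (length(tags)) as.list(tags) else NULL)
}
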