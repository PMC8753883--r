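# Canvas geometry.
#
# Each chromosome set is an independent track block: within a set all
# chromosomes share one bp-per-px scale, so box width is proportional to
# window count and the set's longest chromosome spans the full drawable
# width; relative lengths stay visually truthful. Across sets, each set
# rescales independently (sets may differ in chromosome number and length);
# a common_scale option forces one global bp-per-px instead. Sets stack
# vertically in input order with a fixed gap. Every chromosome row reserves a
# data-track band above the ideogram (scatter/bar marks) and a label band
# below it.

#' Lay out chromosome sets on the canvas
#'
#' @param sets list of track sets; each a list with \code{set_id},
#'   \code{chromosomes} (data.frame) and \code{plan} (\code{window_plan}).
#' @param canvas_width total canvas width in px.
#' @param spacing vertical gap between sets (px).
#' @param chrom_height ideogram height (px).
#' @param track_height data-track band height above each ideogram (px); 0
#'   collapses the band.
#' @param label_height label band height below each ideogram (px per label
#'   row; one row reserved).
#' @param margin_left left margin for chromosome names (px).
#' @param common_scale use one bp-per-px scale across all sets.
#' @return object of class \code{track_layout}: list with \code{boxes}
#'   (data.frame: \code{set_id}, \code{chrom}, \code{x}, \code{y},
#'   \code{width}, \code{height}, \code{data_y}, \code{data_h},
#'   \code{label_y}, \code{n_windows}) and \code{canvas}
#'   (\code{width}, \code{height}, \code{margin_left}).
#' @export
layout_tracks <- function(sets, canvas_width = 1000, spacing = 40,
                          chrom_height = 24, track_height = 80,
                          label_height = 14, margin_left = 80,
                          common_scale = FALSE) {
  stopifnot(length(sets) >= 1)
  drawable <- canvas_width - margin_left - 20
  max_nw_all <- max(vapply(sets, function(s) max(s$plan$counts), numeric(1)))
  if (drawable < max_nw_all) {
    stop(sprintf(
      "canvas too narrow: %g px drawable for %g windows (< 1 px per window)",
      drawable, max_nw_all), call. = FALSE)
  }
  # px per window: within-set the longest chromosome spans the full drawable
  # width, so box width is proportional to window count; common_scale forces
  # one global bp-per-px instead (window widths then differ between sets).
  px_per_win <- vapply(sets, function(s) drawable / max(s$plan$counts), numeric(1))
  if (common_scale) {
    bp_max <- max(vapply(sets, function(s) {
      max(s$chromosomes$end - s$chromosomes$start + 1)
    }, numeric(1)))
    px_per_bp <- drawable / bp_max
    px_per_win <- vapply(sets, function(s) s$plan$window_size * px_per_bp,
                         numeric(1))
  }

  row_h <- track_height + 6 + chrom_height + 4 + label_height
  boxes <- list()
  y <- spacing / 2
  for (si in seq_along(sets)) {
    s <- sets[[si]]
    ch <- s$chromosomes
    for (ci in seq_len(nrow(ch))) {
      nw <- unname(s$plan$counts[[ch$name[ci]]])
      data_y <- y
      chrom_y <- y + track_height + 6
      boxes[[length(boxes) + 1L]] <- data.frame(
        set_id = s$set_id, chrom = ch$name[ci],
        x = margin_left, y = chrom_y,
        width = nw * px_per_win[si], height = chrom_height,
        data_y = data_y, data_h = track_height,
        label_y = chrom_y + chrom_height + 4 + label_height - 3,
        n_windows = unname(s$plan$counts[[ch$name[ci]]]),
        stringsAsFactors = FALSE)
      y <- y + row_h
    }
    y <- y + spacing
  }
  boxes <- do.call(rbind, boxes)
  structure(list(boxes = boxes,
                 canvas = list(width = canvas_width,
                               height = ceiling(y - spacing / 2),
                               margin_left = margin_left)),
            class = "track_layout")
}

#' Map a genomic position to a canvas x coordinate
#'
#' Affine, strictly monotone: \code{chrom.start} maps to \code{box$x},
#' \code{chrom.end} to \code{box$x + box$width}.
#'
#' @param pos base position(s), within \code{[chrom$start, chrom$end]}.
#' @param box one row of a \code{track_layout}'s \code{boxes}.
#' @param chrom the matching chromosome (one-row data.frame or list).
#' @return canvas x in px (vectorized).
#' @export
genomic_to_canvas <- function(pos, box, chrom) {
  if (any(pos < chrom$start | pos > chrom$end)) {
    stop("position outside chromosome range", call. = FALSE)
  }
  L <- chrom$end - chrom$start
  if (L == 0) return(rep(box$x, length(pos)))
  box$x + (pos - chrom$start) / L * box$width
}

#' Piecewise-linear heatmap color ramp
#'
#' Interpolates linearly in RGB across the ordered anchor colors over
#' \code{[v_min, v_max]}: \code{v_min} reproduces the first anchor exactly,
#' \code{v_max} the last; out-of-range values clamp to the end colors; the
#' degenerate \code{v_min == v_max} maps everything to the last anchor.
#'
#' @param value numeric value(s); \code{NA} returns \code{NA}.
#' @param v_min,v_max data range, \code{v_min <= v_max}.
#' @param anchors ordered vector of >= 1 colors (>= 2 for an actual ramp).
#' @return hex color string(s).
#' @examples
#' heatmap_color(5, 0, 10, c("black", "white"))   # "#808080"
#' @export
heatmap_color <- function(value, v_min, v_max, anchors = c("white", "steelblue")) {
  stopifnot(v_min <= v_max, length(anchors) >= 1)
  rgbm <- grDevices::col2rgb(anchors)  # 3 x k
  k <- ncol(rgbm)
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v_min == v_max || k == 1L) {
      return(grDevices::rgb(rgbm[1, k], rgbm[2, k], rgbm[3, k], maxColorValue = 255))
    }
    t <- clamp((v - v_min) / (v_max - v_min), 0, 1)
    seg <- t * (k - 1)
    i <- min(floor(seg), k - 2)         # segment index 0..k-2
    f <- seg - i
    ch <- round(rgbm[, i + 1] * (1 - f) + rgbm[, i + 2] * f)
    grDevices::rgb(ch[1], ch[2], ch[3], maxColorValue = 255)
  }, character(1))
}

#' Place scatter or bar marks for one chromosome's data track
#'
#' Scatter: one mark per feature at its anchor's canvas x, with the value
#' linearly rescaled from \code{[v_min, v_max]} to the track height and
#' inverted so larger values sit higher. Bar: one bar per window with height
#' proportional to the aggregated value (baseline at 0 when all values are
#' non-negative, else at the value-0 position of the \code{[v_min, v_max]}
#' scale). Categorical feature data colors marks by category. An optional
#' dashed reference line (e.g. logFC = 0 separating up- from down-regulated
#' genes) is emitted at its rescaled y.
#'
#' @param features kept annotations of this chromosome (scatter mode).
#' @param agg aggregated windows of this chromosome (bar mode).
#' @param style list: \code{plot_type} ("scatter"|"bar"), \code{color},
#'   \code{palette} (categorical colors), \code{y_reference} (numeric or
#'   \code{NULL}), \code{y_range} (length-2 numeric or \code{NULL}),
#'   \code{anchor} ("start"|"midpoint").
#' @param box the chromosome's layout box row.
#' @param chrom the chromosome (one-row data.frame).
#' @return list with \code{marks} (data.frame: \code{kind} "point"|"bar",
#'   \code{id}, \code{x}, \code{y}, \code{w}, \code{h}, \code{color},
#'   \code{category}), \code{ref_y} (px or \code{NULL}), \code{legend}
#'   (data.frame \code{label}, \code{color}).
#' @export
place_data_track <- function(features = NULL, agg = NULL, style, box, chrom) {
  pt <- style$plot_type
  stopifnot(pt %in% c("scatter", "bar"))
  legend <- data.frame(label = character(0), color = character(0),
                       stringsAsFactors = FALSE)
  y_top <- box$data_y
  h <- box$data_h

  rescale_y <- function(v, v_min, v_max) {
    if (v_max == v_min) return(rep(y_top + h / 2, length(v)))
    y_top + h * (1 - (v - v_min) / (v_max - v_min))
  }

  if (pt == "scatter") {
    num <- !is.na(features$value_num)
    cat_ <- !num & !is.na(features$value)
    if (any(num)) {
      # numeric scatter: y encodes the value
      f <- features[num, , drop = FALSE]
      v <- f$value_num
      rng <- style$y_range %||% range(v)
      anchor_pos <- if ((style$anchor %||% "start") == "midpoint")
        floor((f$start + f$end) / 2) else f$start
      x <- genomic_to_canvas(anchor_pos, box, chrom)
      y <- rescale_y(clamp(v, rng[1], rng[2]), rng[1], rng[2])
      marks <- data.frame(kind = "point", id = f$element_id, x = x, y = y,
                          w = 0, h = 0, color = style$color %||% "#2c7fb8",
                          category = NA_character_, stringsAsFactors = FALSE)
      ref_y <- if (!is.null(style$y_reference))
        rescale_y(clamp(style$y_reference, rng[1], rng[2]), rng[1], rng[2]) else NULL
      return(list(marks = marks, ref_y = ref_y, legend = legend, v_range = rng))
    }
    if (any(cat_)) {
      # categorical scatter: one y level and one color per category
      f <- features[cat_, , drop = FALSE]
      cc <- category_colors(f$value, style$palette %||% default_palette(),
                            levels = style$category_levels)
      lev <- match(f$value, cc$legend$label) - 1
      k <- nrow(cc$legend)
      anchor_pos <- if ((style$anchor %||% "start") == "midpoint")
        floor((f$start + f$end) / 2) else f$start
      x <- genomic_to_canvas(anchor_pos, box, chrom)
      y <- y_top + h * (lev + 0.5) / k
      marks <- data.frame(kind = "point", id = f$element_id, x = x, y = y,
                          w = 0, h = 0, color = cc$colors,
                          category = f$value, stringsAsFactors = FALSE)
      return(list(marks = marks, ref_y = NULL, legend = cc$legend,
                  v_range = c(0, k)))
    }
    stop("scatter track requires a feature data column", call. = FALSE)
  }

  # bar mode: one bar per window with an aggregated value
  keep <- !is.na(agg$agg_value)
  if (!any(keep)) stop("bar track requires numeric window aggregates", call. = FALSE)
  a <- agg[keep, , drop = FALSE]
  v <- a$agg_value
  rng <- style$y_range %||% range(v)
  if (all(v >= 0)) rng[1] <- 0
  win_w <- box$width / box$n_windows
  x <- box$x + a$index * win_w
  top <- rescale_y(clamp(v, rng[1], rng[2]), rng[1], rng[2])
  base <- rescale_y(clamp(0, rng[1], rng[2]), rng[1], rng[2])
  marks <- data.frame(kind = "bar",
                      id = paste0(a$chrom, ":", a$index),
                      x = x, y = pmin(top, base),
                      w = win_w, h = abs(base - top),
                      color = style$color %||% "#41ab5d",
                      category = NA_character_,
                      stringsAsFactors = FALSE)
  ref_y <- if (!is.null(style$y_reference))
    rescale_y(clamp(style$y_reference, rng[1], rng[2]), rng[1], rng[2]) else NULL
  list(marks = marks, ref_y = ref_y, legend = legend, v_range = rng)
}

#' Assign stable categorical colors
#'
#' Categories map to palette colors in first-appearance order, cycling the
#' palette when exhausted; legends list each category once.
#'
#' @param categories character vector (may repeat).
#' @param palette ordered colors; defaults to \code{\link{default_palette}}.
#' @param levels optional preset category ordering (e.g. the global
#'   first-appearance order across several chromosome sets), so the same
#'   category gets the same color everywhere.
#' @return list with \code{colors} (per input element) and \code{legend}
#'   (data.frame \code{label}, \code{color}, one row per distinct category).
#' @export
category_colors <- function(categories, palette = default_palette(),
                            levels = NULL) {
  u <- levels %||% unique(categories[!is.na(categories)])
  pal <- rep_len(to_hex(palette), max(length(u), 1L))
  col <- pal[match(categories, u)]
  list(colors = col,
       legend = data.frame(label = u, color = pal[seq_along(u)],
                           stringsAsFactors = FALSE))
}

#' Stagger feature labels into non-overlapping rows
#'
#' Greedy left-to-right sweep: a label stays in the first row where its
#' bounding box does not intersect the previous label of that row, otherwise
#' it drops to the next row. Label width is estimated as a fixed per-character
#' width.
#'
#' @param features annotations to label (uses \code{element_id} and
#'   \code{start} as anchor).
#' @param box the chromosome's layout box row.
#' @param chrom the chromosome.
#' @param char_width estimated px per character.
#' @param pad horizontal padding between labels (px).
#' @return data.frame: \code{id}, \code{text}, \code{x} (anchor px),
#'   \code{row} (0-based row index). Empty input gives zero rows.
#' @export
place_labels <- function(features, box, chrom, char_width = 7, pad = 2) {
  if (is.null(features) || nrow(features) == 0L) {
    return(data.frame(id = character(0), text = character(0),
                      x = numeric(0), row = integer(0), stringsAsFactors = FALSE))
  }
  x <- genomic_to_canvas(features$start, box, chrom)
  ord <- order(x)
  ids <- features$element_id[ord]
  xs <- x[ord]
  wd <- nchar(ids) * char_width
  left <- xs - wd / 2
  right <- xs + wd / 2
  row_end <- numeric(0)  # rightmost occupied x per row
  rows <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (r in seq_along(row_end)) {
      if (left[i] > row_end[r] + pad) {
        rows[i] <- r - 1L; row_end[r] <- right[i]; placed <- TRUE; break
      }
    }
    if (!placed) {
      row_end <- c(row_end, right[i])
      rows[i] <- length(row_end) - 1L
    }
  }
  data.frame(id = ids, text = ids, x = xs, row = rows, stringsAsFactors = FALSE)
}
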