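# Inter-locus links (edges and chord-like ribbons).
#
# A link endpoint is either the id of a drawn (kept) feature or an explicit
# locus "chrom:pos". Feature endpoints anchor at the feature's start base
# (point-annotation convention) on the chromosome edge facing the partner
# endpoint; locus endpoints map through the same affine coordinate transform.
# Edge style draws a cubic curve (arrowhead at the target iff directed);
# ribbon style draws a closed band whose end widths equal the source/target
# feature widths on canvas (minimum 2 px). Unresolvable endpoints fail before
# any rendering begins.

LOCUS_RE <- "^(.+):([0-9]+)$"

resolve_one_anchor <- function(endpoint, layout, sets) {
  # feature id lookup across all sets first; then "chrom:pos" locus syntax
  for (s in sets) {
    ann <- s$annotations
    if (!is.null(ann) && endpoint %in% ann$element_id) {
      i <- match(endpoint, ann$element_id)
      ci <- match(ann$chrom[i], s$chromosomes$name)
      b <- layout$boxes[layout$boxes$set_id == s$set_id &
                        layout$boxes$chrom == ann$chrom[i], , drop = FALSE]
      if (nrow(b) == 1L) {
        chrom <- s$chromosomes[ci, ]
        x1 <- genomic_to_canvas(ann$start[i], b, chrom)
        x2 <- genomic_to_canvas(ann$end[i], b, chrom)
        return(list(x = x1, box = b, width = max(abs(x2 - x1), 2)))
      }
    }
  }
  m <- regmatches(endpoint, regexec(LOCUS_RE, endpoint))[[1]]
  if (length(m) == 3L) {
    chrom_name <- m[2]
    pos <- as.numeric(m[3])
    for (s in sets) {
      ci <- match(chrom_name, s$chromosomes$name)
      if (!is.na(ci)) {
        chrom <- s$chromosomes[ci, ]
        if (pos < chrom$start || pos > chrom$end) {
          stop(sprintf("link endpoint '%s': position out of bounds for %s [%g, %g]",
                       endpoint, chrom_name, chrom$start, chrom$end), call. = FALSE)
        }
        b <- layout$boxes[layout$boxes$set_id == s$set_id &
                          layout$boxes$chrom == chrom_name, , drop = FALSE]
        return(list(x = genomic_to_canvas(pos, b, chrom), box = b, width = 2))
      }
    }
  }
  stop(sprintf("cannot resolve link endpoint '%s': no such feature or locus",
               endpoint), call. = FALSE)
}

#' Resolve link endpoints to canvas anchor points
#'
#' @param links data.frame from \code{\link{read_link_file}}.
#' @param layout a \code{track_layout}.
#' @param sets the laid-out track sets (each with \code{set_id},
#'   \code{chromosomes}, \code{annotations} = kept features).
#' @return data.frame with one row per link: \code{x1}, \code{y1}, \code{x2},
#'   \code{y2} (px), \code{w1}, \code{w2} (feature widths, px). Anchors sit on
#'   the chromosome edge facing the partner endpoint. Self-links
#'   (source == target) are rejected.
#' @export
resolve_link_anchors <- function(links, layout, sets) {
  if (any(links$source == links$target)) {
    bad <- links$source[links$source == links$target][1]
    stop(sprintf("self-link not supported: '%s' links to itself", bad), call. = FALSE)
  }
  out <- data.frame(x1 = numeric(nrow(links)), y1 = numeric(nrow(links)),
                    x2 = numeric(nrow(links)), y2 = numeric(nrow(links)),
                    w1 = numeric(nrow(links)), w2 = numeric(nrow(links)))
  for (i in seq_len(nrow(links))) {
    a <- resolve_one_anchor(links$source[i], layout, sets)
    b <- resolve_one_anchor(links$target[i], layout, sets)
    # anchor on the edge facing the partner: bottom edge when the partner is
    # below (or level), top edge when above
    a_below <- a$box$y > b$box$y
    out$x1[i] <- a$x
    out$y1[i] <- if (a_below) a$box$y else a$box$y + a$box$height
    out$x2[i] <- b$x
    out$y2[i] <- if (a_below) b$box$y + b$box$height else b$box$y
    out$w1[i] <- a$width
    out$w2[i] <- b$width
  }
  out
}

#' Compute the drawable path of one link
#'
#' @param anchor one row of \code{\link{resolve_link_anchors}} output.
#' @param style \code{"edge"} (cubic curve) or \code{"ribbon"} (closed
#'   chord-like band; end widths equal the feature widths, minimum 2 px).
#' @param gap vertical control-point offset; half the inter-track gap.
#' @return list: \code{d} (SVG path data), \code{closed} (logical).
#' @export
link_geometry <- function(anchor, style = c("edge", "ribbon"), gap = 40) {
  style <- match.arg(style)
  x1 <- anchor$x1; y1 <- anchor$y1; x2 <- anchor$x2; y2 <- anchor$y2
  dy <- if (y2 >= y1) gap / 2 else -gap / 2
  if (style == "edge") {
    d <- sprintf("M %s %s C %s %s, %s %s, %s %s",
                 fmt_px(x1), fmt_px(y1), fmt_px(x1), fmt_px(y1 + dy),
                 fmt_px(x2), fmt_px(y2 - dy), fmt_px(x2), fmt_px(y2))
    return(list(d = d, closed = FALSE))
  }
  h1 <- max(anchor$w1, 2) / 2
  h2 <- max(anchor$w2, 2) / 2
  d <- sprintf(paste0("M %s %s C %s %s, %s %s, %s %s ",
                      "L %s %s C %s %s, %s %s, %s %s Z"),
               fmt_px(x1 - h1), fmt_px(y1),
               fmt_px(x1 - h1), fmt_px(y1 + dy),
               fmt_px(x2 - h2), fmt_px(y2 - dy),
               fmt_px(x2 - h2), fmt_px(y2),
               fmt_px(x2 + h2), fmt_px(y2),
               fmt_px(x2 + h2), fmt_px(y2 - dy),
               fmt_px(x1 + h1), fmt_px(y1 + dy),
               fmt_px(x1 + h1), fmt_px(y1))
  list(d = d, closed = TRUE)
}

#' Color links and build their legend
#'
#' Categorical link values map category -> color in first-appearance order
#' (cycling the palette); numeric values map through
#' \code{\link{heatmap_color}} over the palette as ramp anchors; valueless
#' links all take the first palette color, unless \code{distinct = TRUE},
#' which gives every link its own color (e.g. one color per orthologous
#' pair). The legend lists each category once, one entry per link pair in
#' distinct mode, or a numeric min/max scale.
#'
#' @param links data.frame from \code{\link{read_link_file}}.
#' @param palette ordered colors.
#' @param distinct give every valueless link its own palette color.
#' @return list: \code{colors} (per link), \code{legend} (data.frame
#'   \code{label}, \code{color}).
#' @export
link_colors <- function(links, palette = default_palette(), distinct = FALSE) {
  n <- nrow(links)
  pal <- to_hex(palette)
  has_num <- !is.na(links$value_num)
  has_cat <- !has_num & !is.na(links$value)
  if (any(has_num) && !any(has_cat)) {
    rng <- range(links$value_num[has_num])
    colors <- heatmap_color(links$value_num, rng[1], rng[2], palette)
    colors[is.na(colors)] <- pal[1]
    legend <- data.frame(label = sprintf(c("min (%g)", "max (%g)"), rng),
                         color = heatmap_color(rng, rng[1], rng[2], palette),
                         stringsAsFactors = FALSE)
  } else if (any(has_cat)) {
    cc <- category_colors(ifelse(has_cat, links$value, NA), palette)
    colors <- cc$colors
    colors[is.na(colors)] <- pal[1]
    legend <- cc$legend
  } else if (distinct) {
    colors <- rep_len(pal, n)
    legend <- data.frame(label = paste0(links$source, "-", links$target),
                         color = colors, stringsAsFactors = FALSE)
  } else {
    colors <- rep(pal[1], n)
    legend <- data.frame(label = "link", color = pal[1],
                         stringsAsFactors = FALSE)[0, ]
  }
  list(colors = colors, legend = legend)
}
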