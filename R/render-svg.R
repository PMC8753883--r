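# SVG emission.
#
# A scene (built by run_pipeline / build_scene) is a plain list of drawable
# tables; render_svg() turns it into markup by deterministic string assembly,
# so identical inputs give byte-identical output. Every window rectangle
# carries a stable id "set.chrom.w<index>" and class "window"; marks, links,
# labels and legend entries carry classes "mark", "link", "label",
# "legend-entry" so documents can be audited by recounting primitives.

svg_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  if (length(kv) == 0L) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(kv), unlist(kv)), collapse = " "))
}

#' Render a scene to a standalone SVG document
#'
#' @param scene a scene list as produced by \code{\link{build_scene}}.
#' @return object of class \code{rendered_document}: list with
#'   \code{format = "svg"}, \code{payload} (single character string of
#'   well-formed markup) and \code{manifest} (counts of drawn primitives:
#'   \code{windows}, \code{marks}, \code{links}, \code{labels},
#'   \code{legends}, \code{anchors}).
#' @export
render_svg <- function(scene) {
  W <- scene$canvas$width
  H <- scene$canvas$height
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" xmlns:xlink="http://www.w3.org/1999/xlink" width="%g" height="%g" viewBox="0 0 %g %g">',
            W, H, W, H),
    sprintf('<rect width="%g" height="%g" fill="#ffffff"/>', W, H))

  any_directed <- !is.null(scene$links) && nrow(scene$links) > 0 &&
    any(scene$links$directed)
  if (any_directed) {
    out <- c(out,
      '<defs><marker id="arrow" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="6" markerHeight="6" orient="auto-start-reverse"><path d="M 0 0 L 10 5 L 0 10 z" fill="#555555"/></marker></defs>')
  }
  if (!is.null(scene$title)) {
    out <- c(out, sprintf(
      '<text class="title" x="%s" y="16" font-family="sans-serif" font-size="14" font-weight="bold">%s</text>',
      fmt_px(W / 2), xml_escape(scene$title)))
  }

  g <- scene$chrom_labels
  if (!is.null(g) && nrow(g)) {
    out <- c(out, sprintf(
      '<text class="chrom-name" x="%s" y="%s" font-family="sans-serif" font-size="11" text-anchor="end">%s</text>',
      fmt_px(g$x), fmt_px(g$y), xml_escape(g$text)))
  }

  w <- scene$windows
  if (!is.null(w) && nrow(w)) {
    out <- c(out, sprintf(
      '<rect class="window" id="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#666666" stroke-width="0.3"/>',
      xml_escape(w$key), fmt_px(w$x), fmt_px(w$y), fmt_px(w$w), fmt_px(w$h), w$fill))
  }

  cen <- scene$centromeres
  if (!is.null(cen) && nrow(cen)) {
    out <- c(out, sprintf(
      '<circle class="centromere" cx="%s" cy="%s" r="%s" fill="#333333"/>',
      fmt_px(cen$x), fmt_px(cen$y), fmt_px(cen$r)))
  }

  rl <- scene$ref_lines
  if (!is.null(rl) && nrow(rl)) {
    out <- c(out, sprintf(
      '<line class="refline" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="1" stroke-dasharray="4,3"/>',
      fmt_px(rl$x1), fmt_px(rl$y), fmt_px(rl$x2), fmt_px(rl$y)))
  }

  m <- scene$marks
  n_anchors <- 0L
  if (!is.null(m) && nrow(m)) {
    for (i in seq_len(nrow(m))) {
      el <- if (m$kind[i] == "point") {
        sprintf('<circle class="mark" cx="%s" cy="%s" r="2.5" fill="%s"/>',
                fmt_px(m$x[i]), fmt_px(m$y[i]), m$color[i])
      } else {
        sprintf('<rect class="mark" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                fmt_px(m$x[i]), fmt_px(m$y[i]), fmt_px(m$w[i]), fmt_px(m$h[i]),
                m$color[i])
      }
      if (!is.na(m$href[i])) {
        n_anchors <- n_anchors + 1L
        el <- sprintf('<a xlink:href="%s" href="%s" target="_blank">%s</a>',
                      xml_escape(m$href[i]), xml_escape(m$href[i]), el)
      }
      out <- c(out, el)
    }
  }

  lk <- scene$links
  if (!is.null(lk) && nrow(lk)) {
    out <- c(out, vapply(seq_len(nrow(lk)), function(i) {
      if (lk$closed[i]) {
        sprintf('<path class="link" d="%s" fill="%s" fill-opacity="0.45" stroke="none"/>',
                lk$d[i], lk$color[i])
      } else {
        sprintf('<path class="link" d="%s" fill="none" stroke="%s" stroke-width="1.5"%s/>',
                lk$d[i], lk$color[i],
                if (lk$directed[i]) ' marker-end="url(#arrow)"' else "")
      }
    }, character(1)))
  }

  lb <- scene$labels
  if (!is.null(lb) && nrow(lb)) {
    out <- c(out, sprintf(
      '<text class="label" x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="middle">%s</text>',
      fmt_px(lb$x), fmt_px(lb$y), xml_escape(lb$text)))
  }

  lg <- scene$legends
  if (!is.null(lg) && nrow(lg)) {
    ly <- H - 14 * (nrow(lg) - seq_len(nrow(lg))) - 10
    out <- c(out, '<g class="legend">',
             sprintf('<rect class="legend-swatch" x="%s" y="%s" width="10" height="10" fill="%s"/>',
                     fmt_px(rep(10, nrow(lg))), fmt_px(ly - 9), lg$color),
             sprintf('<text class="legend-entry" x="25" y="%s" font-family="sans-serif" font-size="10">%s</text>',
                     fmt_px(ly), xml_escape(lg$label)),
             '</g>')
  }

  out <- c(out, "</svg>")
  structure(list(format = "svg", payload = paste(out, collapse = "\n"),
                 manifest = list(
                   windows = if (is.null(scene$windows)) 0L else nrow(scene$windows),
                   marks = if (is.null(m)) 0L else nrow(m),
                   links = if (is.null(lk)) 0L else nrow(lk),
                   labels = if (is.null(lb)) 0L else nrow(lb),
                   legends = if (is.null(lg)) 0L else nrow(lg),
                   anchors = n_anchors)),
            class = "rendered_document")
}

#' @export
print.rendered_document <- function(x, ...) {
  cat(sprintf("<rendered %s document: %d bytes; %s>\n", x$format,
              nchar(x$payload, type = "bytes"),
              paste(sprintf("%s=%d", names(x$manifest), unlist(x$manifest)),
                    collapse = " ")))
  invisible(x)
}

#' Write a rendered document to a file
#'
#' @param doc a \code{rendered_document} (svg or html).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_document <- function(doc, path) {
  stopifnot(inherits(doc, "rendered_document"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(doc$payload), con)
  invisible(path)
}
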