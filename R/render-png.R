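# Static raster export.
#
# The PNG is drawn from the same laid-out scene geometry through R's native
# png() graphics device (cairo), one grid primitive per drawable, at a pixel
# size of canvas * dpi / 96 — doubling dpi doubles both dimensions. Drawing
# from the geometry (rather than from the SVG byte stream) keeps the raster
# pipeline dependency-free while guaranteeing the same canvas and the same
# primitives as the vector output.

#' Render a scene to a PNG file
#'
#' @param scene a scene list as produced by \code{\link{build_scene}}.
#' @param path output file path.
#' @param dpi resolution; the image is
#'   \code{canvas_width * dpi / 96} by \code{canvas_height * dpi / 96} pixels.
#' @return a \code{rendered_document} with \code{format = "png"} whose
#'   \code{payload} is the raw PNG bytes; the file is written to \code{path}.
#' @export
render_png <- function(scene, path, dpi = 96) {
  if (!capabilities("png")) {
    stop(paste("PNG export needs R compiled with png/cairo support",
               "(capabilities('png') is FALSE); export SVG or HTML instead,",
               "or rasterize the SVG with an external tool"), call. = FALSE)
  }
  svg_doc <- render_svg(scene)
  cw <- scene$canvas$width
  ch <- scene$canvas$height
  grDevices::png(path, width = cw * dpi / 96, height = ch * dpi / 96,
                 type = "cairo")
  ok <- FALSE
  on.exit(if (!ok) grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  grid::pushViewport(grid::viewport(xscale = c(0, cw), yscale = c(0, ch)))
  nx <- function(v) grid::unit(v, "native")
  ny <- function(v) grid::unit(ch - v, "native")  # scene y runs top-down

  w <- scene$windows
  if (!is.null(w) && nrow(w)) {
    grid::grid.rect(x = nx(w$x), y = ny(w$y + w$h),
                    width = nx(w$w) - nx(0), height = nx(w$h) - nx(0),
                    just = c("left", "bottom"),
                    gp = grid::gpar(fill = w$fill, col = "#666666", lwd = 0.3))
  }
  m <- scene$marks
  if (!is.null(m) && nrow(m)) {
    pts <- m[m$kind == "point", , drop = FALSE]
    if (nrow(pts)) {
      grid::grid.points(x = nx(pts$x), y = ny(pts$y), pch = 16,
                        size = grid::unit(3, "pt"),
                        gp = grid::gpar(col = pts$color))
    }
    bars <- m[m$kind == "bar", , drop = FALSE]
    if (nrow(bars)) {
      grid::grid.rect(x = nx(bars$x), y = ny(bars$y + bars$h),
                      width = nx(bars$w) - nx(0), height = nx(bars$h) - nx(0),
                      just = c("left", "bottom"),
                      gp = grid::gpar(fill = bars$color, col = NA))
    }
  }
  rl <- scene$ref_lines
  if (!is.null(rl) && nrow(rl)) {
    for (i in seq_len(nrow(rl))) {
      grid::grid.lines(x = nx(c(rl$x1[i], rl$x2[i])), y = ny(rep(rl$y[i], 2)),
                       gp = grid::gpar(col = "#999999", lty = "dashed"))
    }
  }
  lb <- scene$labels
  if (!is.null(lb) && nrow(lb)) {
    grid::grid.text(lb$text, x = nx(lb$x), y = ny(lb$y),
                    gp = grid::gpar(fontsize = 7))
  }
  g <- scene$chrom_labels
  if (!is.null(g) && nrow(g)) {
    grid::grid.text(g$text, x = nx(g$x), y = ny(g$y), just = "right",
                    gp = grid::gpar(fontsize = 9))
  }
  grid::popViewport()
  grDevices::dev.off()
  ok <- TRUE
  payload <- readBin(path, "raw", n = file.info(path)$size)
  structure(list(format = "png", payload = payload,
                 manifest = svg_doc$manifest),
            class = "rendered_document")
}
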