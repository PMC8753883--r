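# End-to-end pipeline: read -> validate -> window -> assign -> aggregate ->
# filter -> layout -> links -> render.
#
# A PlotConfig carries every knob as a named field; unknown names are
# rejected at construction, and cross-option conflicts (e.g. a heatmap with no
# data column) fail before any output file is written. Multitrack (polyploid)
# plots pass one chromosome file and one annotation file per track set;
# windows are planned independently per set so sets of different size and
# number each fill the canvas.

PLOT_TYPES <- c("annotation", "heatmap", "scatter", "bar")
AGG_OPS <- c("count", "sum", "mean", "min", "max")

#' Construct a validated plot configuration
#'
#' @param chromosome_files character vector of chromosome file paths, one per
#'   track set.
#' @param annotation_files annotation file paths, parallel to
#'   \code{chromosome_files} (same length).
#' @param link_file optional link file path.
#' @param mode annotation algorithm: \code{"point"} (single anchor base) or
#'   \code{"segment"} (all overlapped windows).
#' @param anchor point-annotation anchor: \code{"start"} or \code{"midpoint"}.
#' @param plot_type \code{"annotation"} (presence/group fill),
#'   \code{"heatmap"}, \code{"scatter"} or \code{"bar"}.
#' @param aggregate_op per-window aggregation: \code{"count"}, \code{"sum"},
#'   \code{"mean"}, \code{"min"}, \code{"max"}.
#' @param filters list of \code{\link{filter_spec}} objects or CLI filter
#'   strings (see \code{\link{parse_filter}}).
#' @param n_windows target window count for the longest chromosome of each
#'   set (ignored when \code{window_size} given).
#' @param window_size explicit window width in bp.
#' @param zero_based,header passed to the file readers.
#' @param canvas_width,track_height,spacing,chrom_height canvas geometry (px).
#' @param y_reference optional dashed baseline value for scatter/bar tracks.
#' @param y_range optional length-2 numeric y range override.
#' @param colors heatmap ramp anchors, mark color, or categorical palette.
#' @param labels draw static feature labels.
#' @param common_scale one global bp-per-px scale across sets.
#' @param link_style \code{"edge"} or \code{"ribbon"}.
#' @param link_distinct one distinct color per valueless link.
#' @param title plot title.
#' @param out output path (extension selects the format when \code{format}
#'   is \code{NULL}).
#' @param format \code{"html"}, \code{"svg"} or \code{"png"}.
#' @param quiet suppress console warnings about dropped annotations.
#' @param seed integer seed; reserved for stochastic style options (jitter),
#'   never affects category colors or geometry.
#' @return object of class \code{plot_config} (a validated named list).
#' @export
plot_config <- function(chromosome_files, annotation_files,
                        link_file = NULL,
                        mode = c("point", "segment"),
                        anchor = c("start", "midpoint"),
                        plot_type = PLOT_TYPES,
                        aggregate_op = AGG_OPS,
                        filters = list(),
                        n_windows = 500, window_size = NULL,
                        zero_based = FALSE, header = FALSE,
                        canvas_width = 1000, track_height = 80,
                        spacing = 40, chrom_height = 24,
                        y_reference = NULL, y_range = NULL,
                        colors = NULL, labels = FALSE,
                        common_scale = FALSE,
                        link_style = c("edge", "ribbon"),
                        link_distinct = FALSE,
                        title = NULL, out = NULL, format = NULL,
                        quiet = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  plot_type <- match.arg(plot_type)
  aggregate_op <- match.arg(aggregate_op)
  link_style <- match.arg(link_style)
  if (length(chromosome_files) < 1L) {
    stop("at least one chromosome file is required", call. = FALSE)
  }
  if (length(annotation_files) != length(chromosome_files)) {
    stop(sprintf(
      "need one annotation file per chromosome file (%d chromosome file(s), %d annotation file(s))",
      length(chromosome_files), length(annotation_files)), call. = FALSE)
  }
  filters <- lapply(filters, function(f) {
    if (inherits(f, "filter_spec")) f else parse_filter(f)
  })
  if (!is.null(format) && !format %in% c("html", "svg", "png")) {
    stop(sprintf("unknown output format '%s'", format), call. = FALSE)
  }
  if (is.null(format) && !is.null(out)) {
    ext <- tolower(tools::file_ext(out))
    if (!ext %in% c("html", "svg", "png")) {
      stop(sprintf("cannot infer output format from '%s'; use format=", out),
           call. = FALSE)
    }
    format <- ext
  }
  if (!is.null(y_range) && (length(y_range) != 2L || y_range[1] > y_range[2])) {
    stop("y_range must be c(min, max) with min <= max", call. = FALSE)
  }
  structure(list(
    chromosome_files = chromosome_files, annotation_files = annotation_files,
    link_file = link_file, mode = mode, anchor = anchor,
    plot_type = plot_type, aggregate_op = aggregate_op, filters = filters,
    n_windows = n_windows, window_size = window_size,
    zero_based = zero_based, header = header,
    canvas_width = canvas_width, track_height = track_height,
    spacing = spacing, chrom_height = chrom_height,
    y_reference = y_reference, y_range = y_range,
    colors = colors, labels = labels, common_scale = common_scale,
    link_style = link_style, link_distinct = link_distinct,
    title = title, out = out, format = format %||% "html",
    quiet = quiet, seed = as.integer(seed)), class = "plot_config")
}

EMPTY_FILL <- "#f0f0f0"
PRESENCE_FILL <- "#41ab5d"

# Build all drawables for processed track sets. Each element of `sets` is a
# list: set_id, chromosomes, annotations (kept), plan, agg (aggregate_windows
# result), report.
#' Assemble the drawable scene
#'
#' Turns processed track sets into the flat drawable tables consumed by
#' \code{\link{render_svg}}, \code{\link{render_html}} and
#' \code{\link{render_png}}: window rectangles with fills, scatter/bar marks,
#' reference lines, labels, link paths, legends and per-window tooltip
#' records. Normally called through \code{\link{run_pipeline}}.
#'
#' @param sets list of processed sets (\code{set_id}, \code{chromosomes},
#'   \code{annotations}, \code{plan}, \code{agg}).
#' @param cfg a \code{\link{plot_config}}.
#' @param links optional data.frame from \code{\link{read_link_file}}.
#' @return a scene list (canvas, windows, marks, ref_lines, labels, links,
#'   legends, tooltips, chrom_labels, centromeres, title).
#' @export
build_scene <- function(sets, cfg, links = NULL) {
  layout <- layout_tracks(sets,
                          canvas_width = cfg$canvas_width,
                          spacing = cfg$spacing,
                          chrom_height = cfg$chrom_height,
                          track_height = if (cfg$plot_type %in% c("scatter", "bar"))
                            cfg$track_height else 0,
                          common_scale = cfg$common_scale)
  palette <- if (!is.null(cfg$colors) && length(cfg$colors) > 1L)
    cfg$colors else default_palette()
  heat_anchors <- cfg$colors %||% c("white", "steelblue")
  if (length(heat_anchors) < 2L) heat_anchors <- c("white", heat_anchors)

  windows <- list(); marks <- list(); ref_lines <- list(); labels <- list()
  tooltips <- list(); legends <- list()
  chrom_labels <- list(); centromeres <- list()

  # global heatmap range so color is comparable across chromosomes of a set
  heat_rng <- NULL
  if (cfg$plot_type == "heatmap") {
    all_v <- unlist(lapply(sets, function(s) s$agg$agg_value))
    all_v <- all_v[!is.na(all_v)]
    if (length(all_v) == 0L) {
      stop("heatmap requires numeric annotation data (no numeric values found)",
           call. = FALSE)
    }
    heat_rng <- range(all_v)
  }

  # global category order (first appearance across sets) so a category keeps
  # one color on every chromosome and the legend lists each exactly once
  cat_levels <- unique(unlist(lapply(sets, function(s) {
    v <- s$annotations
    v$value[is.na(v$value_num) & !is.na(v$value)]
  })))
  if (length(cat_levels) && cfg$plot_type != "heatmap") {
    legends[[length(legends) + 1L]] <-
      category_colors(cat_levels, palette, levels = cat_levels)$legend
  }

  for (s in sets) {
    for (ci in seq_len(nrow(s$chromosomes))) {
      chrom <- s$chromosomes[ci, ]
      box <- layout$boxes[layout$boxes$set_id == s$set_id &
                          layout$boxes$chrom == chrom$name, , drop = FALSE]
      aw <- s$agg[s$agg$chrom == chrom$name, , drop = FALSE]
      feats <- s$annotations[s$annotations$chrom == chrom$name, , drop = FALSE]
      nw <- box$n_windows
      win_w <- box$width / nw

      fill <- rep(EMPTY_FILL, nw)
      occupied <- aw$n_members > 0
      if (cfg$plot_type == "heatmap") {
        has <- !is.na(aw$agg_value)
        fill[has] <- heatmap_color(aw$agg_value[has], heat_rng[1], heat_rng[2],
                                   heat_anchors)
      } else {
        # presence fill; group-annotated windows take their majority category color
        fill[occupied] <- if (length(cfg$colors) == 1L)
          to_hex(cfg$colors) else PRESENCE_FILL
        gc_cat <- vapply(aw$group_counts, function(g) {
          if (length(g) == 0L) NA_character_ else names(g)[which.max(g)]
        }, character(1))
        if (any(!is.na(gc_cat))) {
          cc <- category_colors(gc_cat, palette, levels = cat_levels)
          fill[!is.na(gc_cat)] <- cc$colors[!is.na(gc_cat)]
        }
      }

      wkey <- sprintf("%s.%s.w%d", s$set_id, chrom$name, aw$index)
      windows[[length(windows) + 1L]] <- data.frame(
        set_id = s$set_id, chrom = chrom$name, index = aw$index, key = wkey,
        x = box$x + aw$index * win_w, y = box$y, w = win_w, h = box$height,
        fill = fill, stringsAsFactors = FALSE)

      chrom_labels[[length(chrom_labels) + 1L]] <- data.frame(
        text = if (length(sets) > 1L)
          sprintf("%s %s", s$set_id, chrom$name) else chrom$name,
        x = box$x - 6, y = box$y + box$height / 2 + 4, stringsAsFactors = FALSE)

      if (!is.na(chrom$centromere)) {
        centromeres[[length(centromeres) + 1L]] <- data.frame(
          x = genomic_to_canvas(chrom$centromere, box, chrom),
          y = box$y + box$height / 2, r = box$height / 3)
      }

      if (cfg$plot_type %in% c("scatter", "bar")) {
        style <- list(plot_type = cfg$plot_type,
                      color = if (length(cfg$colors) == 1L) to_hex(cfg$colors) else NULL,
                      palette = palette, category_levels = cat_levels,
                      y_reference = cfg$y_reference, y_range = cfg$y_range,
                      anchor = cfg$anchor)
        tr <- place_data_track(features = feats, agg = aw, style = style,
                               box = box, chrom = chrom)
        tr$marks$set_id <- rep(s$set_id, nrow(tr$marks))
        tr$marks$href <- if (nrow(tr$marks) && tr$marks$kind[1] == "point")
          feats$hyperlink[match(tr$marks$id, feats$element_id)]
        else rep(NA_character_, nrow(tr$marks))
        marks[[length(marks) + 1L]] <- tr$marks
        if (!is.null(tr$ref_y)) {
          ref_lines[[length(ref_lines) + 1L]] <- data.frame(
            x1 = box$x, x2 = box$x + box$width, y = tr$ref_y)
        }
        # categorical track legends are already covered by the global
        # category legend added above (identical rows dedupe via unique())
      } else if (nrow(feats) > 0 && any(!is.na(feats$hyperlink))) {
        # annotation/heatmap plots: hyperlinked features get a small mark
        hf <- feats[!is.na(feats$hyperlink), , drop = FALSE]
        marks[[length(marks) + 1L]] <- data.frame(
          kind = "point", id = hf$element_id,
          x = genomic_to_canvas(hf$start, box, chrom),
          y = box$y - 4, w = 0, h = 0, color = "#555555",
          category = NA_character_, set_id = s$set_id,
          href = hf$hyperlink, stringsAsFactors = FALSE)
      }

      if (isTRUE(cfg$labels) && nrow(feats) > 0) {
        pl <- place_labels(feats, box, chrom)
        if (nrow(pl)) {
          labels[[length(labels) + 1L]] <- data.frame(
            text = pl$text, x = pl$x, y = box$label_y + pl$row * 11,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  windows <- do.call(rbind, windows)
  marks <- if (length(marks)) do.call(rbind, marks) else NULL

  # filters: independent mark layers, later filters paint over earlier ones
  window_tags <- stats::setNames(vector("list", nrow(windows)), windows$key)
  for (fs in cfg$filters) {
    if (fs$scope == "window") {
      for (s in sets) {
        hit <- apply_filter(fs, s$agg)  # "chrom:index" keys
        if (length(hit)) {
          hk <- sprintf("%s.%s.w%s", s$set_id,
                        sub(":[0-9]+$", "", hit), sub("^.*:", "", hit))
          windows$fill[windows$key %in% hk] <- to_hex(fs$color)
          for (k in hk) {
            window_tags[[k]] <- c(window_tags[[k]], fs$label %||% "filtered")
          }
        }
      }
    } else {
      for (s in sets) {
        hit <- apply_filter(fs, s$annotations)
        if (length(hit) && !is.null(marks)) {
          sel <- marks$set_id == s$set_id & marks$id %in% hit &
            marks$kind == "point"
          marks$color[sel] <- to_hex(fs$color)
        }
      }
    }
    if (!is.null(fs$label)) {
      legends[[length(legends) + 1L]] <- data.frame(
        label = fs$label, color = to_hex(fs$color), stringsAsFactors = FALSE)
    }
  }

  # links
  link_paths <- NULL
  if (!is.null(links) && nrow(links) > 0) {
    anchors <- resolve_link_anchors(links, layout, sets)
    lc <- link_colors(links, palette = cfg$colors %||% default_palette(),
                      distinct = cfg$link_distinct)
    geo <- lapply(seq_len(nrow(links)), function(i) {
      link_geometry(anchors[i, ], style = cfg$link_style, gap = cfg$spacing)
    })
    link_paths <- data.frame(
      d = vapply(geo, `[[`, character(1), "d"),
      closed = vapply(geo, `[[`, logical(1), "closed"),
      color = lc$colors, directed = links$directed, stringsAsFactors = FALSE)
    if (nrow(lc$legend)) legends[[length(legends) + 1L]] <- lc$legend
  }

  legends <- if (length(legends)) unique(do.call(rbind, legends)) else NULL

  # tooltips: one record per window
  for (s in sets) {
    for (i in seq_len(nrow(s$agg))) {
      aw <- s$agg[i, , drop = FALSE]
      key <- sprintf("%s.%s.w%d", s$set_id, aw$chrom, aw$index)
      tooltips[[key]] <- build_tooltip_payload(
        aw, s$annotations, tags = unique(window_tags[[key]] %||% character(0)),
        agg_op = cfg$aggregate_op)
    }
  }

  height <- layout$canvas$height +
    (if (!is.null(legends)) 14 * nrow(legends) + 16 else 0) +
    (if (!is.null(cfg$title)) 22 else 0)

  list(canvas = list(width = cfg$canvas_width, height = height),
       title = cfg$title,
       boxes = layout$boxes,
       windows = windows,
       marks = marks,
       ref_lines = if (length(ref_lines)) do.call(rbind, ref_lines) else NULL,
       labels = if (length(labels)) do.call(rbind, labels) else NULL,
       links = link_paths,
       legends = legends,
       tooltips = tooltips,
       chrom_labels = do.call(rbind, chrom_labels),
       centromeres = if (length(centromeres)) do.call(rbind, centromeres) else NULL,
       layout = layout)
}

#' Run the full pipeline
#'
#' Reads and validates all input files, plans and builds windows per track
#' set, assigns and aggregates annotations, applies filters, lays out the
#' canvas, resolves links, renders, and (when \code{cfg$out} is set) writes
#' the output file. Dropped annotations are a console warning, never a
#' failure; structurally invalid input files raise errors before any output
#' is written.
#'
#' @param cfg a \code{\link{plot_config}}.
#' @return list with \code{document} (\code{rendered_document}),
#'   \code{reports} (per-set \code{chromocanvas_validation}), \code{scene},
#'   and \code{sets} (processed per-set data), invisibly.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines("chr1\t1\t1000", file.path(dir, "chrom.tsv"))
#' writeLines(c("geneA\tchr1\t10\t50\t2.5", "geneB\tchr1\t400\t420\t-1"),
#'            file.path(dir, "ann.tsv"))
#' cfg <- plot_config(file.path(dir, "chrom.tsv"), file.path(dir, "ann.tsv"),
#'                    plot_type = "heatmap", aggregate_op = "mean",
#'                    n_windows = 10)
#' res <- run_pipeline(cfg)
#' res$document$manifest
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "plot_config"))
  n_sets <- length(cfg$chromosome_files)
  sets <- vector("list", n_sets)
  reports <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    chrom <- read_chromosome_file(cfg$chromosome_files[i],
                                  zero_based = cfg$zero_based,
                                  header = cfg$header)
    ann <- read_annotation_file(cfg$annotation_files[i],
                                zero_based = cfg$zero_based,
                                header = cfg$header)
    rep_ <- validate_annotations(ann, chrom)
    if (!isTRUE(cfg$quiet)) emit_console_diagnostics(rep_)
    plan <- plan_windows(chrom, target_windows = cfg$n_windows,
                         window_size = cfg$window_size)
    asg <- assign_annotations(rep_$kept, chrom, plan,
                              mode = cfg$mode, anchor = cfg$anchor)
    win <- build_windows_all(chrom, plan)
    agg <- aggregate_windows(win, asg, rep_$kept, op = cfg$aggregate_op)
    sets[[i]] <- list(set_id = sprintf("set%d", i), chromosomes = chrom,
                      annotations = rep_$kept, plan = plan, agg = agg)
    reports[[i]] <- rep_
  }

  # pre-flight: data-dependent plot types need numeric (or categorical, for
  # scatter) data before anything is written
  if (cfg$plot_type %in% c("heatmap", "bar")) {
    any_num <- any(vapply(sets, function(s) any(!is.na(s$annotations$value_num)),
                          logical(1)))
    if (!any_num) {
      stop(sprintf(
        "plot type '%s' requires a numeric annotation data column, but none was found",
        cfg$plot_type), call. = FALSE)
    }
  }
  if (cfg$plot_type == "scatter") {
    any_data <- any(vapply(sets, function(s) any(!is.na(s$annotations$value)),
                           logical(1)))
    if (!any_data) {
      stop("plot type 'scatter' requires an annotation data column, but none was found",
           call. = FALSE)
    }
  }

  links <- if (!is.null(cfg$link_file)) read_link_file(cfg$link_file,
                                                       header = cfg$header)
           else NULL
  scene <- build_scene(sets, cfg, links = links)

  doc <- switch(cfg$format,
                svg = render_svg(scene),
                html = render_html(scene),
                png = {
                  if (is.null(cfg$out)) {
                    stop("png output requires an output path", call. = FALSE)
                  }
                  render_png(scene, cfg$out)
                })
  if (!is.null(cfg$out) && cfg$format != "png") write_document(doc, cfg$out)
  invisible(list(document = doc, reports = reports, scene = scene, sets = sets))
}
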