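# Fixed-width genomic windows.
#
# Every chromosome in a set is cut into contiguous, disjoint windows of one
# shared width w so that window counts are comparable across chromosomes:
# w = ceiling(L_max / target_windows), where L_max is the longest chromosome
# length (end - start + 1) in the set. The longest chromosome then gets exactly
# target_windows windows (fewer only when it is shorter than target_windows
# bp); all windows except possibly the last of each chromosome have width w.

#' Plan windows for a chromosome set
#'
#' @param chromosomes data.frame from \code{\link{read_chromosome_file}}.
#' @param target_windows desired window count for the longest chromosome in
#'   the set; ignored when \code{window_size} is given. Default 500, chosen so
#'   the longest chromosome fills a publication-width canvas at >= 2 px per
#'   window.
#' @param window_size explicit window width in bp (>= 1), overriding the
#'   computed width.
#' @return object of class \code{window_plan}: list with \code{window_size}
#'   (bp) and \code{counts} (named integer vector, chromosome -> window count,
#'   each \code{ceiling(length / window_size)}).
#' @examples
#' chrom <- data.frame(name = c("a", "b"), start = 1, end = c(100, 50))
#' plan_windows(chrom, target_windows = 10)
#' @export
plan_windows <- function(chromosomes, target_windows = 500, window_size = NULL) {
  stopifnot(is.data.frame(chromosomes), nrow(chromosomes) >= 1)
  len <- chromosomes$end - chromosomes$start + 1
  if (!is.null(window_size)) {
    if (!is.numeric(window_size) || length(window_size) != 1L || window_size < 1) {
      stop("window_size must be a single integer >= 1", call. = FALSE)
    }
    w <- floor(window_size)
  } else {
    if (!is.numeric(target_windows) || target_windows < 1) {
      stop("target_windows must be >= 1", call. = FALSE)
    }
    w <- max(1, ceiling(max(len) / target_windows))
  }
  counts <- ceiling(len / w)
  names(counts) <- chromosomes$name
  structure(list(window_size = w, counts = counts), class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window plan: width %g bp; %d chromosome(s), %g windows total>\n",
              x$window_size, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Build the windows of one chromosome
#'
#' Window k (0-based) spans
#' \code{[start + k*w, min(start + (k+1)*w - 1, end)]}: contiguous, disjoint,
#' exactly covering \code{[start, end]}; only the last window may be narrower.
#' A chromosome shorter than one window gets a single truncated window, never
#' zero.
#'
#' @param chrom one-row data.frame (or list) with \code{name}, \code{start},
#'   \code{end}.
#' @param plan a \code{window_plan} covering this chromosome.
#' @return data.frame with columns \code{chrom}, \code{index} (0-based),
#'   \code{span_start}, \code{span_end}.
#' @export
build_windows <- function(chrom, plan) {
  stopifnot(inherits(plan, "window_plan"))
  name <- as.character(chrom$name)
  if (!name %in% names(plan$counts)) {
    stop(sprintf("plan does not cover chromosome '%s'", name), call. = FALSE)
  }
  w <- plan$window_size
  n <- unname(plan$counts[[name]])
  k <- seq_len(n) - 1
  data.frame(chrom = name, index = k,
             span_start = chrom$start + k * w,
             span_end = pmin(chrom$start + (k + 1) * w - 1, chrom$end),
             stringsAsFactors = FALSE)
}

#' Build windows for every chromosome in a set
#'
#' @inheritParams plan_windows
#' @param plan a \code{window_plan} for the set.
#' @return row-bound data.frame of \code{\link{build_windows}} results, in
#'   chromosome file order.
#' @export
build_windows_all <- function(chromosomes, plan) {
  do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    build_windows(chromosomes[i, ], plan)
  }))
}

point_index <- function(pos, chrom_start, window_size, n_windows) {
  pmin(floor((pos - chrom_start) / window_size), n_windows - 1)
}

#' Point-annotation window index
#'
#' Point-annotation ignores a feature's size and places it on a single base
#' (its anchor). The window index is
#' \code{floor((anchor - chrom.start) / w)}, clamped to the last window.
#'
#' @param pos anchor base position (bp); must be in-bound (validate first).
#' @param chrom one-row chromosome data.frame or list.
#' @param plan the set's \code{window_plan}.
#' @return 0-based window index (vectorized over \code{pos}).
#' @export
assign_point <- function(pos, chrom, plan) {
  n <- unname(plan$counts[[as.character(chrom$name)]])
  if (any(pos < chrom$start | pos > chrom$end)) {
    stop("position out of chromosome bounds; run validate_annotations first",
         call. = FALSE)
  }
  point_index(pos, chrom$start, plan$window_size, n)
}

#' Segment-annotation window range
#'
#' Segment-annotation uses the feature's size: the feature occupies every
#' window whose span overlaps \code{[start, end]}, which is the contiguous
#' index range \code{[assign_point(start), assign_point(end)]}.
#'
#' @param start,end feature interval (bp), in-bound, \code{start <= end}.
#' @inheritParams assign_point
#' @return integer vector of 0-based window indices (contiguous).
#' @export
assign_segment <- function(start, end, chrom, plan) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  i1 <- assign_point(start, chrom, plan)
  i2 <- assign_point(end, chrom, plan)
  seq.int(i1, i2)
}

#' Assign validated annotations to windows
#'
#' @param annotations kept annotations (see \code{\link{validate_annotations}}).
#' @param chromosomes the set's chromosomes.
#' @param plan the set's \code{window_plan}.
#' @param mode \code{"point"} (single anchor base) or \code{"segment"} (every
#'   overlapped window).
#' @param anchor for point mode: \code{"start"} (default) or \code{"midpoint"}
#'   (\code{floor((start + end) / 2)}).
#' @return data.frame with one row per (feature, window) membership:
#'   \code{element_id}, \code{chrom}, \code{window} (0-based index),
#'   \code{ann_row} (row index into \code{annotations}).
#' @export
assign_annotations <- function(annotations, chromosomes, plan,
                               mode = c("point", "segment"),
                               anchor = c("start", "midpoint")) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  if (nrow(annotations) == 0L) {
    return(data.frame(element_id = character(0), chrom = character(0),
                      window = integer(0), ann_row = integer(0),
                      stringsAsFactors = FALSE))
  }
  ci <- match(annotations$chrom, chromosomes$name)
  if (anyNA(ci)) stop("annotation on unknown chromosome; validate first", call. = FALSE)
  nwin <- unname(plan$counts[match(annotations$chrom, names(plan$counts))])
  cstart <- chromosomes$start[ci]
  if (mode == "point") {
    pos <- if (anchor == "start") annotations$start
           else floor((annotations$start + annotations$end) / 2)
    idx <- point_index(pos, cstart, plan$window_size, nwin)
    data.frame(element_id = annotations$element_id, chrom = annotations$chrom,
               window = idx, ann_row = seq_len(nrow(annotations)),
               stringsAsFactors = FALSE)
  } else {
    i1 <- point_index(annotations$start, cstart, plan$window_size, nwin)
    i2 <- point_index(annotations$end, cstart, plan$window_size, nwin)
    reps <- i2 - i1 + 1
    data.frame(
      element_id = rep(annotations$element_id, reps),
      chrom = rep(annotations$chrom, reps),
      window = unlist(lapply(seq_along(i1), function(j) seq.int(i1[j], i2[j]))),
      ann_row = rep(seq_len(nrow(annotations)), reps),
      stringsAsFactors = FALSE)
  }
}
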