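# Tab-delimited readers for chromosome, annotation and link files.
#
# Files are UTF-8 TSV without a header row by default; lines that are blank or
# start with "#" are ignored. Coordinates are 1-based, fully closed intervals
# [start, end]; `zero_based = TRUE` converts BED-style 0-based half-open input
# on read (start + 1, end unchanged). Structural problems — wrong column count,
# non-integer coordinates, empty or duplicate identifiers — are hard failures
# that name the offending line; they are meant to terminate a CLI run with a
# console message. Semantic problems in annotations (unknown chromosome,
# out-of-bound coordinates, start > end) are never fatal: validate_annotations()
# drops those rows with a per-reason diagnostic and the plot is drawn from the
# rest.

read_tsv_rows <- function(path, header = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read '%s': file does not exist", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  idx <- which(keep)
  if (isTRUE(header) && length(idx) > 0L) idx <- idx[-1L]
  list(fields = strsplit(lines[idx], "\t", fixed = TRUE), line = idx)
}

bad_row <- function(path, line, why) {
  stop(sprintf("invalid input file '%s': line %d: %s", path, line, why),
       call. = FALSE)
}

parse_coord <- function(token, path, line, what) {
  if (!is_integer_token(token)) {
    bad_row(path, line, sprintf("%s '%s' is not an integer coordinate", what, token))
  }
  as.numeric(token)
}

#' Read a chromosome file
#'
#' One row per chromosome or chromosomal region to draw:
#' \code{name<TAB>start<TAB>end[<TAB>centromere]}. Names must be nonempty and
#' unique; \code{start <= end}; a centromere, when given, must lie inside
#' \code{[start, end]}. Any violation is a hard failure naming the offending
#' line (in a CLI run this terminates the program with a console message).
#'
#' @param path path to a tab-delimited file.
#' @param zero_based interpret coordinates as 0-based half-open (BED) and
#'   convert to the package's 1-based closed convention.
#' @param header skip one header line.
#' @return data.frame with columns \code{name}, \code{start}, \code{end},
#'   \code{centromere} (\code{NA} when absent), in file order.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t1\t1000\t400", "chr2\t1\t600"), p)
#' read_chromosome_file(p)
#' @export
read_chromosome_file <- function(path, zero_based = FALSE, header = FALSE) {
  rows <- read_tsv_rows(path, header = header)
  n <- length(rows$fields)
  out <- data.frame(name = character(n), start = numeric(n), end = numeric(n),
                    centromere = rep(NA_real_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- rows$fields[[i]]
    ln <- rows$line[i]
    if (length(f) < 3L || length(f) > 4L) {
      bad_row(path, ln, sprintf("expected 3 or 4 tab-separated fields, found %d", length(f)))
    }
    if (!nzchar(trimws(f[1]))) bad_row(path, ln, "empty chromosome name")
    start <- parse_coord(f[2], path, ln, "start")
    end <- parse_coord(f[3], path, ln, "end")
    if (zero_based) start <- start + 1
    if (start > end) {
      bad_row(path, ln, sprintf("start (%s) greater than end (%s)", f[2], f[3]))
    }
    cen <- NA_real_
    if (length(f) == 4L && nzchar(trimws(f[4]))) {
      cen <- parse_coord(f[4], path, ln, "centromere")
      if (zero_based) cen <- cen + 1
      if (cen < start || cen > end) {
        bad_row(path, ln, sprintf("centromere %s outside [%s, %s]", f[4], f[2], f[3]))
      }
    }
    out$name[i] <- trimws(f[1]); out$start[i] <- start; out$end[i] <- end
    out$centromere[i] <- cen
  }
  dup <- duplicated(out$name)
  if (any(dup)) {
    bad_row(path, rows$line[which(dup)[1]],
            sprintf("duplicate chromosome name '%s'", out$name[which(dup)[1]]))
  }
  out
}

#' Read an annotation file
#'
#' One feature per row:
#' \code{id<TAB>chrom<TAB>start<TAB>end[<TAB>value[<TAB>hyperlink]]}.
#' The value column is inferred per row: numeric when the whole token lexes as
#' a decimal number, otherwise kept as a category string. Wrong column counts,
#' non-integer coordinates and empty ids are hard failures; coordinate
#' semantics (bounds, start <= end) are checked later by
#' \code{\link{validate_annotations}}.
#'
#' @inheritParams read_chromosome_file
#' @return data.frame with columns \code{element_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{value} (raw string or \code{NA}),
#'   \code{value_num} (parsed numeric or \code{NA}), \code{hyperlink}.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("geneA\tchr1\t10\t50\t2.5",
#'              "geneB\tchr1\t60\t90\tpathwayX\thttp://example.org/geneB"), p)
#' read_annotation_file(p)
#' @export
read_annotation_file <- function(path, zero_based = FALSE, header = FALSE) {
  rows <- read_tsv_rows(path, header = header)
  n <- length(rows$fields)
  out <- data.frame(element_id = character(n), chrom = character(n),
                    start = numeric(n), end = numeric(n),
                    value = rep(NA_character_, n),
                    value_num = rep(NA_real_, n),
                    hyperlink = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- rows$fields[[i]]
    ln <- rows$line[i]
    if (length(f) < 4L || length(f) > 6L) {
      bad_row(path, ln, sprintf("expected 4 to 6 tab-separated fields, found %d", length(f)))
    }
    if (!nzchar(trimws(f[1]))) bad_row(path, ln, "empty element id")
    if (!nzchar(trimws(f[2]))) bad_row(path, ln, "empty chromosome name")
    start <- parse_coord(f[3], path, ln, "start")
    end <- parse_coord(f[4], path, ln, "end")
    if (zero_based) start <- start + 1
    out$element_id[i] <- trimws(f[1]); out$chrom[i] <- trimws(f[2])
    out$start[i] <- start; out$end[i] <- end
    if (length(f) >= 5L && nzchar(trimws(f[5]))) {
      tok <- trimws(f[5])
      out$value[i] <- tok
      if (is_numeric_token(tok)) out$value_num[i] <- as.numeric(tok)
    }
    if (length(f) == 6L && nzchar(trimws(f[6]))) out$hyperlink[i] <- trimws(f[6])
  }
  out
}

#' Read a link file
#'
#' One connection per row:
#' \code{source<TAB>target[<TAB>value[<TAB>directed]]}. Endpoints are either
#' element ids of annotated features or explicit loci written \code{"chrom:pos"}.
#' \code{directed} accepts \code{0/1}, \code{true/false}, \code{yes/no}
#' (case-insensitive); default undirected.
#'
#' @inheritParams read_chromosome_file
#' @return data.frame with columns \code{source}, \code{target}, \code{value}
#'   (raw string or \code{NA}), \code{value_num}, \code{directed} (logical).
#' @export
read_link_file <- function(path, header = FALSE) {
  rows <- read_tsv_rows(path, header = header)
  n <- length(rows$fields)
  out <- data.frame(source = character(n), target = character(n),
                    value = rep(NA_character_, n), value_num = rep(NA_real_, n),
                    directed = rep(FALSE, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- rows$fields[[i]]
    ln <- rows$line[i]
    if (length(f) < 2L || length(f) > 4L) {
      bad_row(path, ln, sprintf("expected 2 to 4 tab-separated fields, found %d", length(f)))
    }
    if (!nzchar(trimws(f[1])) || !nzchar(trimws(f[2]))) {
      bad_row(path, ln, "empty link endpoint")
    }
    out$source[i] <- trimws(f[1]); out$target[i] <- trimws(f[2])
    if (length(f) >= 3L && nzchar(trimws(f[3]))) {
      tok <- trimws(f[3])
      out$value[i] <- tok
      if (is_numeric_token(tok)) out$value_num[i] <- as.numeric(tok)
    }
    if (length(f) == 4L && nzchar(trimws(f[4]))) {
      tok <- tolower(trimws(f[4]))
      if (tok %in% c("1", "true", "yes", "directed")) out$directed[i] <- TRUE
      else if (tok %in% c("0", "false", "no", "undirected")) out$directed[i] <- FALSE
      else bad_row(path, ln, sprintf("cannot parse directed flag '%s'", f[4]))
    }
  }
  out
}

#' Validate annotations against chromosome bounds
#'
#' An annotation is kept iff its chromosome names a known entry and it is fully
#' contained in that chromosome's interval:
#' \code{chrom.start <= start} and \code{end <= chrom.end} (partial overlaps
#' are dropped). Rows whose chromosome is unknown drop with reason
#' \code{unknown-chromosome}; contained-coordinate failures drop with
#' \code{out-of-bound}; rows with \code{start > end} drop with
#' \code{malformed-row}. This operation never hard-fails: removal plus a
#' console-visible diagnostic is the contract, and rendering proceeds with the
#' kept rows.
#'
#' @param annotations data.frame from \code{\link{read_annotation_file}}.
#' @param chromosomes data.frame from \code{\link{read_chromosome_file}}.
#' @return object of class \code{chromocanvas_validation}: list with
#'   \code{kept} (data.frame), \code{dropped} (data.frame with added
#'   \code{reason} column), \code{messages} (character, one per drop reason).
#' @examples
#' chrom <- data.frame(name = "chr1", start = 1, end = 1000, centromere = NA)
#' ann <- data.frame(element_id = c("a", "b"), chrom = c("chr1", "chr1"),
#'                   start = c(10, 900), end = c(50, 1500),
#'                   value = NA, value_num = NA, hyperlink = NA)
#' validate_annotations(ann, chrom)
#' @export
validate_annotations <- function(annotations, chromosomes) {
  stopifnot(is.data.frame(annotations), is.data.frame(chromosomes))
  n <- nrow(annotations)
  reason <- rep(NA_character_, n)
  ci <- match(annotations$chrom, chromosomes$name)
  reason[is.na(ci)] <- "unknown-chromosome"
  malformed <- is.na(reason) & annotations$start > annotations$end
  reason[malformed] <- "malformed-row"
  inb <- is.na(reason) &
    annotations$start >= chromosomes$start[ci] &
    annotations$end <= chromosomes$end[ci]
  reason[is.na(reason) & !inb] <- "out-of-bound"

  kept <- annotations[is.na(reason), , drop = FALSE]
  dropped <- annotations[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  rownames(kept) <- NULL; rownames(dropped) <- NULL

  messages <- character(0)
  if (any(reason %in% "out-of-bound", na.rm = TRUE)) {
    k <- sum(reason %in% "out-of-bound")
    messages <- c(messages, sprintf(
      "%d annotation%s with coordinates outside the target chromosome boundary removed",
      k, if (k == 1L) "" else "s"))
  }
  if (any(reason %in% "unknown-chromosome", na.rm = TRUE)) {
    bad <- unique(annotations$chrom[reason %in% "unknown-chromosome"])
    messages <- c(messages, sprintf(
      "%d annotation%s on unknown chromosome%s (%s) removed",
      sum(reason %in% "unknown-chromosome"),
      if (sum(reason %in% "unknown-chromosome") == 1L) "" else "s",
      if (length(bad) == 1L) "" else "s", paste(bad, collapse = ", ")))
  }
  if (any(reason %in% "malformed-row", na.rm = TRUE)) {
    messages <- c(messages, sprintf(
      "%d annotation%s with start > end removed", sum(reason %in% "malformed-row"),
      if (sum(reason %in% "malformed-row") == 1L) "" else "s"))
  }
  structure(list(kept = kept, dropped = dropped, messages = messages),
            class = "chromocanvas_validation")
}

#' @export
print.chromocanvas_validation <- function(x, ...) {
  cat(sprintf("<chromocanvas validation: %d kept, %d dropped>\n",
              nrow(x$kept), nrow(x$dropped)))
  for (m in x$messages) cat(" ", m, "\n")
  invisible(x)
}

#' Print validation diagnostics on the console
#'
#' Emits one warning line per drop reason to standard error; silent when
#' nothing was dropped.
#'
#' @param report a \code{chromocanvas_validation} object.
#' @return the report, invisibly.
#' @export
emit_console_diagnostics <- function(report) {
  stopifnot(inherits(report, "chromocanvas_validation"))
  for (m in report$messages) message("warning: ", m)
  invisible(report)
}
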