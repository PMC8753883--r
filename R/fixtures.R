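# Seeded synthetic fixtures.
#
# Generates chromosome / annotation / link TSVs in the package's file dialect
# together with a JSON sidecar manifest recording the ground truth: which
# feature ids were deliberately written out-of-bound, and each in-bound
# feature's point-window assignment computed by a naive linear scan over
# enumerated window spans (independent of the arithmetic index formula used by
# the engine). Feature start positions are uniform over the chromosome;
# chromosome lengths are uniform over length_range. Everything derives from
# one integer seed, so a spec written twice produces byte-identical files.

#' Construct a fixture specification
#'
#' @param n_sets number of chromosome sets (track sets).
#' @param chroms_per_set chromosomes per set.
#' @param length_range chromosome length range in bp, \code{c(min, max)}.
#' @param n_features total feature count (split evenly across sets).
#' @param value_model \code{"none"}, \code{"normal"}, \code{"lognormal"} or
#'   \code{"categorical"}.
#' @param value_mean,value_sd parameters of the normal / lognormal value
#'   model (log-scale for lognormal).
#' @param categories number of category levels for the categorical model.
#' @param oob_fraction fraction of features written deliberately out-of-bound
#'   (coordinates beyond the chromosome end); exactly
#'   \code{round(oob_fraction * n_features)} features.
#' @param feature_span_range feature length range in bp.
#' @param hyperlink_fraction fraction of in-bound features given a hyperlink.
#' @param n_links number of feature-to-feature links.
#' @param directed_fraction fraction of links flagged directed.
#' @param target_windows window target used for the manifest's naive window
#'   oracle.
#' @param seed integer seed controlling every random draw.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_sets = 1, chroms_per_set = 3,
                         length_range = c(5e5, 2e6),
                         n_features = 100,
                         value_model = c("none", "normal", "lognormal",
                                         "categorical"),
                         value_mean = 0, value_sd = 1, categories = 3,
                         oob_fraction = 0, feature_span_range = c(200, 5000),
                         hyperlink_fraction = 0, n_links = 0,
                         directed_fraction = 0, target_windows = 500,
                         seed = 1L) {
  value_model <- match.arg(value_model)
  stopifnot(n_sets >= 1, chroms_per_set >= 1, n_features >= 0,
            oob_fraction >= 0, oob_fraction <= 1,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            n_links >= 0)
  structure(list(n_sets = n_sets, chroms_per_set = chroms_per_set,
                 length_range = length_range, n_features = n_features,
                 value_model = value_model, value_mean = value_mean,
                 value_sd = value_sd, categories = categories,
                 oob_fraction = oob_fraction,
                 feature_span_range = feature_span_range,
                 hyperlink_fraction = hyperlink_fraction,
                 n_links = n_links, directed_fraction = directed_fraction,
                 target_windows = target_windows, seed = as.integer(seed)),
            class = "fixture_spec")
}

# naive point-window oracle: enumerate spans, linear scan for the span
# containing the anchor base
naive_point_window <- function(pos, chrom_start, chrom_end, window_size) {
  starts <- seq(chrom_start, chrom_end, by = window_size)
  ends <- pmin(starts + window_size - 1, chrom_end)
  for (k in seq_along(starts)) {
    if (pos >= starts[k] && pos <= ends[k]) return(k - 1L)
  }
  NA_integer_
}

#' Generate a synthetic fixture on disk
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param outdir output directory (created if missing).
#' @return list of written file paths: \code{chromosome_files},
#'   \code{annotation_files} (one per set), \code{link_file} (or \code{NULL}),
#'   \code{manifest} (JSON sidecar with the ground truth).
#' @examples
#' fx <- generate_fixture(fixture_spec(n_features = 20, seed = 7), tempfile())
#' read_chromosome_file(fx$chromosome_files[1])
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop(sprintf("cannot create output directory '%s'", outdir), call. = FALSE)
    }
  }
  set.seed(spec$seed)

  chromosome_files <- character(spec$n_sets)
  annotation_files <- character(spec$n_sets)
  manifest <- list(seed = spec$seed, sets = list())
  all_features <- list()

  n_per_set <- diff(round(seq(0, spec$n_features, length.out = spec$n_sets + 1)))
  n_oob_total <- round(spec$oob_fraction * spec$n_features)
  oob_left <- n_oob_total

  for (si in seq_len(spec$n_sets)) {
    lens <- round(stats::runif(spec$chroms_per_set,
                               spec$length_range[1], spec$length_range[2]))
    chrom <- data.frame(
      name = sprintf("s%d_chr%d", si, seq_len(spec$chroms_per_set)),
      start = 1, end = lens,
      centromere = round(lens * stats::runif(spec$chroms_per_set, 0.3, 0.7)),
      stringsAsFactors = FALSE)
    cf <- file.path(outdir, sprintf("chromosomes_set%d.tsv", si))
    writeLines(sprintf("%s\t%d\t%d\t%d", chrom$name, chrom$start, chrom$end,
                       chrom$centromere), cf)
    chromosome_files[si] <- cf

    nf <- n_per_set[si]
    # exact out-of-bound budget: remaining sets share what is left
    n_oob <- if (si == spec$n_sets) oob_left
             else min(oob_left, round(spec$oob_fraction * nf))
    oob_left <- oob_left - n_oob
    ci <- sample.int(spec$chroms_per_set, nf, replace = TRUE)
    span <- round(stats::runif(nf, spec$feature_span_range[1],
                               spec$feature_span_range[2]))
    is_oob <- rep(FALSE, nf)
    if (n_oob > 0) is_oob[sample.int(nf, n_oob)] <- TRUE
    start <- integer(nf); end <- integer(nf)
    for (j in seq_len(nf)) {
      L <- chrom$end[ci[j]]
      if (is_oob[j]) {
        start[j] <- L + round(stats::runif(1, 1, 1e4))
        end[j] <- start[j] + span[j]
      } else {
        start[j] <- round(stats::runif(1, 1, max(1, L - span[j])))
        end[j] <- min(start[j] + span[j] - 1, L)
      }
    }
    id <- sprintf("s%d_f%d", si, seq_len(nf))
    value <- switch(spec$value_model,
      none = rep(NA_character_, nf),
      normal = sprintf("%.4f", stats::rnorm(nf, spec$value_mean, spec$value_sd)),
      lognormal = sprintf("%.4f", stats::rlnorm(nf, spec$value_mean, spec$value_sd)),
      categorical = sprintf("group%d", sample.int(spec$categories, nf,
                                                  replace = TRUE)))
    href <- rep(NA_character_, nf)
    if (spec$hyperlink_fraction > 0 && nf > 0) {
      nh <- round(spec$hyperlink_fraction * nf)
      hi <- sample.int(nf, nh)
      href[hi] <- sprintf("https://example.org/%s", id[hi])
    }
    lines <- vapply(seq_len(nf), function(j) {
      base <- sprintf("%s\t%s\t%d\t%d", id[j], chrom$name[ci[j]],
                      start[j], end[j])
      if (!is.na(href[j])) {
        sprintf("%s\t%s\t%s", base,
                if (is.na(value[j])) "" else value[j], href[j])
      } else if (!is.na(value[j])) {
        sprintf("%s\t%s", base, value[j])
      } else base
    }, character(1))
    af <- file.path(outdir, sprintf("annotations_set%d.tsv", si))
    writeLines(lines, af)
    annotation_files[si] <- af

    # ground truth: window oracle over in-bound features
    w <- max(1, ceiling(max(chrom$end - chrom$start + 1) / spec$target_windows))
    oracle <- list()
    for (j in which(!is_oob)) {
      oracle[[id[j]]] <- naive_point_window(start[j], chrom$start[ci[j]],
                                            chrom$end[ci[j]], w)
    }
    manifest$sets[[si]] <- list(
      set_id = sprintf("set%d", si),
      chromosome_file = basename(cf), annotation_file = basename(af),
      window_size = w,
      oob_ids = id[is_oob],
      inbound_ids = id[!is_oob],
      point_windows = oracle)
    all_features[[si]] <- data.frame(id = id, oob = is_oob,
                                     stringsAsFactors = FALSE)
  }

  link_file <- NULL
  if (spec$n_links > 0) {
    pool <- do.call(rbind, all_features)
    pool <- pool$id[!pool$oob]
    if (length(pool) < 2L) stop("need >= 2 in-bound features to draw links",
                                call. = FALSE)
    src <- character(spec$n_links); tgt <- character(spec$n_links)
    for (j in seq_len(spec$n_links)) {
      pair <- sample(pool, 2L)
      src[j] <- pair[1]; tgt[j] <- pair[2]
    }
    directed <- stats::runif(spec$n_links) < spec$directed_fraction
    link_file <- file.path(outdir, "links.tsv")
    writeLines(sprintf("%s\t%s\t\t%d", src, tgt, as.integer(directed)),
               link_file)
    manifest$links <- list(file = basename(link_file),
                           n = spec$n_links,
                           n_directed = sum(directed))
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(chromosome_files = chromosome_files,
       annotation_files = annotation_files,
       link_file = link_file, manifest = manifest_path)
}
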