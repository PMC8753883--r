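# In-code fixture builders shared by the test files.

make_chrom <- function(name = "chr1", start = 1, end = 1000, centromere = NA) {
  data.frame(name = name, start = start, end = end, centromere = centromere,
             stringsAsFactors = FALSE)
}

make_ann <- function(id, chrom, start, end, value = NA_character_,
                     hyperlink = NA_character_) {
  value <- as.character(value)
  data.frame(element_id = id, chrom = chrom, start = start, end = end,
             value = value,
             value_num = suppressWarnings(
               ifelse(grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
                            value), as.numeric(value), NA_real_)),
             hyperlink = hyperlink, stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# naive linear-scan assignment oracle: scan every window span of the feature's
# chromosome for containment/overlap
oracle_point_window <- function(pos, windows) {
  which(windows$span_start <= pos & pos <= windows$span_end) - 1L
}

oracle_segment_windows <- function(start, end, windows) {
  which(windows$span_start <= end & start <= windows$span_end) - 1L
}

# run the installed CLI in a fresh Rscript process
run_cli <- function(args) {
  script <- system.file("cli", "chromocanvas.R", package = "chromocanvas")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), shQuote(args)), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

# standard small end-to-end fixture: 1 set, 2 chromosomes, numeric values
small_pipeline_fixture <- function(dir = tempfile(), seed = 5, n_features = 40,
                                   ...) {
  generate_fixture(fixture_spec(n_sets = 1, chroms_per_set = 2,
                                length_range = c(2e5, 4e5),
                                n_features = n_features,
                                value_model = "normal", seed = seed, ...), dir)
}
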