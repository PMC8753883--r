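# SVG/HTML/PNG emission: well-formedness, primitive counts, determinism,
# self-containment.

render_fixture_result <- function(dir = tempfile(), seed = 9, format = "svg",
                                  ...) {
  fx <- generate_fixture(
    fixture_spec(n_sets = 2, chroms_per_set = 2, length_range = c(1e5, 3e5),
                 n_features = 40, value_model = "normal",
                 hyperlink_fraction = 0.25, n_links = 6,
                 directed_fraction = 0.5, seed = seed), dir)
  cfg <- plot_config(fx$chromosome_files, fx$annotation_files,
                     link_file = fx$link_file, plot_type = "scatter",
                     aggregate_op = "mean", n_windows = 40,
                     quiet = TRUE, format = format, ...)
  list(fx = fx, cfg = cfg, res = run_pipeline(cfg))
}

test_that("the SVG is well-formed and its manifest matches an XML recount", {
  skip_if_not_installed("xml2")
  rr <- render_fixture_result()
  doc <- rr$res$document
  x <- xml2::read_xml(doc$payload)  # errors if not well-formed
  count <- function(cls) length(xml2::xml_find_all(
    x, sprintf("//*[@class='%s']", cls)))
  expect_equal(count("window"), doc$manifest$windows)
  expect_equal(count("mark"), doc$manifest$marks)
  expect_equal(count("link"), doc$manifest$links)
  expect_equal(count("label"), doc$manifest$labels)
  expect_equal(count("legend-entry"), doc$manifest$legends)
  # one window rectangle per built window across all sets
  total_windows <- sum(vapply(rr$res$sets, function(s) nrow(s$agg), numeric(1)))
  expect_equal(doc$manifest$windows, total_windows)
  # every hyperlinked kept feature is wrapped in exactly one anchor
  n_href <- sum(vapply(rr$res$sets, function(s)
    sum(!is.na(s$annotations$hyperlink)), numeric(1)))
  expect_equal(doc$manifest$anchors, n_href)
  expect_equal(length(xml2::xml_find_all(x, "//*[local-name()='a']")), n_href)
  # one arrowhead per directed link
  n_dir <- sum(vapply(xml2::xml_find_all(x, "//*[@class='link']"),
                      function(p) !is.na(xml2::xml_attr(p, "marker-end")),
                      logical(1)))
  expect_equal(n_dir, sum(read_link_file(rr$fx$link_file)$directed))
})

test_that("empty annotation sets still render a valid windows-only document", {
  d <- tempfile(); dir.create(d)
  cf <- write_tsv_lines(c("chr1\t1\t100", "chr2\t1\t55"),
                        file.path(d, "c.tsv"))
  af <- write_tsv_lines(character(0), file.path(d, "a.tsv"))
  cfg <- plot_config(cf, af, n_windows = 10, format = "svg", quiet = TRUE)
  res <- run_pipeline(cfg)
  expect_equal(res$document$manifest$windows, 10 + 6)
  expect_equal(res$document$manifest$marks, 0)
  skip_if_not_installed("xml2")
  expect_no_error(xml2::read_xml(res$document$payload))
})

test_that("the HTML embeds one tooltip record per window and no external refs", {
  skip_if_not_installed("xml2")
  rr <- render_fixture_result(format = "html")
  doc <- rr$res$document
  h <- xml2::read_html(doc$payload)
  expect_equal(doc$manifest$tooltips, doc$manifest$windows)
  lines <- strsplit(doc$payload, "\n", fixed = TRUE)[[1]]
  tt_line <- grep("^window\\.CC_TOOLTIPS = ", lines, value = TRUE)
  expect_length(tt_line, 1)
  tt <- jsonlite::fromJSON(sub(";$", "", sub("^window\\.CC_TOOLTIPS = ", "",
                                             tt_line)),
                           simplifyVector = FALSE)
  expect_length(tt, doc$manifest$windows)
  keys <- vapply(xml2::xml_find_all(h, "//*[@class='window']"),
                 xml2::xml_attr, character(1), "id")
  expect_setequal(names(tt), keys)
  # self-contained: no external script/style/font references
  expect_length(xml2::xml_find_all(h, "//script[@src]"), 0)
  expect_length(xml2::xml_find_all(h, "//link"), 0)
  expect_length(xml2::xml_find_all(h, "//style[contains(text(), '@import')]"), 0)
  # user hyperlinks are the only http references outside tooltip data
  expect_false(grepl("https?://(cdn|fonts|ajax)", doc$payload))
})

test_that("identical inputs render byte-identical SVG and HTML", {
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- render_fixture_result(d1, seed = 33, format = "svg")
  r2 <- render_fixture_result(d2, seed = 33, format = "svg")
  expect_identical(r1$res$document$payload, r2$res$document$payload)
  h1 <- render_fixture_result(tempfile(), seed = 33, format = "html")
  h2 <- render_fixture_result(tempfile(), seed = 33, format = "html")
  expect_identical(h1$res$document$payload, h2$res$document$payload)
})

test_that("window rectangles carry stable set/chrom/index ids", {
  rr <- render_fixture_result()
  ids <- regmatches(rr$res$document$payload,
                    gregexpr('id="set[12]\\.s[12]_chr[12]\\.w[0-9]+"',
                             rr$res$document$payload))[[1]]
  expect_length(ids, rr$res$document$manifest$windows)
  expect_length(unique(ids), length(ids))
})

test_that("png export honours canvas dimensions and dpi scaling", {
  rr <- render_fixture_result()
  p <- tempfile(fileext = ".png")
  doc <- render_png(rr$res$scene, p, dpi = 96)
  expect_true(file.exists(p))
  expect_equal(doc$format, "png")
  dim96 <- dim(png::readPNG(p))
  expect_equal(dim96[2], rr$res$scene$canvas$width)
  expect_equal(dim96[1], rr$res$scene$canvas$height)
  p2 <- tempfile(fileext = ".png")
  render_png(rr$res$scene, p2, dpi = 192)
  dim192 <- dim(png::readPNG(p2))
  expect_equal(dim192[1:2], dim96[1:2] * 2)
})

test_that("heatmap windows take ramp colors and filters paint over them", {
  d <- tempfile(); dir.create(d)
  cf <- write_tsv_lines("chr1\t1\t100", file.path(d, "c.tsv"))
  af <- write_tsv_lines(c("lo\tchr1\t5\t6\t0", "hi\tchr1\t95\t96\t10",
                          "mid\tchr1\t45\t46\t5"), file.path(d, "a.tsv"))
  cfg <- plot_config(cf, af, plot_type = "heatmap", aggregate_op = "mean",
                     n_windows = 10, colors = c("black", "white"),
                     format = "svg", quiet = TRUE)
  res <- run_pipeline(cfg)
  w <- res$scene$windows
  expect_equal(w$fill[1], "#000000")
  expect_equal(w$fill[10], "#FFFFFF")
  expect_true(all(abs(grDevices::col2rgb(w$fill[5]) - 128) <= 1))

  cfg2 <- plot_config(cf, af, plot_type = "annotation", n_windows = 10,
                      filters = list("window:count ge 1 yellow:hit"),
                      format = "svg", quiet = TRUE)
  res2 <- run_pipeline(cfg2)
  w2 <- res2$scene$windows
  expect_equal(w2$fill[c(1, 5, 10)], rep("#FFFF00", 3))
  expect_true(all(w2$fill[c(2:4, 6:9)] == w2$fill[2]))
  expect_true(any(res2$scene$legends$label == "hit"))
})
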