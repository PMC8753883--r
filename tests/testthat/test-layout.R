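# Canvas geometry: track stacking, coordinate mapping, data tracks, colors,
# labels.

two_chrom_set <- function(set_id = "set1", ends = c(100, 50), target = 10) {
  ch <- make_chrom(paste0(set_id, "_chr", seq_along(ends)), end = ends)
  list(set_id = set_id, chromosomes = ch,
       plan = plan_windows(ch, target_windows = target))
}

test_that("box widths are proportional to window counts within a set", {
  s <- two_chrom_set()
  lt <- layout_tracks(list(s), canvas_width = 1000)
  expect_equal(lt$boxes$n_windows, c(10, 5))
  expect_equal(lt$boxes$width[1] / lt$boxes$width[2], 2)
  # the longest chromosome spans the full drawable width
  drawable <- 1000 - lt$canvas$margin_left - 20
  expect_lt(abs(lt$boxes$width[1] - drawable), 1)
})

test_that("sets stack vertically in input order and lay out independently", {
  s1 <- two_chrom_set("s1")
  s2 <- two_chrom_set("s2", ends = c(300, 200, 100))
  lt <- layout_tracks(list(s1, s2), canvas_width = 800)
  y1 <- lt$boxes$y[lt$boxes$set_id == "s1"]
  y2 <- lt$boxes$y[lt$boxes$set_id == "s2"]
  expect_true(max(y1) < min(y2))
  # per-set independence: changing set 2 never moves set 1's boxes
  s2b <- two_chrom_set("s2", ends = c(5000, 10))
  ltb <- layout_tracks(list(s1, s2b), canvas_width = 800)
  expect_identical(lt$boxes[lt$boxes$set_id == "s1", ],
                   ltb$boxes[ltb$boxes$set_id == "s1", ])
  # pure function: identical input, identical geometry
  expect_identical(layout_tracks(list(s1, s2), canvas_width = 800), lt)
})

test_that("layout rejects a canvas narrower than one px per window", {
  s <- two_chrom_set(target = 1000)
  expect_error(layout_tracks(list(s), canvas_width = 120), "too narrow")
})

test_that("genomic-to-canvas mapping is affine, bounded and order-preserving", {
  ch <- make_chrom(end = 1001)
  s <- list(set_id = "s", chromosomes = ch, plan = plan_windows(ch, 10))
  box <- layout_tracks(list(s), canvas_width = 500)$boxes[1, ]
  expect_equal(genomic_to_canvas(ch$start, box, ch), box$x)
  expect_equal(genomic_to_canvas(ch$end, box, ch), box$x + box$width)
  mid <- genomic_to_canvas((ch$start + ch$end) / 2, box, ch)
  expect_lt(abs(mid - (box$x + box$width / 2)), 0.5)
  pos <- sort(sample.int(1001, 50))
  xs <- genomic_to_canvas(pos, box, ch)
  expect_true(all(diff(xs) >= 0))
  expect_error(genomic_to_canvas(0, box, ch), "outside")
})

test_that("heatmap anchors reproduce exactly, interpolate linearly and clamp", {
  expect_equal(heatmap_color(0, 0, 10, c("black", "white")), "#000000")
  expect_equal(heatmap_color(10, 0, 10, c("black", "white")), "#FFFFFF")
  mid <- grDevices::col2rgb(heatmap_color(5, 0, 10, c("black", "white")))
  expect_true(all(abs(mid - 128) <= 1))
  # out-of-range clamps to end colors
  expect_equal(heatmap_color(c(-99, 99), 0, 10, c("black", "white")),
               c("#000000", "#FFFFFF"))
  # degenerate range maps to the last anchor
  expect_equal(heatmap_color(3, 3, 3, c("black", "white")), "#FFFFFF")
  # multi-anchor: middle anchor reproduced exactly; monotone per channel
  ramp <- c("#000000", "#FF0000", "#FFFFFF")
  expect_equal(heatmap_color(0.5, 0, 1, ramp), "#FF0000")
  reds <- grDevices::col2rgb(heatmap_color(seq(0, 1, 0.05), 0, 1, ramp))["red", ]
  expect_true(all(diff(reds) >= 0))
})

test_that("scatter marks rescale values linearly onto the track, inverted", {
  ch <- make_chrom(end = 100)
  s <- list(set_id = "s", chromosomes = ch, plan = plan_windows(ch, 10))
  box <- layout_tracks(list(s), canvas_width = 500, track_height = 100)$boxes[1, ]
  feats <- make_ann(c("a", "b", "c"), "chr1", c(10, 50, 90), c(10, 50, 90),
                    value = c("0", "5", "10"))
  tr <- place_data_track(features = feats, style = list(plot_type = "scatter"),
                         box = box, chrom = ch)
  expect_equal(tr$marks$y - box$data_y, c(100, 50, 0))
  # reference line at 0 sits strictly between positive and negative marks
  feats2 <- make_ann(c("up", "dn"), "chr1", c(10, 20), c(10, 20),
                     value = c("2", "-2"))
  tr2 <- place_data_track(features = feats2,
                          style = list(plot_type = "scatter", y_reference = 0),
                          box = box, chrom = ch)
  expect_true(tr2$marks$y[1] < tr2$ref_y && tr2$ref_y < tr2$marks$y[2])
})

test_that("categorical scatter colors marks by group with one legend entry each", {
  ch <- make_chrom(end = 100)
  s <- list(set_id = "s", chromosomes = ch, plan = plan_windows(ch, 10))
  box <- layout_tracks(list(s), canvas_width = 500)$boxes[1, ]
  feats <- make_ann(sprintf("f%d", 1:6), "chr1", seq(10, 60, 10),
                    seq(10, 60, 10),
                    value = c("glycolysis", "TCA", "lipid",
                              "glycolysis", "TCA", "lipid"))
  tr <- place_data_track(features = feats, style = list(plot_type = "scatter"),
                         box = box, chrom = ch)
  expect_equal(nrow(tr$legend), 3)
  expect_length(unique(tr$marks$color), 3)
  expect_equal(tr$marks$color[1:3], tr$marks$color[4:6])
})

test_that("bar marks scale with the aggregate and sit on the window grid", {
  ch <- make_chrom(end = 100)
  plan <- plan_windows(ch, 10)
  s <- list(set_id = "s", chromosomes = ch, plan = plan)
  box <- layout_tracks(list(s), canvas_width = 500, track_height = 80)$boxes[1, ]
  win <- build_windows_all(ch, plan)
  ann <- make_ann(c("a", "b", "c"), "chr1", c(5, 15, 15), c(5, 15, 15),
                  value = c("1", "2", "2"))
  asg <- assign_annotations(ann, ch, plan)
  aw <- aggregate_windows(win, asg, ann, op = "sum")
  tr <- place_data_track(agg = aw, style = list(plot_type = "bar"),
                         box = box, chrom = ch)
  expect_equal(nrow(tr$marks), 2)            # only windows with a value
  expect_equal(tr$marks$h[2] / tr$marks$h[1], 4)  # sums 1 vs 4, baseline 0
  expect_equal(tr$marks$x, box$x + c(0, 1) * box$width / 10)
})

test_that("labels stagger greedily into non-overlapping rows", {
  ch <- make_chrom(end = 1000)
  s <- list(set_id = "s", chromosomes = ch, plan = plan_windows(ch, 10))
  box <- layout_tracks(list(s), canvas_width = 1000)$boxes[1, ]
  far <- make_ann(c("geneAAA", "geneBBB"), "chr1", c(10, 700), c(10, 700))
  pl <- place_labels(far, box, ch)
  expect_equal(pl$row, c(0, 0))
  near <- make_ann(c("geneAAA", "geneBBB"), "chr1", c(500, 510), c(500, 510))
  pl2 <- place_labels(near, box, ch)
  expect_equal(sort(pl2$row), c(0, 1))
  expect_equal(nrow(place_labels(far[0, ], box, ch)), 0)

  # no two labels in one row intersect, over randomized label sets
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    feats <- make_ann(replicate(n, paste(sample(letters, sample(3:10, 1),
                                                TRUE), collapse = "")),
                      "chr1", sort(sample.int(1000, n)), 1000)
    feats$end <- feats$start
    pl <- place_labels(feats, box, ch, char_width = 7)
    for (r in unique(pl$row)) {
      rows <- pl[pl$row == r, ]
      rows <- rows[order(rows$x), ]
      if (nrow(rows) > 1) {
        rw <- nchar(rows$text) * 7
        left <- rows$x - rw / 2
        right <- rows$x + rw / 2
        expect_true(all(left[-1] > right[-nrow(rows)]))
      }
    }
  }
})

test_that("stable category colors cycle the palette in first-appearance order", {
  cc <- category_colors(c("A", "B", "A"))
  expect_equal(nrow(cc$legend), 2)
  expect_equal(cc$colors, cc$legend$color[c(1, 2, 1)])
  many <- category_colors(sprintf("c%02d", 1:25))
  expect_equal(nrow(many$legend), 25)
  expect_equal(many$legend$color[21], many$legend$color[1])  # cycles at 20
})
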