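# Per-window aggregation, tooltips and condition-based filters.

test_that("aggregate_values implements the five operators", {
  expect_equal(aggregate_values(c(1, 2, 3), "mean"), 2)
  expect_equal(aggregate_values(c(-2, 5), "max"), 5)
  expect_equal(aggregate_values(c(0.5, 0.25, 0.25), "sum"), 1)
  expect_equal(aggregate_values(c(-2, 5), "min"), -2)
  expect_equal(aggregate_values(numeric(0), "count"), 0)
  expect_equal(aggregate_values(c(1, 1, 1), "count"), 3)
  expect_error(aggregate_values(numeric(0), "mean"), "at least one")
})

build_agg_case <- function(values, positions, op, target = 10, end = 100) {
  ch <- make_chrom(end = end)
  plan <- plan_windows(ch, target_windows = target)
  win <- build_windows_all(ch, plan)
  ann <- make_ann(sprintf("f%d", seq_along(positions)), "chr1",
                  positions, positions, value = values)
  asg <- assign_annotations(ann, ch, plan, mode = "point")
  aggregate_windows(win, asg, ann, op = op)
}

test_that("window aggregates match brute-force recomputation from members", {
  aw <- build_agg_case(c(1, 3), c(5, 9), "mean")
  expect_equal(aw$agg_value[1], 2)
  expect_equal(aw$n_members[1], 2)
  expect_true(all(is.na(aw$agg_value[-1])))

  set.seed(21)
  for (op in c("sum", "mean", "min", "max", "count")) {
    n <- 300
    pos <- sample.int(100, n, replace = TRUE)
    vals <- round(stats::rnorm(n), 3)
    aw <- build_agg_case(vals, pos, op)
    brute <- vapply(seq_len(nrow(aw)), function(k) {
      m <- vals[pos >= aw$span_start[k] & pos <= aw$span_end[k]]
      if (op == "count") return(length(m))
      if (length(m) == 0) return(NA_real_)
      switch(op, sum = sum(m), mean = mean(m), min = min(m), max = max(m))
    }, numeric(1))
    expect_equal(aw$agg_value, brute, tolerance = 1e-12)
  }
})

test_that("mean times n equals sum within 1e-9 relative tolerance", {
  set.seed(22)
  pos <- sample.int(100, 500, replace = TRUE)
  vals <- stats::rnorm(500, sd = 10)
  means <- build_agg_case(vals, pos, "mean")
  sums <- build_agg_case(vals, pos, "sum")
  has <- !is.na(means$agg_value)
  expect_true(all(abs(means$agg_value[has] * means$n_members[has] -
                      sums$agg_value[has]) <=
                  1e-9 * pmax(abs(sums$agg_value[has]), 1)))
})

test_that("count aggregation equals membership cardinality and ignores value type", {
  aw <- build_agg_case(c("catA", "catB", "3.5"), c(5, 7, 9), "count")
  expect_equal(aw$agg_value[1], 3)
  expect_equal(aw$n_members, c(3, rep(0, 9)))
  expect_equal(aw$group_counts[[1]], c(catA = 1L, catB = 1L))
})

test_that("aggregation is permutation-invariant in member order", {
  set.seed(23)
  pos <- sample.int(100, 50, replace = TRUE)
  vals <- stats::rnorm(50)
  a1 <- build_agg_case(vals, pos, "sum")
  perm <- sample.int(50)
  a2 <- build_agg_case(vals[perm], pos[perm], "sum")
  expect_equal(a1$agg_value, a2$agg_value)
})

test_that("segment features contribute full value to every overlapped window", {
  ch <- make_chrom(end = 100)
  plan <- plan_windows(ch, target_windows = 10)
  win <- build_windows_all(ch, plan)
  ann <- make_ann("seg", "chr1", 5, 25, value = "2.0")
  asg <- assign_annotations(ann, ch, plan, mode = "segment")
  aw <- aggregate_windows(win, asg, ann, op = "sum")
  expect_equal(aw$agg_value[1:3], c(2, 2, 2))
  expect_true(all(is.na(aw$agg_value[4:10])))
})

test_that("filters reproduce their brute-force predicate", {
  # window count filter (>= 5 members highlighted)
  set.seed(24)
  pos <- sample.int(100, 60, replace = TRUE)
  aw <- build_agg_case(rep("1", 60), pos, "count")
  marked <- apply_filter(filter_spec("window", "count", "ge", 5), aw)
  brute <- paste0(aw$chrom, ":", aw$index)[aw$n_members >= 5]
  expect_setequal(marked, brute)

  # feature |value| filter
  ann <- make_ann(c("f1", "f2", "f3"), "chr1", 1:3, 1:3,
                  value = c("-3", "0.5", "2.1"))
  hit <- apply_filter(filter_spec("feature", "value", "abs_ge", 2), ann)
  expect_equal(hit, c("f1", "f3"))

  # between is closed on both ends
  ann2 <- make_ann(sprintf("g%d", 1:4), "chr1", 1:4, 1:4,
                   value = c("0", "0.5", "1", "2"))
  expect_equal(apply_filter(filter_spec("feature", "value", "between", c(0, 1)),
                            ann2), c("g1", "g2", "g3"))

  # randomized equivalence across all operators
  set.seed(25)
  vals <- round(stats::rnorm(500, sd = 3), 2)
  annr <- make_ann(sprintf("r%d", 1:500), "chr1", 1:500, 1:500, value = vals)
  ops <- list(lt = `<`, le = `<=`, gt = `>`, ge = `>=`, eq = `==`)
  for (op in names(ops)) {
    spec <- filter_spec("feature", "value", op, 0.5)
    expect_setequal(apply_filter(spec, annr),
                    annr$element_id[ops[[op]](vals, 0.5)])
  }
  spec <- filter_spec("feature", "value", "abs_ge", 2)
  expect_setequal(apply_filter(spec, annr), annr$element_id[abs(vals) >= 2])
})

test_that("filters are idempotent and never mutate their input", {
  aw <- build_agg_case(rep("1", 40), sample.int(100, 40, replace = TRUE), "count")
  before <- aw$n_members
  spec <- filter_spec("window", "count", "ge", 3)
  m1 <- apply_filter(spec, aw)
  m2 <- apply_filter(spec, aw)
  expect_identical(m1, m2)
  expect_identical(aw$n_members, before)
})

test_that("filter construction and string parsing validate their grammar", {
  expect_error(filter_spec("feature", "value", "between", 1), "2 threshold")
  expect_error(filter_spec("feature", "value", "ge", c(1, 2)), "1 threshold")
  expect_error(filter_spec("window", "value", "ge", 1), "agg_value")
  fs <- parse_filter("window:count ge 5 yellow:highDEG")
  expect_equal(fs$scope, "window")
  expect_equal(fs$field, "count")
  expect_equal(fs$thresholds, 5)
  expect_equal(fs$label, "highDEG")
  fs2 <- parse_filter("feature:value between 0,1 orange")
  expect_equal(fs2$thresholds, c(0, 1))
  expect_null(fs2$label)
  expect_error(parse_filter("nonsense"), "cannot parse")
})

test_that("tooltip payloads carry span, members, values, links and counts", {
  ch <- make_chrom(end = 100)
  plan <- plan_windows(ch, target_windows = 10)
  win <- build_windows_all(ch, plan)
  ann <- make_ann(c("geneA", "geneB"), "chr1", c(2, 15), c(8, 18),
                  value = c("2.5", "pathX"),
                  hyperlink = c(NA, "https://example.org/geneB"))
  asg <- assign_annotations(ann, ch, plan)
  aw <- aggregate_windows(win, asg, ann, op = "mean")
  p0 <- build_tooltip_payload(aw[1, ], ann, agg_op = "mean")
  expect_equal(p0$span, "1-10")
  expect_equal(p0$members[[1]]$id, "geneA")
  expect_equal(p0$members[[1]]$value, 2.5)
  expect_equal(p0$agg_value, 2.5)
  p1 <- build_tooltip_payload(aw[2, ], ann, agg_op = "mean")
  expect_equal(p1$members[[1]]$hyperlink, "https://example.org/geneB")
  expect_equal(p1$members[[1]]$value, "pathX")
  expect_equal(p1$groups, list(pathX = 1L))
  pe <- build_tooltip_payload(aw[3, ], ann, agg_op = "mean")
  expect_equal(pe$n, 0)
  expect_length(pe$members, 0)
})
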