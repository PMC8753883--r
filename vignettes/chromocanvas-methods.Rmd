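---
title: "chromocanvas: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromocanvas: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromocanvas)
```

## The windowed-ideogram model

chromocanvas draws each chromosome as a contiguous run of fixed-width
genomic windows, because whole chromosomes (10⁷–10⁹ bp) cannot map base-per-
pixel onto a publication canvas. For a chromosome set with lengths
$L_1,\dots,L_m$ (bp, $L_i = \mathrm{end}_i - \mathrm{start}_i + 1$) and a
window target $T$, the set's shared window width is

$$w = \left\lceil \frac{\max_i L_i}{T} \right\rceil,$$

so the longest chromosome receives exactly $T$ windows (fewer only when it is
shorter than $T$ bp) and all chromosomes in the set share one width — window
counts, and therefore per-window statistics such as feature counts, are
directly comparable across chromosomes. Window $k$ (0-based) of a chromosome
spans $[\mathrm{start} + kw,\ \min(\mathrm{start} + (k+1)w - 1, \mathrm{end})]$:
windows are contiguous, disjoint, exactly cover the chromosome, and only the
last may be truncated. A chromosome shorter than one window still gets a
single truncated window, never zero. The exact windowing rule is this
package's own definition, validated by its invariants (exact cover, equal
widths, oracle-checked assignment) rather than by equivalence to any other
implementation.

Two annotation algorithms place features into windows:

* **point-annotation** ignores a feature's size and anchors it on a single
  base — window $\lfloor(\mathrm{anchor}-\mathrm{start})/w\rfloor$, clamped
  to the last window;
* **segment-annotation** uses the feature's size: the feature occupies every
  window whose span overlaps $[\mathrm{start},\mathrm{end}]$, which is the
  contiguous range between the point-windows of its two endpoints.

The point anchor defaults to the feature's *start* coordinate rather than its
midpoint: the start is deterministic, matches intuition for stranded features
such as genes, and keeps point- and segment-annotation consistent at the left
edge. `anchor = "midpoint"` (CLI `--point-anchor midpoint`) uses
$\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$ instead.

## Coordinate conventions

All coordinates are **1-based, fully closed intervals** $[\mathrm{start},
\mathrm{end}]$, for chromosomes and annotations alike. Input files carry
explicit start and end columns, which reads most naturally as closed
intervals and avoids off-by-one ambiguity; users with true BED (0-based,
half-open) files set `zero_based = TRUE` / `--zero-based`, which converts on
read (start + 1, end unchanged).

An annotation is in-bound iff its chromosome is known **and both endpoints
lie inside** the chromosome's interval (full containment). Partial overlaps
are dropped, not clipped: "outside the boundary" is taken literally, and full
containment is the simplest semantics to state, test and reason about.
Out-of-bound and unknown-chromosome rows are removed with a per-reason
console warning and the plot renders from the kept rows — dropping is never
fatal. By contrast, *structural* defects (wrong column count, non-integer
coordinates, duplicate chromosome names, a chromosome with start > end)
terminate the run with a message naming the offending line: a structurally
broken file signals a wrong file, not a few bad rows. One semantic case sits
between the two: an annotation row with start > end is well-formed
structurally but violates the interval model, so it is dropped with reason
`malformed-row` rather than killing the run.

## Aggregation and filters

A window aggregates its members' numeric values with `sum`, `mean`
($= \mathrm{sum}/n$), `min`, `max` or `count`. Three choices matter:

* **Segment features contribute their full value to every window they
  overlap** — no length-proportional proration. This keeps every number a
  user sees in a tooltip identical to a number in their input file; prorated
  fractions would be unexplainable in a tooltip. The cost is that a long
  segment contributes to the `sum` of every window it crosses; that is a
  documented property of the aggregation, not an artifact.
* **Mixed value columns never poison arithmetic**: a value token is numeric
  iff the whole token lexes as a decimal number, else it is a category
  string. Categorical members are excluded from numeric aggregation but
  still counted by `count` and tallied into per-category group counts.
* A window with members but no numeric member has an absent aggregate
  (`NA`), not zero — zero is a value, absence is not.

Filters ("epi-tags") are predicates `(scope, field, comparator, thresholds)`
with a highlight color and optional tag label: `lt, le, gt, ge, eq` compare
literally, `between` is closed on both ends, and `abs_ge` marks
$|x| \ge t$ so that "x ≥ 2 or x ≤ −2" is a single filter. Filters never
mutate values; multiple filters compose as independent mark layers, later
layers painting over earlier ones — a deliberate simplification over a
boolean combination grammar.

## Layout, color, labels

Within a set, chromosomes share one bp-per-px scale, so box width is
proportional to window count and the set's longest chromosome spans the full
drawable width — relative lengths within a set are visually truthful. Across
sets, each set rescales independently (sets may differ arbitrarily in
chromosome number and length; a 2-Gb genome must not crush a 20-Mb one);
`common_scale = TRUE` forces one global scale when cross-set length
comparison is the point. Sets stack vertically in input order.

The genomic→canvas map is affine
($\mathrm{start} \mapsto x$, $\mathrm{end} \mapsto x + \mathrm{width}$) and
strictly monotone. Heatmap colors interpolate piecewise-linearly in RGB
across ordered anchor colors over the data range $[v_{\min}, v_{\max}]$:
anchor positions reproduce anchor colors exactly, out-of-range values clamp
to the end colors, and the degenerate $v_{\min} = v_{\max}$ maps everything
to the last anchor (a single-valued track reads as "maximal" rather than
failing). The default ramp is white → steel blue; categorical data draws
from a fixed 20-color cycle assigned in first-appearance order **globally
across all sets**, so a category keeps one color on every chromosome and
legends are stable across runs. Scatter tracks rescale values linearly from
$[v_{\min}, v_{\max}]$ (data range by default, `y_range` to override) onto
the track height, inverted so larger values sit higher; an optional dashed
reference line (e.g. logFC = 0 separating up- from down-regulation) is drawn
at its rescaled position. Bars rise from a baseline at 0 when all values are
non-negative, otherwise from the value-0 position of the $[v_{\min},
v_{\max}]$ scale — "height proportional to the aggregate" reads as
proportional to magnitude, and a nonzero baseline would fake ratios.
Categorical scatter (a category string instead of a number) places marks on
one y-level per category with category colors — a single value column is
either numeric or categorical, never both. Static labels stagger greedily:
a left-to-right sweep drops a label to the next row when its estimated
bounding box (fixed per-character width, 7 px) would intersect the previous
label in the current row. Centromeres, when present, render as a decorative
notch and never affect windowing.

## Links

Link endpoints are feature ids or explicit loci `chrom:pos`. Feature
endpoints anchor at the feature's start base (the point-annotation
convention) on the chromosome edge facing the partner endpoint; unresolvable
endpoints fail before any rendering begins, naming the offender, and
self-links are rejected. Edge style draws a cubic Bézier whose control
points offset vertically by half the inter-track gap (an aesthetic
constant); a directed link carries exactly one arrowhead, at the target.
Ribbon style draws a closed chord-like band whose end widths equal the two
features' on-canvas widths, with a 2 px minimum so short features stay
visible. Categorical link values map to the palette in first-appearance
order; numeric values run through the same heatmap ramp; valueless links all
take the first palette color unless `link_distinct = TRUE`, which gives each
link its own color (one color per orthologous pair, with one legend entry
per pair).

## Rendering and determinism

SVG and HTML are assembled as strings with fixed two-decimal coordinate
formatting, so **identical inputs produce byte-identical documents** — no
random state touches geometry or colors (the `seed` option is reserved for
explicitly stochastic style options and never affects category colors, to
keep legends stable). Every window rectangle carries a stable id
(`set.chrom.w<index>`) and class, as do marks, links, labels and legend
entries, so documents can be audited by recounting primitives; the returned
manifest holds those counts. The HTML file is fully self-contained — inline
SVG, an embedded JSON map with one tooltip record per window, and a small
inlined script for hover tooltips, click-through feature hyperlinks, and
wheel/drag zoom-and-pan. Zoom is a viewport transform of the vector canvas;
it does **not** re-window at higher resolution, a deliberate v1 bound. PNG
export draws the same scene geometry through R's native cairo `png()`
device at `canvas × dpi/96` pixels, a design choice that keeps the raster
path dependency-free while guaranteeing the same canvas as the vector
output.

## The synthetic fixture generator

`generate_fixture()` emulates the statistical shape of real inputs without
any download: chromosome lengths uniform over a range, feature start
positions uniform along the chromosome, numeric values normal or lognormal
(log fold-changes and expression-like data respectively), categories uniform
over $k$ levels, and a controlled fraction of rows written deliberately
out-of-bound. A JSON sidecar manifest records the ground truth — the
out-of-bound ids and each in-bound feature's point-window computed by a
naive linear scan over enumerated spans — so tests compare engine output to
recorded truth rather than to the engine itself. The generator does *not*
emulate real genomic structure: no clustered gene density, no exon/intron
architecture, no correlated values along the chromosome, no sequence
content. Passing tests therefore demonstrate the correctness of windowing,
assignment, aggregation, validation and rendering contracts on
distributionally simple data; they do not certify visual quality or
performance on genome-scale feature sets beyond the sizes exercised.

## Numerical choices and problem sizes

Coordinates are stored as doubles (exact for integers up to $2^{53}$, far
beyond any genome). Mean is computed as sum/n; the test suite asserts
$|\mathrm{mean}\cdot n - \mathrm{sum}| \le 10^{-9}$ relative. Heatmap
channels round to the nearest integer, so a black→white midpoint is
(128, 128, 128) within ±1 per channel. Property-style checks run at sizes
chosen to finish a full suite run in well under a minute of compute per
file: 500 randomized chromosomes (lengths up to 10⁶ bp, targets up to 1000)
for exact cover, 10⁴ randomized features against the linear-scan assignment
oracle, 10⁴ feature starts for the chi-square uniformity check
(α = 0.01), and a few thousand items for aggregation and filter
equivalence. `scripts/acceptance.R` re-measures the same quantities from
scratch at those sizes.

## Known limitations

* One value column per annotation file: a feature is numeric *or*
  categorical, so a combined numeric-plus-category scatter (value positions,
  pathway colors) needs two tracks.
* No length-normalized or weighted aggregation; no statistical testing of
  window values.
* Fixed-window viewport zoom; no adaptive re-binning, no sliding windows.
* No GFF/GTF/VCF ingestion, remote URLs, or gzip transparency — TSV in the
  documented dialect only.
* Linear (non-circular) layout only; label metrics use a fixed
  per-character width estimate, not font metrics.
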