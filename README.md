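# chromocanvas

Windowed chromosome ideograms with annotation tracks, per-window data
aggregation, condition-based highlighting, and inter-locus links — exported as
standalone interactive HTML, static SVG, or PNG.

## The problem

Genome-scale feature maps (gene positions, SNPs, transposable elements) and
the data attached to them (expression log fold-changes, methylation levels,
feature densities) are awkward to show on a single publication-ready figure:
chromosomes are orders of magnitude longer than any printable canvas, and
web-based genome browsers are not built for self-contained, shareable plots.
chromocanvas addresses this the way ideogram tools in this field do: each
chromosome is drawn as a **continuous run of fixed-width genomic windows**,
every annotated feature is assigned to windows, and per-window summaries are
painted onto (heatmaps) or above (scatter/bar tracks) the chromosome body.
Multiple chromosome sets — homologous chromosomes of phased diploid/polyploid
assemblies, or different species — render as independent tracks, and links
connect loci within or across sets.

## The model

For a chromosome set with lengths `L_1 … L_m` (in bp) and a target of `T`
windows, the shared window width is

```
w = ceil(max(L_i) / T)
```

so the longest chromosome gets exactly `T` windows and window counts are
comparable across the set; chromosome `i` gets `ceil(L_i / w)` contiguous,
disjoint windows `[start + k·w, start + (k+1)·w − 1]` (the last one
truncated). Features enter windows by **point-annotation** (the anchor base
`start`, ignoring feature size: window `floor((anchor − start)/w)`) or
**segment-annotation** (every window overlapping `[start, end]`). A window
holding several features shows one aggregated value — `sum`, `mean`, `min`,
`max` or `count` — while individual values stay visible in hover tooltips.
Filters ("epi-tags") mark features or windows satisfying a condition, e.g.
`count ≥ 5` per window or `|logFC| ≥ 2` per gene. Coordinates are 1-based
closed intervals; true BED (0-based half-open) input converts on read with
`zero_based = TRUE` / `--zero-based`.

Input files are plain TSV: chromosomes (`name start end [centromere]`),
annotations (`id chrom start end [value [hyperlink]]`, value inferred numeric
or categorical per row), links (`source target [value [directed]]`).
Structurally broken files (wrong column counts, non-integer coordinates)
terminate the run with a message naming the offending line; annotations whose
coordinates fall outside their chromosome are **removed with a console
warning** and the plot renders from the rest.

## Worked example

```r
library(chromocanvas)
dir <- tempfile(); dir.create(dir)
writeLines(c("chr1\t1\t240000\t120000", "chr2\t1\t150000\t60000"),
           file.path(dir, "chromosomes.tsv"))
writeLines(c("geneA\tchr1\t10500\t12800\t2.7\thttps://example.org/geneA",
             "geneB\tchr1\t98000\t99600\t-1.4",
             "geneC\tchr1\t99500\t101200\t-2.3",
             "geneD\tchr2\t40200\t45900\t0.8",
             "geneE\tchr2\t300000\t301000\t1.1"),   # beyond chr2's end
           file.path(dir, "annotations.tsv"))

cfg <- plot_config(
  chromosome_files = file.path(dir, "chromosomes.tsv"),
  annotation_files = file.path(dir, "annotations.tsv"),
  plot_type = "heatmap", aggregate_op = "mean", n_windows = 24,
  filters = list("feature:value abs_ge 2 orange:strongFC"),
  out = file.path(dir, "plot.html"))
res <- run_pipeline(cfg)
print(res$reports[[1]])
print(res$document)
```

prints

```
warning: 1 annotation with coordinates outside the target chromosome boundary removed
<chromocanvas validation: 4 kept, 1 dropped>
  1 annotation with coordinates outside the target chromosome boundary removed
<rendered html document: 14767 bytes; windows=39 marks=1 links=0 labels=0 legends=1 anchors=1 tooltips=39>
```

`geneE` lies beyond chr2's end, so it is dropped with a warning and the plot
is built from the remaining four genes. With `n_windows = 24` the window
width is `ceil(240000/24) = 10000` bp, giving 24 windows on chr1 and 15 on
chr2 — the 39 window rectangles and 39 tooltip records in the manifest. The
mean log fold-change per window colors the heatmap; the one hyperlinked gene
becomes a clickable anchor; the `strongFC` filter (|value| ≥ 2) adds one
legend entry and recolors the marks of geneA and geneC.

The same plot from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "chromocanvas.R", package = "chromocanvas"))')" \
  plot --chromosomes chromosomes.tsv --annotations annotations.tsv \
  --plot-type heatmap --aggregate mean --n-windows 24 \
  --filter "feature:value abs_ge 2 orange:strongFC" --out plot.html
```

Subcommands `validate` (readers + out-of-bound check only) and `fixtures`
(seeded synthetic chromosome/annotation/link files with a ground-truth
manifest) complete the CLI; see `--help`.

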