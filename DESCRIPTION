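Package: chromocanvas
Title: Windowed Chromosome Ideograms with Annotation Tracks, Filters and Links
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Renders chromosomes as contiguous fixed-width genomic windows and
    annotates them with point or segment features from tab-delimited (BED-like)
    files. Feature-associated numeric or categorical data can be aggregated per
    window (sum, mean, min, max, count), drawn as scatter, bar or heatmap
    tracks, highlighted by condition-based filters, and connected across loci
    with directed or undirected links. Multiple chromosome sets (e.g. phased
    haplotypes or different species) are laid out as independent tracks.
    Output is a standalone interactive HTML file (tooltips, zoom, hyperlinks),
    a static SVG, or a PNG. Includes a seeded synthetic fixture generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    grid,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    IRanges,
    png,
    S4Vectors,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
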