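#' Default categorical palette
#'
#' Fixed 20-color cycle used for categorical data (group annotations, link
#' categories, pathway colors) when the user supplies no palette. Assignment is
#' by first appearance so legends are stable across runs.
#'
#' @return Character vector of 20 hex colors.
#' @export
default_palette <- function() {
  c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
    "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
    "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
    "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fixed-precision numeric formatting so emitted markup is byte-stable.
fmt_px <- function(x) {
  s <- sprintf("%.2f", x)
  s[s == "-0.00"] <- "0.00"
  s
}

is_integer_token <- function(x) grepl("^[+-]?[0-9]+$", x)

is_numeric_token <- function(x) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Convert any R color to "#rrggbb" hex
#' @param col color name or hex string
#' @return lowercase hex string
#' @keywords internal
to_hex <- function(col) {
  m <- grDevices::col2rgb(col)
  grDevices::rgb(m[1, ], m[2, ], m[3, ], maxColorValue = 255)
}
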