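# Standalone interactive HTML.
#
# The HTML document embeds the SVG inline, a JSON map of per-window tooltip
# records, and a small interactivity script authored here and inlined
# verbatim: hovering a window shows its tooltip (members, individual values,
# aggregate, groups, tags), hyperlinked features are real anchors opening in a
# new tab, and the mouse wheel / drag zooms and pans the vector canvas
# (viewport transform; windows are not re-binned at higher zoom). Nothing is
# fetched at view time and no external script, style or font is referenced:
# the file is fully self-contained and works offline.

HTML_JS <- '
(function () {
  var tip = document.getElementById("cc-tooltip");
  var svg = document.querySelector("svg");
  var data = window.CC_TOOLTIPS || {};
  function show(evt, key) {
    var d = data[key];
    if (!d) return;
    var html = "<b>" + d.chrom + ":" + d.span + "</b><br/>" +
               d.n + " element(s)";
    if (d.agg_value !== undefined && d.agg_value !== null)
      html += "<br/>" + (d.agg_op || "aggregate") + " = " + d.agg_value;
    if (d.members) d.members.forEach(function (m) {
      html += "<br/>" + m.id + (m.value !== undefined && m.value !== null ?
        ": " + m.value : "");
    });
    if (d.groups) Object.keys(d.groups).forEach(function (g) {
      html += "<br/>[" + g + "] x" + d.groups[g];
    });
    if (d.tags) html += "<br/>tags: " + d.tags.join(", ");
    tip.innerHTML = html;
    tip.style.display = "block";
    tip.style.left = (evt.pageX + 12) + "px";
    tip.style.top = (evt.pageY + 12) + "px";
  }
  function hide() { tip.style.display = "none"; }
  Array.prototype.forEach.call(document.querySelectorAll(".window"),
    function (el) {
      el.addEventListener("mousemove", function (e) { show(e, el.id); });
      el.addEventListener("mouseleave", hide);
    });
  var scale = 1, tx = 0, ty = 0, drag = null;
  function apply() {
    svg.style.transformOrigin = "0 0";
    svg.style.transform = "translate(" + tx + "px," + ty + "px) scale(" + scale + ")";
  }
  svg.addEventListener("wheel", function (e) {
    e.preventDefault();
    var f = e.deltaY < 0 ? 1.15 : 1 / 1.15;
    scale = Math.max(0.2, Math.min(40, scale * f));
    apply();
  }, { passive: false });
  svg.addEventListener("mousedown", function (e) {
    drag = { x: e.clientX - tx, y: e.clientY - ty };
  });
  window.addEventListener("mousemove", function (e) {
    if (drag) { tx = e.clientX - drag.x; ty = e.clientY - drag.y; apply(); }
  });
  window.addEventListener("mouseup", function () { drag = null; });
})();
'

#' Render a scene to a standalone interactive HTML document
#'
#' @param scene a scene list as produced by \code{\link{build_scene}}; its
#'   \code{tooltips} entry (named list keyed by window id) drives the hover
#'   tooltips — one record per window.
#' @param title page title.
#' @return a \code{rendered_document} with \code{format = "html"}; the
#'   manifest is the SVG manifest plus \code{tooltips}.
#' @export
render_html <- function(scene, title = scene$title %||% "chromocanvas") {
  svg_doc <- render_svg(scene)
  # strip the XML prologue when inlining
  svg_markup <- sub("^<\\?xml[^>]*\\?>\n", "", svg_doc$payload)
  tt <- scene$tooltips %||% stats::setNames(list(), character(0))
  tt_json <- jsonlite::toJSON(tt, auto_unbox = TRUE, digits = NA, null = "null")
  out <- c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", xml_escape(title)),
    "<style>",
    "body { font-family: sans-serif; margin: 12px; }",
    "#cc-tooltip { display: none; position: absolute; background: #fffef0;",
    "  border: 1px solid #888; padding: 6px 8px; font-size: 11px;",
    "  pointer-events: none; max-width: 340px; box-shadow: 2px 2px 4px rgba(0,0,0,.25); }",
    ".window:hover { stroke: #000000; stroke-width: 1; }",
    "</style>",
    "</head>",
    "<body>",
    '<div id="cc-tooltip"></div>',
    '<div id="cc-canvas">',
    svg_markup,
    "</div>",
    "<script>",
    sprintf("window.CC_TOOLTIPS = %s;", tt_json),
    HTML_JS,
    "</script>",
    "</body>",
    "</html>")
  manifest <- svg_doc$manifest
  manifest$tooltips <- length(tt)
  structure(list(format = "html", payload = paste(out, collapse = "\n"),
                 manifest = manifest),
            class = "rendered_document")
}
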