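#' @title Output serialization
#' @description Every successful run writes exactly three files: the genome
#'   PNG, the legend PNG, and a tab-separated pixel-coordinate file (one row
#'   per drawn feature, in draw order). An HTML image map is an optional
#'   fourth output. Pixel origin is top-left, y increasing downward, in both
#'   the PNGs and the coordinate file.
#' @name outputs
NULL

#' Write the three output files of a render
#'
#' @param render a `genome_render` from [render_genome()]
#' @param prefix output path prefix; writes `<prefix>.png`,
#'   `<prefix>.legend.png` and `<prefix>.coords.tsv`
#' @return character vector of the three paths, invisibly
#' @export
write_outputs <- function(render, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  paths <- c(genome = paste0(prefix, ".png"),
             legend = paste0(prefix, ".legend.png"),
             coords = paste0(prefix, ".coords.tsv"))
  ok <- tryCatch({
    png::writePNG(canvas_pixels(render$genome), target = paths["genome"])
    png::writePNG(canvas_pixels(render$legend), target = paths["legend"])
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok))
    stop("cannot write output under '", prefix, "': ", ok, call. = FALSE)
  con <- file(paths["coords"], "w")
  on.exit(close(con))
  writeLines("#name\tx1\ty1\tx2\ty2", con)
  d <- render$drawn
  if (nrow(d))
    writeLines(paste(d$name, d$x1, d$y1, d$x2, d$y2, sep = "\t"), con)
  invisible(paths)
}

#' Read a coordinate file back into a data.frame
#'
#' @param path a `.coords.tsv` written by [write_outputs()]
#' @return data.frame with columns `name, x1, y1, x2, y2`
#' @export
read_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stopifnot(length(lines) >= 1, lines[1] == "#name\tx1\ty1\tx2\ty2")
  body <- lines[-1]
  if (!length(body))
    return(data.frame(name = character(0), x1 = integer(0), y1 = integer(0),
                      x2 = integer(0), y2 = integer(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  data.frame(name = vapply(parts, `[`, character(1), 1),
             x1 = as.integer(vapply(parts, `[`, character(1), 2)),
             y1 = as.integer(vapply(parts, `[`, character(1), 3)),
             x2 = as.integer(vapply(parts, `[`, character(1), 4)),
             y2 = as.integer(vapply(parts, `[`, character(1), 5)),
             stringsAsFactors = FALSE)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Build an HTML client-side image map from drawn features
#'
#' @param drawn data.frame of drawn features (`name, x1, y1, x2, y2`)
#' @param url_template href template containing the literal placeholder
#'   `{name}`, substituted per feature (HTML-escaped)
#' @param map_name value of the map's `name` attribute
#' @return character vector of HTML lines (`<map>` element)
#' @export
write_imagemap <- function(drawn, url_template, map_name = "genome") {
  if (!grepl("{name}", url_template, fixed = TRUE))
    stop("url_template must contain the placeholder {name}", call. = FALSE)
  areas <- character(0)
  if (nrow(drawn)) {
    esc <- .html_escape(drawn$name)
    href <- vapply(esc, function(nm)
      gsub("{name}", nm, url_template, fixed = TRUE), character(1),
      USE.NAMES = FALSE)
    areas <- sprintf(
      '  <area shape="rect" coords="%d,%d,%d,%d" href="%s" title="%s" alt="%s">',
      drawn$x1, drawn$y1, drawn$x2, drawn$y2, href, esc, esc)
  }
  c(sprintf('<map name="%s">', .html_escape(map_name)), areas, "</map>")
}
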