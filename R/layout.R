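#' @title Unit-to-pixel geometry
#' @description Backbones are drawn as parallel vertical bars, top-aligned,
#'   left to right in input order, all sharing one pixels-per-unit scale so
#'   drawn lengths stay proportional to unit spans — the point of a
#'   whole-genome view. The unit axis is continuous: position p on a backbone
#'   starting at s maps to (p - s) units from the bar top.
#' @name layout
NULL

#' Compute the layout frame for a set of backbones
#'
#' The shared scale is chosen so the longest backbone exactly fills the
#' drawable height (image height minus vertical margins and title/label
#' space), unless the config fixes `pixels_per_unit`, in which case a fixed
#' scale that would overflow the image is fatal and the error reports the
#' minimal image height needed.
#'
#' @param backbones data.frame (seqid, start, end, label) as produced by
#'   [partition_features()]
#' @param config a `render_config`
#' @return a `layout_frame`: list with `width`, `height`, `scale`
#'   (px per unit), `margin_top`, `margin_bottom`, `ruler_gutter`, and a
#'   `backbones` data.frame gaining `x_center`, `y_top`, `drawn_len`
#' @export
compute_frame <- function(backbones, config = default_config()) {
  stopifnot(nrow(backbones) >= 1)
  g <- config$general
  title_h <- if (nzchar(g$title))
    unname(text_extent(g$title, g$font_size + 4)[2]) + 8 else 0
  label_h <- unname(text_extent("X", g$font_size)[2]) + 4  # labels above bars
  margin_top <- g$margin + title_h + label_h
  margin_bottom <- g$margin
  gutter <- if (g$ruler == "on") g$ruler_gutter else 0
  n <- nrow(backbones)
  width <- if (g$image_width > 0) g$image_width
           else g$margin + gutter + n * g$chrom_spacing + g$margin
  height <- g$image_height
  drawable <- height - margin_top - margin_bottom
  if (drawable <= 0)
    stop("image_height ", height, " leaves no drawable area below margins",
         call. = FALSE)
  spans <- backbones$end - backbones$start
  max_span <- max(spans)
  if (g$pixels_per_unit > 0) {
    scale <- g$pixels_per_unit
    need <- max_span * scale + margin_top + margin_bottom
    if (max_span * scale > drawable)
      stop(sprintf(paste0("fixed scale %g px/unit overflows the image: ",
                          "longest backbone needs image_height >= %d"),
                   scale, as.integer(ceiling(need))), call. = FALSE)
  } else {
    scale <- drawable / max_span
  }
  bb <- backbones
  bb$x_center <- g$margin + gutter + (seq_len(n) - 0.5) * g$chrom_spacing
  bb$y_top <- rep(margin_top, n)
  bb$drawn_len <- spans * scale
  structure(list(width = as.integer(round(width)),
                 height = as.integer(round(height)),
                 scale = scale, margin_top = margin_top,
                 margin_bottom = margin_bottom, ruler_gutter = gutter,
                 backbones = bb),
            class = "layout_frame")
}

#' @export
print.layout_frame <- function(x, ...) {
  cat(sprintf("<layout_frame> %dx%d px, %d backbone(s), %.6g px/unit\n",
              x$width, x$height, nrow(x$backbones), x$scale))
  invisible(x)
}

#' Map a backbone-unit position to pixel coordinates
#'
#' The mapping is affine and strictly increasing in `pos`:
#' `y = y_top + (pos - start) * scale`, `x = x_center`.
#'
#' @param frame a `layout_frame`
#' @param seqid backbone identifier
#' @param pos unit coordinate, within the backbone's span
#' @return named numeric `c(x, y)` in px
#' @export
to_pixel <- function(frame, seqid, pos) {
  i <- match(seqid, frame$backbones$seqid)
  if (is.na(i)) stop("unknown backbone seqid '", seqid, "'", call. = FALSE)
  bb <- frame$backbones[i, ]
  if (pos < bb$start || pos > bb$end)
    stop(sprintf("position %s outside backbone %s span [%s, %s]",
                 .num_str(pos), seqid, .num_str(bb$start), .num_str(bb$end)),
         call. = FALSE)
  c(x = bb$x_center, y = bb$y_top + (pos - bb$start) * frame$scale)
}

#' Ruler tick positions for the shared unit axis
#'
#' Ticks are computed on the relative axis (0 at each backbone's top) over
#' the longest backbone span. The major step is the largest value of the form
#' 1, 2 or 5 times a power of ten that yields between 4 and 10 major ticks;
#' minor ticks subdivide each major interval in five.
#'
#' @param frame a `layout_frame`
#' @param config a `render_config`
#' @return a `tick_set` data.frame: `pos` (relative units, increasing),
#'   `label` (majors only, `""` for minors), `major` (logical)
#' @export
ruler_ticks <- function(frame, config = default_config()) {
  span <- max(frame$backbones$end - frame$backbones$start)
  step <- .tick_step(span)
  major <- seq(0, span, by = step)
  minor <- seq(0, span, by = step / 5)
  minor <- minor[!minor %in% major]
  pos <- c(major, minor)
  is_major <- c(rep(TRUE, length(major)), rep(FALSE, length(minor)))
  o <- order(pos)
  structure(data.frame(pos = pos[o],
                       label = ifelse(is_major[o], .tick_label(pos[o]), ""),
                       major = is_major[o], stringsAsFactors = FALSE),
            class = c("tick_set", "data.frame"))
}

# largest step in {1,2,5} x 10^k giving 4..10 major ticks (incl. 0 and <= span)
.tick_step <- function(span) {
  stopifnot(span > 0)
  k <- floor(log10(span))
  cand <- sort(as.vector(outer(c(1, 2, 5), 10^((k - 2):(k + 1)))),
               decreasing = TRUE)
  for (step in cand) {
    n <- floor(span / step + 1e-9) + 1
    if (n >= 4 && n <= 10) return(step)
  }
  10^(k - 1)  # unreachable for positive spans; defensive fallback
}

.tick_label <- function(pos) {
  vapply(pos, function(p) {
    if (p == 0) return("0")
    if (abs(p) >= 1e6 && p %% 1e5 == 0) return(paste0(.num_str(p / 1e6), "M"))
    if (abs(p) >= 1e3 && p %% 100 == 0) return(paste0(.num_str(p / 1e3), "K"))
    .num_str(p)
  }, character(1))
}

#' Place text labels with greedy downward collision avoidance
#'
#' Labels keep their preferred anchor when free. When two boxes on the same
#' side of the same backbone overlap vertically, the later one (by anchor y,
#' then input order) is nudged downward by the minimal amount that clears the
#' earlier box plus the configured gap. Boxes are clamped inside the image;
#' a label that cannot fit even after nudging is dropped, with one warning
#' listing all dropped names.
#'
#' @param candidates data.frame with columns `text`, `x` (left edge px),
#'   `y` (top edge px), `side` (grouping key, e.g. "Gm01/right"), and
#'   optionally `size` (font px, default from config)
#' @param frame a `layout_frame`
#' @param config a `render_config`
#' @return data.frame `text, x1, y1, x2, y2, kept` (dropped rows have
#'   `kept = FALSE` and NA coordinates), one row per candidate, input order
#' @export
place_labels <- function(candidates, frame, config = default_config()) {
  n <- nrow(candidates)
  gap <- config$general$label_gap
  size <- if ("size" %in% names(candidates)) candidates$size
          else rep(config$general$font_size, n)
  ext <- t(vapply(seq_len(n), function(i) text_extent(candidates$text[i], size[i]),
                  numeric(2)))
  out <- data.frame(text = candidates$text, x1 = NA_real_, y1 = NA_real_,
                    x2 = NA_real_, y2 = NA_real_, kept = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  ord <- order(candidates$y, seq_len(n))
  dropped <- character(0)
  for (grp in split(ord, candidates$side[ord])) {
    floor_y <- -Inf
    for (i in grp) {
      w <- ext[i, 1]; h <- ext[i, 2]
      x1 <- min(max(candidates$x[i], 1), frame$width - w)
      y1 <- max(candidates$y[i], floor_y, 1)
      if (y1 + h > frame$height) {
        y1 <- frame$height - h           # clamp inward at the bottom edge
        if (y1 < floor_y) { dropped <- c(dropped, candidates$text[i]); next }
      }
      out$x1[i] <- x1; out$y1[i] <- y1
      out$x2[i] <- x1 + w; out$y2[i] <- y1 + h
      out$kept[i] <- TRUE
      floor_y <- y1 + h + gap
    }
  }
  if (length(dropped))
    warning("labels dropped (no room after nudging): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out
}
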