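#' @title Glyph rendering
#' @description Draws backbones and six glyph kinds — centromere overlays,
#'   position shapes, range bars, border bands, marker ticks, histogram bars —
#'   onto a raster canvas, builds the legend, and records one pixel bounding
#'   box per drawn feature for the coordinate file / image map.
#' @name render
NULL

# collector for drawn-feature rows (name, glyph, integer pixel box, locator)
.drawn_new <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- vector("list", 256L); e$n <- 0L; e$anon <- 0L
  e
}

.drawn_add <- function(d, name, glyph, x1, y1, x2, y2, locator, frame) {
  xr <- pmin(pmax(as.integer(round(sort(c(x1, x2)))), 1L), frame$width)
  yr <- pmin(pmax(as.integer(round(sort(c(y1, y2)))), 1L), frame$height)
  n <- d$n + 1L
  if (n > length(d$rows)) d$rows <- c(d$rows, vector("list", length(d$rows)))
  d$rows[[n]] <- data.frame(name = name, glyph = glyph,
                            x1 = xr[1], y1 = yr[1], x2 = xr[2], y2 = yr[2],
                            locator = locator, stringsAsFactors = FALSE)
  d$n <- n
  invisible(d)
}

.drawn_df <- function(d) {
  if (d$n == 0L)
    return(data.frame(name = character(0), glyph = character(0),
                      x1 = integer(0), y1 = integer(0), x2 = integer(0),
                      y2 = integer(0), locator = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, d$rows[seq_len(d$n)])
}

.side_of <- function(offset) if (offset < 0) -1 else 1

# greedy first-fit column assignment for vertically overlapping intervals
.assign_columns <- function(y1, y2) {
  n <- length(y1)
  col <- integer(n)
  last_end <- numeric(0)
  for (i in order(y1, seq_len(n))) {
    placed <- 0L
    for (k in seq_along(last_end)) {
      if (y1[i] > last_end[k]) { placed <- k; break }
    }
    if (placed == 0L) { last_end <- c(last_end, y2[i]); placed <- length(last_end) }
    else last_end[placed] <- y2[i]
    col[i] <- placed
  }
  col
}

#' Draw one backbone bar with its label
#' @param cv canvas; @param frame a `layout_frame`; @param i backbone row index
#' @param config a `render_config`; @param drawn internal collector
#' @keywords internal
draw_backbone <- function(cv, frame, i, config, drawn) {
  bb <- frame$backbones[i, ]
  g <- config$general
  hw <- g$chrom_width / 2
  x1 <- bb$x_center - hw; x2 <- bb$x_center + hw
  y1 <- bb$y_top; y2 <- bb$y_top + bb$drawn_len
  color <- parse_color("gray55")
  r <- hw
  # rounded ends: body rect plus end caps
  cv_rect(cv, x1, y1 + r, x2, y2 - r, color)
  cv_circle(cv, bb$x_center, y1 + r, g$chrom_width, color)
  cv_circle(cv, bb$x_center, y2 - r, g$chrom_width, color)
  ext <- text_extent(bb$label, g$font_size)
  cv_text(cv, bb$x_center - ext[1] / 2, y1 - ext[2] - 4, bb$label,
          parse_color("black"), g$font_size)
  .drawn_add(drawn, bb$label, "backbone", x1, y1, x2, y2,
             sprintf("backbone %s", bb$seqid), frame)
}

#' Draw a centromere overlay (rectangle wider than the backbone bar)
#' @keywords internal
draw_centromere <- function(cv, frame, feature, style, config, drawn, k) {
  bb <- frame$backbones[match(feature$seqid, frame$backbones$seqid), ]
  w <- config$general$chrom_width + 2 * style$overhang
  y1 <- to_pixel(frame, feature$seqid, feature$start)["y"]
  y2 <- to_pixel(frame, feature$seqid, feature$end)["y"]
  cv_rect(cv, bb$x_center - w / 2, y1, bb$x_center + w / 2, y2, style$color)
  .drawn_add(drawn, feature_name(feature, k), "centromere",
             bb$x_center - w / 2, y1, bb$x_center + w / 2, y2,
             .locator(feature), frame)
}

#' Draw a translucent border band across the full backbone width
#' @keywords internal
draw_border <- function(cv, frame, feature, style, config, drawn, k) {
  bb <- frame$backbones[match(feature$seqid, frame$backbones$seqid), ]
  hw <- config$general$chrom_width / 2
  y1 <- to_pixel(frame, feature$seqid, feature$start)["y"]
  y2 <- to_pixel(frame, feature$seqid, feature$end)["y"]
  if (round(y2) - round(y1) < 1) y2 <- y1   # zero-length: 1-px line
  cv_rect(cv, bb$x_center - hw, y1, bb$x_center + hw, y2, style$color)
  .drawn_add(drawn, feature_name(feature, k), "border",
             bb$x_center - hw, y1, bb$x_center + hw, y2, .locator(feature),
             frame)
}

#' Draw a marker tick extending outward from the backbone edge
#' @keywords internal
draw_marker <- function(cv, frame, feature, style, config, drawn, k) {
  bb <- frame$backbones[match(feature$seqid, frame$backbones$seqid), ]
  hw <- config$general$chrom_width / 2
  side <- .side_of(style$offset)
  y <- to_pixel(frame, feature$seqid, (feature$start + feature$end) / 2)["y"]
  x_in <- bb$x_center + side * hw
  x_out <- x_in + side * style$tick_length
  cv_rect(cv, min(x_in, x_out), y, max(x_in, x_out), y, style$color)
  .drawn_add(drawn, feature_name(feature, k), "marker",
             min(x_in, x_out), y, max(x_in, x_out), y, .locator(feature),
             frame)
}

#' Count features into fixed-width bins along a backbone
#'
#' Each feature is counted once, in the bin containing its midpoint
#' `(start + end) / 2`. Bins are half-open `[s + (k-1) b, s + k b)` from the
#' backbone start; the last bin is truncated at the backbone end (a midpoint
#' exactly at the end falls in the last bin). The number of bins is
#' `ceiling(span / bin_size)` and counts always sum to the number of
#' features.
#'
#' @param features list of [genome_feature], all on `backbone`'s seqid
#' @param backbone one-row data.frame (seqid, start, end)
#' @param bin_size bin width in backbone units (> 0)
#' @return a `histogram_series`: list with `seqid`, `bin_size`, `counts`
#'   (integer per bin), `breaks` (bin boundaries, length `nbins + 1`)
#' @export
bin_histogram <- function(features, backbone, bin_size) {
  stopifnot(bin_size > 0)
  span <- backbone$end - backbone$start
  nbins <- as.integer(ceiling(span / bin_size))
  counts <- integer(nbins)
  if (length(features)) {
    mids <- vapply(features, function(f) (f$start + f$end) / 2, numeric(1))
    idx <- pmin(floor((mids - backbone$start) / bin_size) + 1L, nbins)
    tab <- tabulate(idx, nbins)
    counts <- as.integer(tab)
  }
  breaks <- backbone$start + bin_size * (0:nbins)
  breaks[nbins + 1L] <- backbone$end
  structure(list(seqid = backbone$seqid, bin_size = bin_size,
                 counts = counts, breaks = breaks),
            class = "histogram_series")
}

#' @export
print.histogram_series <- function(x, ...) {
  cat(sprintf("<histogram_series> %s: %d bin(s) of %s units, %d feature(s)\n",
              x$seqid, length(x$counts), .num_str(x$bin_size),
              sum(x$counts)))
  invisible(x)
}

#' Draw one histogram series as horizontal bars beside the backbone
#'
#' Bar length is `count / global_max * max_bar_length`; `global_max` is the
#' maximum bin count over every series in the image, so bar lengths are
#' comparable across chromosomes. Zero-count bins draw nothing.
#' @keywords internal
draw_histogram <- function(cv, frame, series, style, config, drawn,
                           global_max) {
  bb <- frame$backbones[match(series$seqid, frame$backbones$seqid), ]
  hw <- config$general$chrom_width / 2
  side <- .side_of(style$offset)
  x0 <- bb$x_center + side * (hw + abs(style$offset))
  for (k in seq_along(series$counts)) {
    cnt <- series$counts[k]
    if (cnt == 0L) next
    len <- cnt / global_max * style$max_bar_length
    y1 <- to_pixel(frame, series$seqid, series$breaks[k])["y"]
    y2 <- to_pixel(frame, series$seqid, series$breaks[k + 1L])["y"]
    x_out <- x0 + side * len
    cv_rect(cv, min(x0, x_out), y1, max(x0, x_out), y2, style$color)
    .drawn_add(drawn, sprintf("%s:density:%d", series$seqid, k), "histogram",
               min(x0, x_out), y1, max(x0, x_out), y2,
               sprintf("%s bin %d (n=%d)", series$seqid, k, cnt), frame)
  }
  invisible(drawn)
}

# draw all range features on one backbone side with outward column stacking
.draw_ranges <- function(cv, frame, feats, styles, config, drawn, ks) {
  y1 <- vapply(feats, function(f) to_pixel(frame, f$seqid, f$start)["y"],
               numeric(1))
  y2 <- vapply(feats, function(f) to_pixel(frame, f$seqid, f$end)["y"],
               numeric(1))
  cols <- .assign_columns(y1, y2)
  hw <- config$general$chrom_width / 2
  for (i in seq_along(feats)) {
    st <- styles[[i]]
    side <- .side_of(st$offset)
    bb <- frame$backbones[match(feats[[i]]$seqid, frame$backbones$seqid), ]
    inner <- bb$x_center + side * (hw + abs(st$offset) +
                                   (cols[i] - 1) * (st$width + st$stack_gap))
    outer <- inner + side * st$width
    cv_rect(cv, min(inner, outer), y1[i], max(inner, outer), y2[i], st$color)
    .drawn_add(drawn, feature_name(feats[[i]], ks[i]), "range",
               min(inner, outer), y1[i], max(inner, outer), y2[i],
               .locator(feats[[i]]), frame)
  }
  invisible(drawn)
}

# draw all position features on one backbone side, stacking outward when the
# glyph boxes overlap vertically
.draw_positions <- function(cv, frame, feats, styles, config, drawn, ks) {
  ym <- vapply(feats, function(f)
    to_pixel(frame, f$seqid, (f$start + f$end) / 2)["y"], numeric(1))
  sizes <- vapply(styles, function(s) s$size, numeric(1))
  cols <- .assign_columns(ym - sizes / 2, ym + sizes / 2)
  hw <- config$general$chrom_width / 2
  for (i in seq_along(feats)) {
    st <- styles[[i]]
    side <- .side_of(st$offset)
    bb <- frame$backbones[match(feats[[i]]$seqid, frame$backbones$seqid), ]
    cx <- bb$x_center + side * (hw + abs(st$offset) + st$size / 2 +
                                (cols[i] - 1) * (st$size + st$stack_gap))
    d <- st$size
    if (st$shape == "circle") cv_circle(cv, cx, ym[i], d, st$color)
    else if (st$shape == "doublecircle") {
      cv_circle(cv, cx, ym[i], d, st$color, hollow = TRUE)
      cv_circle(cv, cx, ym[i], max(1, d - 4), st$color)
    } else cv_rect(cv, cx - d / 2, ym[i] - d / 2, cx + d / 2, ym[i] + d / 2,
                   st$color)
    .drawn_add(drawn, feature_name(feats[[i]], ks[i]), "position",
               cx - d / 2, ym[i] - d / 2, cx + d / 2, ym[i] + d / 2,
               .locator(feats[[i]]), frame)
  }
  invisible(drawn)
}

.draw_ruler <- function(cv, frame, config) {
  g <- config$general
  ticks <- ruler_ticks(frame, config)
  axis_x <- g$margin + g$ruler_gutter - 12
  y0 <- frame$margin_top
  black <- parse_color("black")
  span <- max(frame$backbones$end - frame$backbones$start)
  cv_rect(cv, axis_x, y0, axis_x, y0 + span * frame$scale, black)
  for (i in seq_len(nrow(ticks))) {
    y <- y0 + ticks$pos[i] * frame$scale
    len <- if (ticks$major[i]) 6 else 3
    cv_rect(cv, axis_x - len, y, axis_x, y, black)
    if (ticks$major[i] && nzchar(ticks$label[i])) {
      ext <- text_extent(ticks$label[i], g$font_size - 2)
      cv_text(cv, axis_x - len - 3 - ext[1], y - ext[2] / 2, ticks$label[i],
              black, g$font_size - 2)
    }
  }
}

#' Build the legend image
#'
#' One swatch + label row per distinct (glyph kind, class) actually drawn, in
#' first-appearance order, preceded by a backbone entry.
#'
#' @param entries data.frame with columns `glyph`, `class`, `color`
#'   (list-column of RGBA vectors or hex strings)
#' @param config a `render_config`
#' @return list with `canvas` (the legend image) and `rows` (the de-duplicated
#'   entries data.frame)
#' @export
build_legend <- function(entries, config = default_config()) {
  fs <- config$general$font_size
  rows <- entries[!duplicated(paste(entries$glyph, entries$class, sep = "|")), ,
                  drop = FALSE]
  labels <- ifelse(nzchar(rows$class) & rows$class != rows$glyph,
                   paste0(rows$class, " (", rows$glyph, ")"), rows$glyph)
  row_h <- max(16, text_extent("X", fs)[2] + 6)
  tw <- if (nrow(rows)) max(vapply(labels, function(t) text_extent(t, fs)[1],
                                   numeric(1))) else 0
  cv <- canvas_new(20 + 26 + tw + 20, 10 + row_h * max(1, nrow(rows)) + 10,
                   config$general$background, config$general$background_alpha)
  black <- parse_color("black")
  for (i in seq_len(nrow(rows))) {
    y <- 10 + (i - 1) * row_h
    col <- rows$color[[i]]
    if (is.character(col)) col <- parse_color(col)
    if (rows$glyph[i] == "marker")
      cv_rect(cv, 20, y + row_h / 2, 20 + 18, y + row_h / 2, col)
    else if (rows$glyph[i] == "position")
      cv_rect(cv, 20 + 5, y + row_h / 2 - 4, 20 + 13, y + row_h / 2 + 4, col)
    else cv_rect(cv, 20, y + row_h / 2 - 5, 20 + 18, y + row_h / 2 + 5, col)
    cv_text(cv, 20 + 26, y + row_h / 2 - text_extent("X", fs)[2] / 2,
            labels[i], black, fs)
  }
  list(canvas = cv, rows = cbind(rows, label = labels))
}

#' Render a validated feature collection
#'
#' Produces the genome canvas, the legend canvas, and the drawn-feature table.
#' Draw order (later layers over earlier): backbones, borders, centromeres,
#' ranges, histograms, positions, markers, text labels. Every rendered
#' feature contributes exactly one drawn-feature row, except features routed
#' to the histogram glyph, which are aggregated into one row per non-empty
#' bin. Histogram bar lengths share one normalization across the whole image.
#'
#' @param collection a `feature_collection`
#' @param config a `render_config`
#' @param validate if `TRUE` (default), run [validate_collection()] first and
#'   fail on any error
#' @return a `genome_render`: list with `genome` (canvas), `legend` (canvas),
#'   `drawn` (data.frame name/glyph/x1/y1/x2/y2/locator), `frame`,
#'   `legend_rows`
#' @export
render_genome <- function(collection, config = default_config(),
                          validate = TRUE) {
  if (validate) {
    rep <- validate_collection(collection)
    if (nrow(rep$errors))
      stop("collection failed validation:\n  ",
           paste(sprintf("[%s] %s: %s", rep$errors$rule, rep$errors$locator,
                         rep$errors$message), collapse = "\n  "),
           call. = FALSE)
  }
  frame <- compute_frame(collection$backbones, config)
  g <- config$general
  cv <- canvas_new(frame$width, frame$height, g$background, g$background_alpha)
  drawn <- .drawn_new()
  black <- parse_color("black")

  if (nzchar(g$title)) {
    ext <- text_extent(g$title, g$font_size + 4)
    cv_text(cv, (frame$width - ext[1]) / 2, g$margin / 2, g$title, black,
            g$font_size + 4)
  }
  if (g$ruler == "on") .draw_ruler(cv, frame, config)

  for (i in seq_len(nrow(frame$backbones)))
    draw_backbone(cv, frame, i, config, drawn)

  feats <- collection$features
  kinds <- vapply(feats, function(f) f$style$glyph, character(1))
  ks <- seq_along(feats)   # synthesized-name disambiguator

  for (i in which(kinds == "border"))
    draw_border(cv, frame, feats[[i]], feats[[i]]$style, config, drawn, ks[i])
  for (i in which(kinds == "centromere"))
    draw_centromere(cv, frame, feats[[i]], feats[[i]]$style, config, drawn,
                    ks[i])

  idx_range <- which(kinds == "range")
  if (length(idx_range)) {
    sides <- vapply(idx_range, function(i)
      paste(feats[[i]]$seqid, .side_of(feats[[i]]$style$offset)), character(1))
    for (grp in split(idx_range, sides))
      .draw_ranges(cv, frame, feats[grp], lapply(feats[grp], `[[`, "style"),
                   config, drawn, ks[grp])
  }

  idx_hist <- which(kinds == "histogram")
  series_list <- list(); series_styles <- list()
  if (length(idx_hist)) {
    keys <- vapply(idx_hist, function(i)
      paste(feats[[i]]$seqid, .feature_class(feats[[i]]), sep = "|"),
      character(1))
    for (grp in split(idx_hist, keys)) {
      f1 <- feats[[grp[1]]]
      bbrow <- frame$backbones[match(f1$seqid, frame$backbones$seqid), ]
      series_list[[length(series_list) + 1L]] <-
        bin_histogram(feats[grp], bbrow, f1$style$bin_size)
      series_styles[[length(series_styles) + 1L]] <- f1$style
    }
    global_max <- max(vapply(series_list, function(s)
      max(s$counts, 0L), numeric(1)))
    if (global_max > 0)
      for (j in seq_along(series_list))
        draw_histogram(cv, frame, series_list[[j]], series_styles[[j]],
                       config, drawn, global_max)
  }

  idx_pos <- which(kinds == "position")
  if (length(idx_pos)) {
    sides <- vapply(idx_pos, function(i)
      paste(feats[[i]]$seqid, .side_of(feats[[i]]$style$offset)), character(1))
    for (grp in split(idx_pos, sides))
      .draw_positions(cv, frame, feats[grp], lapply(feats[grp], `[[`, "style"),
                      config, drawn, ks[grp])
  }

  for (i in which(kinds == "marker"))
    draw_marker(cv, frame, feats[[i]], feats[[i]]$style, config, drawn, ks[i])

  # feature text labels (placed after all glyphs so they sit on top)
  want_label <- which(vapply(feats, function(f)
    f$style$label != "none" && !is.na(feature_attr(f, "Name")), logical(1)))
  if (length(want_label)) {
    cand <- do.call(rbind, lapply(want_label, function(i) {
      f <- feats[[i]]
      bb <- frame$backbones[match(f$seqid, frame$backbones$seqid), ]
      y <- to_pixel(frame, f$seqid, (f$start + f$end) / 2)["y"]
      txt <- feature_attr(f, "Name")
      ext <- text_extent(txt, g$font_size)
      lx <- switch(f$style$label,
        left = bb$x_center - g$chrom_width / 2 - 30 - ext[1],
        right = bb$x_center + g$chrom_width / 2 + 30,
        above = bb$x_center - ext[1] / 2,
        below = bb$x_center - ext[1] / 2,
        bb$x_center + g$chrom_width / 2 + 30)
      ly <- switch(f$style$label,
        above = y - ext[2] - 2, below = y + 2, y - ext[2] / 2)
      data.frame(text = txt, x = lx, y = ly,
                 side = paste(f$seqid, f$style$label),
                 stringsAsFactors = FALSE)
    }))
    placed <- place_labels(cand, frame, config)
    for (i in which(placed$kept))
      cv_text(cv, placed$x1[i], placed$y1[i], placed$text[i], black,
              g$font_size)
  }

  drawn_df <- .drawn_df(drawn)
  entries <- data.frame(glyph = "backbone", class = "backbone",
                        stringsAsFactors = FALSE)
  entries$color <- list(parse_color("gray55"))
  featrows <- drawn_df[drawn_df$glyph != "backbone", , drop = FALSE]
  if (length(feats)) {
    first_of_kind <- !duplicated(vapply(feats, function(f)
      paste(f$style$glyph, .feature_class(f), sep = "|"), character(1)))
    extra <- do.call(rbind, lapply(which(first_of_kind), function(i) {
      data.frame(glyph = feats[[i]]$style$glyph,
                 class = .feature_class(feats[[i]]), stringsAsFactors = FALSE)
    }))
    if (!is.null(extra)) {
      extra$color <- lapply(which(first_of_kind), function(i)
        feats[[i]]$style$color)
      entries <- rbind(entries, extra)
    }
  }
  legend <- build_legend(entries, config)

  structure(list(genome = cv, legend = legend$canvas, drawn = drawn_df,
                 frame = frame, legend_rows = legend$rows),
            class = "genome_render")
}

#' @export
print.genome_render <- function(x, ...) {
  cat(sprintf("<genome_render> %dx%d px, %d drawn feature(s), %d legend row(s)\n",
              x$frame$width, x$frame$height, nrow(x$drawn),
              nrow(x$legend_rows)))
  invisible(x)
}
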