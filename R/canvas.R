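# Raster canvas. Draw calls record operations; rasterization happens in one
# pass over local channel matrices (cheap in-place updates), then the result
# is cached. Coordinates are 1-based pixel indices, origin top-left, y down.
# No anti-aliasing anywhere: identical inputs give byte-identical buffers.

#' Create a drawing canvas
#' @param width,height image dimensions in px (positive integers)
#' @param background background color spec
#' @param background_alpha background alpha in [0, 1]
#' @return a `canvas` (environment recording draw operations)
#' @keywords internal
canvas_new <- function(width, height, background = "white",
                       background_alpha = 1) {
  cv <- new.env(parent = emptyenv())
  cv$width <- as.integer(max(1, round(width)))
  cv$height <- as.integer(max(1, round(height)))
  cv$bg <- parse_color(background, background_alpha)
  cv$ops <- vector("list", 64L)
  cv$n_ops <- 0L
  cv$pixels <- NULL
  class(cv) <- "canvas"
  cv
}

.cv_push <- function(cv, op) {
  n <- cv$n_ops + 1L
  if (n > length(cv$ops)) cv$ops <- c(cv$ops, vector("list", length(cv$ops)))
  cv$ops[[n]] <- op
  cv$n_ops <- n
  cv$pixels <- NULL
  invisible(cv)
}

#' Fill an axis-aligned rectangle (alpha-composited over)
#' @param cv canvas; @param x1,y1,x2,y2 pixel bounds; @param color RGBA [0,1]
#' @keywords internal
cv_rect <- function(cv, x1, y1, x2, y2, color) {
  .cv_push(cv, list(kind = "rect", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                    color = color))
}

#' Fill a circle of diameter d centered at (cx, cy)
#' @keywords internal
cv_circle <- function(cv, cx, cy, d, color, hollow = FALSE) {
  .cv_push(cv, list(kind = "circle", cx = cx, cy = cy, d = d, color = color,
                    hollow = hollow))
}

#' Draw text with its top-left corner at (x, y)
#' @keywords internal
cv_text <- function(cv, x, y, text, color, size = 10) {
  .cv_push(cv, list(kind = "text", x = x, y = y, text = text, color = color,
                    size = size))
}

#' Rasterize a canvas to an RGBA pixel array
#'
#' Compositing runs over four function-local channel matrices so slice
#' assignments stay in place (no whole-buffer copies per glyph).
#'
#' @param cv a `canvas`
#' @return numeric array `height x width x 4`, values in [0, 1], as written
#'   by [png::writePNG()]
#' @keywords internal
canvas_pixels <- function(cv) {
  if (!is.null(cv$pixels)) return(cv$pixels)
  w <- cv$width; h <- cv$height
  rm <- matrix(cv$bg[1], h, w); gm <- matrix(cv$bg[2], h, w)
  bm <- matrix(cv$bg[3], h, w); am <- matrix(cv$bg[4], h, w)
  clampx <- function(x) min(max(as.integer(round(x)), 1L), w)
  clampy <- function(y) min(max(as.integer(round(y)), 1L), h)
  for (i in seq_len(cv$n_ops)) {
    op <- cv$ops[[i]]
    mask <- NULL
    if (op$kind == "rect") {
      if (round(op$x2) < 1 || round(op$x1) > w ||
          round(op$y2) < 1 || round(op$y1) > h) next
      cols <- clampx(op$x1):clampx(op$x2)
      rows <- clampy(op$y1):clampy(op$y2)
    } else if (op$kind == "circle") {
      rad <- op$d / 2
      cols <- clampx(op$cx - rad):clampx(op$cx + rad)
      rows <- clampy(op$cy - rad):clampy(op$cy + rad)
      dx <- outer(rep(1, length(rows)), cols - op$cx)
      dy <- outer(rows - op$cy, rep(1, length(cols)))
      mask <- dx * dx + dy * dy <= rad * rad
      if (isTRUE(op$hollow))
        mask <- mask & (dx * dx + dy * dy >= (rad - 1.5)^2)
      if (!any(mask)) next
    } else if (op$kind == "text") {
      m <- .rasterize_text(op$text, op$size)
      if (!length(m)) next
      x1 <- as.integer(round(op$x)); y1 <- as.integer(round(op$y))
      cols_all <- x1:(x1 + ncol(m) - 1L)
      rows_all <- y1:(y1 + nrow(m) - 1L)
      keep_c <- cols_all >= 1L & cols_all <= w
      keep_r <- rows_all >= 1L & rows_all <= h
      if (!any(keep_c) || !any(keep_r)) next
      cols <- cols_all[keep_c]; rows <- rows_all[keep_r]
      mask <- m[keep_r, keep_c, drop = FALSE]
      if (!any(mask)) next
    } else next
    a <- op$color[4]
    if (a <= 0) next
    ia <- 1 - a
    if (is.null(mask)) {
      rm[rows, cols] <- op$color[1] * a + rm[rows, cols] * ia
      gm[rows, cols] <- op$color[2] * a + gm[rows, cols] * ia
      bm[rows, cols] <- op$color[3] * a + bm[rows, cols] * ia
      am[rows, cols] <- a + am[rows, cols] * ia
    } else {
      sr <- rm[rows, cols, drop = FALSE]; sg <- gm[rows, cols, drop = FALSE]
      sb <- bm[rows, cols, drop = FALSE]; sa <- am[rows, cols, drop = FALSE]
      sr[mask] <- op$color[1] * a + sr[mask] * ia
      sg[mask] <- op$color[2] * a + sg[mask] * ia
      sb[mask] <- op$color[3] * a + sb[mask] * ia
      sa[mask] <- a + sa[mask] * ia
      rm[rows, cols] <- sr; gm[rows, cols] <- sg
      bm[rows, cols] <- sb; am[rows, cols] <- sa
    }
  }
  px <- array(0, dim = c(h, w, 4L))
  px[, , 1] <- rm; px[, , 2] <- gm; px[, , 3] <- bm; px[, , 4] <- am
  cv$pixels <- px
  px
}

#' @export
print.canvas <- function(x, ...) {
  cat(sprintf("<canvas> %dx%d px, %d draw op(s)\n", x$width, x$height,
              x$n_ops))
  invisible(x)
}
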