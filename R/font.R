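# 5x7 bitmap face used for all text. Each glyph is five column bytes, bit 0 =
# top row. Lowercase maps to uppercase; unknown characters draw a hollow box.
# Rasterizing text from a face defined in source keeps every output image
# byte-deterministic across platforms and font stacks.

.font5x7 <- list(
  " " = c(0x00, 0x00, 0x00, 0x00, 0x00),
  "!" = c(0x00, 0x00, 0x5F, 0x00, 0x00),
  "#" = c(0x14, 0x7F, 0x14, 0x7F, 0x14),
  "%" = c(0x23, 0x13, 0x08, 0x64, 0x62),
  "(" = c(0x00, 0x1C, 0x22, 0x41, 0x00),
  ")" = c(0x00, 0x41, 0x22, 0x1C, 0x00),
  "+" = c(0x08, 0x08, 0x3E, 0x08, 0x08),
  "," = c(0x00, 0x50, 0x30, 0x00, 0x00),
  "-" = c(0x08, 0x08, 0x08, 0x08, 0x08),
  "." = c(0x00, 0x60, 0x60, 0x00, 0x00),
  "/" = c(0x20, 0x10, 0x08, 0x04, 0x02),
  "0" = c(0x3E, 0x51, 0x49, 0x45, 0x3E),
  "1" = c(0x00, 0x42, 0x7F, 0x40, 0x00),
  "2" = c(0x42, 0x61, 0x51, 0x49, 0x46),
  "3" = c(0x21, 0x41, 0x45, 0x4B, 0x31),
  "4" = c(0x18, 0x14, 0x12, 0x7F, 0x10),
  "5" = c(0x27, 0x45, 0x45, 0x45, 0x39),
  "6" = c(0x3C, 0x4A, 0x49, 0x49, 0x30),
  "7" = c(0x01, 0x71, 0x09, 0x05, 0x03),
  "8" = c(0x36, 0x49, 0x49, 0x49, 0x36),
  "9" = c(0x06, 0x49, 0x49, 0x29, 0x1E),
  ":" = c(0x00, 0x36, 0x36, 0x00, 0x00),
  ";" = c(0x00, 0x56, 0x36, 0x00, 0x00),
  "=" = c(0x14, 0x14, 0x14, 0x14, 0x14),
  "?" = c(0x02, 0x01, 0x51, 0x09, 0x06),
  "A" = c(0x7E, 0x11, 0x11, 0x11, 0x7E),
  "B" = c(0x7F, 0x49, 0x49, 0x49, 0x36),
  "C" = c(0x3E, 0x41, 0x41, 0x41, 0x22),
  "D" = c(0x7F, 0x41, 0x41, 0x22, 0x1C),
  "E" = c(0x7F, 0x49, 0x49, 0x49, 0x41),
  "F" = c(0x7F, 0x09, 0x09, 0x09, 0x01),
  "G" = c(0x3E, 0x41, 0x49, 0x49, 0x7A),
  "H" = c(0x7F, 0x08, 0x08, 0x08, 0x7F),
  "I" = c(0x00, 0x41, 0x7F, 0x41, 0x00),
  "J" = c(0x20, 0x40, 0x41, 0x3F, 0x01),
  "K" = c(0x7F, 0x08, 0x14, 0x22, 0x41),
  "L" = c(0x7F, 0x40, 0x40, 0x40, 0x40),
  "M" = c(0x7F, 0x02, 0x0C, 0x02, 0x7F),
  "N" = c(0x7F, 0x04, 0x08, 0x10, 0x7F),
  "O" = c(0x3E, 0x41, 0x41, 0x41, 0x3E),
  "P" = c(0x7F, 0x09, 0x09, 0x09, 0x06),
  "Q" = c(0x3E, 0x41, 0x51, 0x21, 0x5E),
  "R" = c(0x7F, 0x09, 0x19, 0x29, 0x46),
  "S" = c(0x46, 0x49, 0x49, 0x49, 0x31),
  "T" = c(0x01, 0x01, 0x7F, 0x01, 0x01),
  "U" = c(0x3F, 0x40, 0x40, 0x40, 0x3F),
  "V" = c(0x1F, 0x20, 0x40, 0x20, 0x1F),
  "W" = c(0x3F, 0x40, 0x38, 0x40, 0x3F),
  "X" = c(0x63, 0x14, 0x08, 0x14, 0x63),
  "Y" = c(0x07, 0x08, 0x70, 0x08, 0x07),
  "Z" = c(0x61, 0x51, 0x49, 0x45, 0x43),
  "[" = c(0x00, 0x7F, 0x41, 0x41, 0x00),
  "]" = c(0x00, 0x41, 0x41, 0x7F, 0x00),
  "_" = c(0x40, 0x40, 0x40, 0x40, 0x40))

.font_box <- c(0x7F, 0x41, 0x41, 0x41, 0x7F)

.glyph_columns <- function(ch) {
  g <- .font5x7[[ch]]
  if (is.null(g)) g <- .font5x7[[toupper(ch)]]
  if (is.null(g)) g <- .font_box
  g
}

# integer scale factor approximating a requested pixel height (7 rows/glyph)
.font_scale <- function(size) max(1L, as.integer(round(size / 7)))

#' Pixel extent of a text string in the built-in face
#' @param text character scalar
#' @param size requested glyph height in px (rounded to a multiple of 7)
#' @return c(width, height) in px
#' @export
text_extent <- function(text, size = 10) {
  s <- .font_scale(size)
  n <- nchar(text)
  w <- if (n == 0L) 0L else (6L * n - 1L) * s
  c(width = w, height = 7L * s)
}

# logical matrix (rows = 7*s, cols = text width) of lit pixels
.rasterize_text <- function(text, size = 10) {
  s <- .font_scale(size)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(matrix(FALSE, 0, 0))
  wid <- 6L * n - 1L
  m <- matrix(FALSE, 7L, wid)
  for (i in seq_len(n)) {
    cols <- .glyph_columns(chars[i])
    for (j in 1:5) {
      bits <- bitwAnd(bitwShiftR(cols[j], 0:6), 1L) == 1L
      m[, (i - 1L) * 6L + j] <- bits
    }
  }
  if (s > 1L) m <- m[rep(seq_len(nrow(m)), each = s),
                     rep(seq_len(ncol(m)), each = s), drop = FALSE]
  m
}
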