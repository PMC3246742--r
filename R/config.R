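#' @title Layered render configuration
#' @description Almost every aspect of the output image is configurable: a
#'   built-in default layer, overlaid by an INI-style file, overlaid by
#'   `section.key=value` command-line overrides (CLI > file > defaults).
#' @name config
NULL

# 10 high-contrast fill colors; classes are assigned by first appearance
.palette10 <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
                "#A65628", "#F781BF", "#17BECF", "#666666", "#BCBD22")

#' Parse a color specification to RGBA in [0, 1]
#'
#' Accepts any name known to R's color database (a superset of the CSS names)
#' or `#RRGGBB` / `#RRGGBBAA` hex.
#'
#' @param spec character color name or hex string
#' @param alpha extra alpha multiplier in [0, 1]
#' @return numeric length-4 vector (r, g, b, a), each in [0, 1]
#' @export
parse_color <- function(spec, alpha = 1) {
  rgba <- tryCatch(grDevices::col2rgb(spec, alpha = TRUE)[, 1] / 255,
                   error = function(e)
                     stop("unknown color '", spec, "'", call. = FALSE))
  rgba[4] <- rgba[4] * alpha
  unname(rgba)
}

.glyph_kinds <- c("centromere", "position", "range", "border", "marker",
                  "histogram")

.default_glyphs <- function() list(
  centromere = list(color = "black", overhang = 4, label = "none",
                    transparency = 1),
  position   = list(color = "", shape = "rect", size = 6, offset = 10,
                    label = "none", transparency = 1, stack_gap = 2),
  range      = list(color = "", width = 8, offset = -14, label = "none",
                    transparency = 1, stack_gap = 2),
  border     = list(color = "gray50", label = "none", transparency = 0.5),
  marker     = list(color = "black", tick_length = 8, offset = 2,
                    label = "none", transparency = 1),
  histogram  = list(color = "green4", bin_size = 400000, max_bar_length = 60,
                    offset = 4, label = "none", transparency = 1))

#' Built-in default configuration
#'
#' @return a `render_config` list with components `general` (image options),
#'   `glyphs` (per-glyph-kind defaults) and `rules` (override rules, empty)
#' @export
default_config <- function() {
  structure(list(
    general = list(
      image_width = 0,          # 0 = derived from backbone count and spacing
      image_height = 700,
      margin = 40,
      chrom_spacing = 70,
      chrom_width = 16,
      background = "white",
      background_alpha = 1,
      title = "",
      font_size = 10,
      ruler = "on",
      ruler_gutter = 56,
      pixels_per_unit = 0,      # 0 = fit longest backbone to drawable height
      backbone_type = "chromosome",
      point_threshold = 1,      # span <= this (units) draws a position glyph
      label_gap = 2),
    glyphs = .default_glyphs(),
    rules = list()),
    class = "render_config")
}

#' @export
print.render_config <- function(x, ...) {
  cat(sprintf("<render_config> %dx%s px, %d override rule(s)\n",
              x$general$image_width,
              x$general$image_height, length(x$rules)))
  invisible(x)
}

.numeric_keys <- c("image_width", "image_height", "margin", "chrom_spacing",
                   "chrom_width", "background_alpha", "font_size",
                   "ruler_gutter", "pixels_per_unit", "point_threshold",
                   "label_gap", "overhang", "size", "offset", "width",
                   "transparency", "stack_gap", "tick_length", "bin_size",
                   "max_bar_length")

.coerce_value <- function(section, key, value) {
  if (key %in% .numeric_keys) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v))
      stop("config [", section, "] ", key, ": '", value, "' is not numeric",
           call. = FALSE)
    return(v)
  }
  value
}

.check_config <- function(config) {
  g <- config$general
  if (g$pixels_per_unit < 0)
    stop("config [general] pixels_per_unit: must be >= 0", call. = FALSE)
  for (k in c("image_height", "margin", "chrom_spacing", "chrom_width",
              "font_size", "label_gap"))
    if (g[[k]] < 0) stop("config [general] ", k, ": must be >= 0", call. = FALSE)
  if (g$background_alpha < 0 || g$background_alpha > 1)
    stop("config [general] background_alpha: must be in [0, 1]", call. = FALSE)
  if (!g$ruler %in% c("on", "off"))
    stop("config [general] ruler: must be 'on' or 'off'", call. = FALSE)
  for (kind in names(config$glyphs)) {
    gl <- config$glyphs[[kind]]
    if (!is.null(gl$transparency) && (gl$transparency < 0 || gl$transparency > 1))
      stop("config [", kind, "] transparency: must be in [0, 1]", call. = FALSE)
    if (!is.null(gl$bin_size) && gl$bin_size <= 0)
      stop("config [", kind, "] bin_size: must be > 0", call. = FALSE)
  }
  for (r in config$rules) {
    if (!is.null(r$style$glyph) && !r$style$glyph %in% .glyph_kinds)
      stop("config [rule ", r$name, "] glyph: unknown glyph kind '",
           r$style$glyph, "'", call. = FALSE)
  }
  invisible(config)
}

# parse INI text into list(section -> named character vector), keeping
# section order; repeated [rule ...] sections stay distinct
.parse_ini <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in seq_along(lines)) {
    line <- sub("[#;].*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      current <- length(sections) + 1L
      sections[[current]] <- list(name = gsub("^\\[|\\]$", "", line),
                                  keys = character(0))
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (is.null(current) || eq < 0L)
      stop("config line ", ln, ": expected '[section]' or 'key = value', got '",
           lines[ln], "'", call. = FALSE)
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    sections[[current]]$keys[key] <- val
  }
  sections
}

.apply_section <- function(config, section, keys, origin) {
  if (section == "general") {
    for (k in names(keys)) {
      if (!k %in% names(config$general)) {
        warning("unknown config key [general] ", k, " (", origin, "), ignored",
                call. = FALSE)
        next
      }
      v <- .coerce_value("general", k, keys[[k]])
      if (k == "backbone_type")
        v <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
      config$general[[k]] <- v
    }
  } else if (section %in% .glyph_kinds) {
    for (k in names(keys)) {
      if (!k %in% names(config$glyphs[[section]])) {
        warning("unknown config key [", section, "] ", k, " (", origin,
                "), ignored", call. = FALSE)
        next
      }
      config$glyphs[[section]][[k]] <- .coerce_value(section, k, keys[[k]])
    }
  } else if (startsWith(section, "rule")) {
    match <- list(); style <- list()
    for (k in names(keys)) {
      v <- keys[[k]]
      if (k %in% c("match_source", "match_type", "match_class"))
        match[[sub("^match_", "", k)]] <- v
      else style[[k]] <- .coerce_value(section, k, v)
    }
    config$rules[[length(config$rules) + 1L]] <-
      list(name = trimws(sub("^rule", "", section)), match = match,
           style = style)
  } else {
    warning("unknown config section [", section, "] (", origin, "), ignored",
            call. = FALSE)
  }
  config
}

#' Load a configuration file with layered precedence
#'
#' Builds the effective configuration as defaults, overlaid by the file's
#' values, overlaid by command-line overrides (`section.key=value`). Unknown
#' keys warn; type-invalid values (non-numeric where a number is required,
#' negative scale, transparency outside [0, 1]) are fatal and name the key.
#'
#' File dialect: INI sections `[general]`, one per glyph kind
#' (`[centromere]`, `[position]`, `[range]`, `[border]`, `[marker]`,
#' `[histogram]`), and any number of `[rule NAME]` override sections whose
#' `match_source` / `match_type` / `match_class` keys select features and
#' whose remaining keys (including `glyph`) restyle them. `#` starts a
#' comment.
#'
#' @param path config file path, or `NULL` for defaults only
#' @param overrides character vector of `section.key=value` CLI overrides
#' @return a `render_config`
#' @export
load_config <- function(path = NULL, overrides = character(0)) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    for (sec in .parse_ini(readLines(path, warn = FALSE)))
      config <- .apply_section(config, sec$name, sec$keys, origin = path)
  }
  if (length(overrides)) {
    parsed <- lapply(overrides, function(ov) {
      parts <- regmatches(ov, regexec("^([^.=]+)\\.([^=]+)=(.*)$", ov))[[1]]
      if (!length(parts))
        stop("override '", ov, "' is not section.key=value", call. = FALSE)
      parts[-1]
    })
    secs <- vapply(parsed, `[`, character(1), 1)
    for (sec in unique(secs)) {
      of <- parsed[secs == sec]
      config <- .apply_section(
        config, sec,
        stats::setNames(vapply(of, `[`, character(1), 3),
                        vapply(of, `[`, character(1), 2)),
        origin = "command line")
    }
  }
  .check_config(config)
}

#' Deterministic class-to-color assignment
#'
#' Classes without an explicit color draw from a fixed 10-color palette in
#' first-appearance order; from the 11th distinct class onward colors repeat
#' (index modulo palette length).
#'
#' @param features list of [genome_feature]
#' @param config a `render_config`
#' @return named character vector: class -> hex color
#' @export
assign_class_colors <- function(features, config = default_config()) {
  classes <- unique(vapply(features, .feature_class, character(1)))
  if (!length(classes)) return(stats::setNames(character(0), character(0)))
  stats::setNames(.palette10[(seq_along(classes) - 1L) %% length(.palette10) + 1L],
                  classes)
}

.rule_matches <- function(rule, feature) {
  m <- rule$match
  if (length(m) == 0L) return(FALSE)
  if (!is.null(m$source) && !identical(m$source, feature$source)) return(FALSE)
  if (!is.null(m$type) && !identical(m$type, feature$ftype)) return(FALSE)
  if (!is.null(m$class) && !identical(m$class, .feature_class(feature)))
    return(FALSE)
  TRUE
}

.dispatch_glyph <- function(feature, config) {
  if (feature$ftype == "centromere") return("centromere")
  span <- feature$end - feature$start
  if (span <= config$general$point_threshold) "position" else "range"
}

#' Resolve the concrete drawing style for one feature
#'
#' Resolution layers, lowest to highest: glyph-kind defaults; the class
#' palette color; the first matching `[rule]` section (file order); a
#' feature-level `color` GFF attribute. The result is fully concrete — every
#' option the glyph kind needs has a value.
#'
#' @param feature a [genome_feature]
#' @param config a `render_config`
#' @param class_colors optional precomputed map from [assign_class_colors()];
#'   computed from the single feature when omitted
#' @return a `glyph_style` list: `glyph`, `color` (RGBA in [0,1]), plus the
#'   kind's options (shape/size/width/offset/overhang/tick_length/bin_size/
#'   max_bar_length/label/font_size/stack_gap/transparency as applicable)
#' @export
resolve_style <- function(feature, config = default_config(),
                          class_colors = NULL) {
  if (is.null(class_colors))
    class_colors <- assign_class_colors(list(feature), config)

  rule <- NULL
  for (r in config$rules) if (.rule_matches(r, feature)) { rule <- r; break }

  kind <- if (!is.null(rule) && !is.null(rule$style$glyph)) rule$style$glyph
          else .dispatch_glyph(feature, config)
  style <- config$glyphs[[kind]]
  style$glyph <- kind
  style$font_size <- config$general$font_size

  if (!is.null(rule))
    for (k in setdiff(names(rule$style), "glyph")) {
      if (!k %in% c(names(style), "color"))
        warning("rule '", rule$name, "': key '", k, "' not used by glyph '",
                kind, "'", call. = FALSE)
      style[[k]] <- rule$style[[k]]
    }

  cl <- .feature_class(feature)
  if (!nzchar(style$color))
    style$color <- unname(class_colors[cl])
  if (is.na(style$color) || !nzchar(style$color)) style$color <- .palette10[1]
  fcol <- feature_attr(feature, "color")
  if (!is.na(fcol) && nzchar(fcol)) {
    # resolution must always succeed: a bad color attribute falls back
    ok <- tryCatch({ parse_color(fcol); TRUE }, error = function(e) FALSE)
    if (ok) style$color <- fcol
    else warning("feature at ", .locator(feature), ": unknown color '",
                 fcol, "', using class color", call. = FALSE)
  }

  style$color <- parse_color(style$color, alpha = style$transparency)
  structure(style, class = "glyph_style")
}
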