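#' @title GFF3 reading, validation and writing
#' @description Flat GFF3 records are the package's lingua franca: backbones
#'   (chromosomes, linkage groups, pseudomolecules) and the features drawn on
#'   them all arrive as 9-column records. Coordinates are kept as doubles so
#'   genetic-map (centimorgan) and cytological units work unchanged.
#' @name gff_io
NULL

# accept a path, a single text blob, or a character vector of lines
.read_lines_or_text <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  out <- unlist(strsplit(as.character(x), "\n", fixed = TRUE),
                use.names = FALSE)
  if (is.null(out)) character(0) else out
}

# characters GFF3 requires to be percent-encoded inside attribute values
.gff_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x <- gsub("\n", "%0A", x, fixed = TRUE)
  x
}

.gff_decode <- function(x) {
  vapply(x, function(s) {
    if (!grepl("%", s, fixed = TRUE)) return(s)
    utils::URLdecode(s)
  }, character(1), USE.NAMES = FALSE)
}

# shortest decimal representation that round-trips through as.numeric
.num_str <- function(x) {
  s <- as.character(x)
  bad <- !is.na(x) & (as.numeric(s) != x)
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' Construct a single genome feature record
#'
#' @param seqid backbone identifier (GFF3 column 1)
#' @param source producer tag (column 2)
#' @param ftype feature type (column 3)
#' @param start,end 1-based inclusive coordinates in backbone units; doubles
#'   are accepted so non-integer unit systems (cM, cMC) are first-class
#' @param score numeric score or `NA`
#' @param strand one of `"+"`, `"-"`, `"."`, `"?"`
#' @param attributes named character vector decoded from column 9
#' @param line source line number, if known (used in error messages)
#' @return an object of class `genome_feature`
#' @export
genome_feature <- function(seqid, source = ".", ftype, start, end,
                           score = NA_real_, strand = ".",
                           attributes = character(0), line = NA_integer_) {
  stopifnot(nzchar(seqid), is.numeric(start), is.numeric(end))
  if (end < start) stop("feature on '", seqid, "': end < start")
  if (anyDuplicated(names(attributes)))
    stop("feature on '", seqid, "': duplicate attribute keys")
  structure(list(seqid = as.character(seqid), source = as.character(source),
                 ftype = as.character(ftype), start = as.numeric(start),
                 end = as.numeric(end), score = as.numeric(score),
                 strand = as.character(strand),
                 attributes = attributes, line = as.integer(line)),
            class = "genome_feature")
}

#' @export
print.genome_feature <- function(x, ...) {
  at <- if (length(x$attributes))
    paste(names(x$attributes), x$attributes, sep = "=", collapse = ";") else "."
  cat(sprintf("<genome_feature> %s %s [%s, %s] %s %s\n", x$seqid, x$ftype,
              .num_str(x$start), .num_str(x$end), x$strand, at))
  invisible(x)
}

#' Look up a feature attribute, case-insensitively
#'
#' GFF3 in the wild mixes `Name`/`name` and `class`/`Class`; the renderer's
#' reserved keys are matched without regard to case. Other keys are matched
#' exactly first, then case-insensitively.
#'
#' @param feature a `genome_feature`
#' @param key attribute key
#' @param default value returned when the key is absent
#' @return attribute value (character) or `default`
#' @export
feature_attr <- function(feature, key, default = NA_character_) {
  at <- feature$attributes
  if (length(at) == 0L) return(default)
  i <- match(key, names(at))
  if (is.na(i)) i <- match(tolower(key), tolower(names(at)))
  if (is.na(i)) default else unname(at[i])
}

#' Display name of a feature (Name attribute, else a synthesized id)
#' @param feature a `genome_feature`
#' @param k disambiguating index used when no Name is present
#' @return character scalar
#' @export
feature_name <- function(feature, k = 1L) {
  nm <- feature_attr(feature, "Name")
  if (!is.na(nm) && nzchar(nm)) return(nm)
  sprintf("%s:%s-%s:%d", feature$seqid, .num_str(feature$start),
          .num_str(feature$end), k)
}

.parse_attributes <- function(col9, line) {
  if (col9 == "." || col9 == "") return(character(0))
  parts <- strsplit(col9, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  keys <- character(length(parts)); vals <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0L)
      stop("line ", line, ": attribute '", p, "' is not key=value")
    keys[i] <- .gff_decode(trimws(substr(p, 1L, eq - 1L)))
    vals[i] <- .gff_decode(substr(p, eq + 1L, nchar(p)))
  }
  if (anyDuplicated(keys))
    stop("line ", line, ": duplicate attribute key '",
         keys[anyDuplicated(keys)], "'")
  stats::setNames(vals, keys)
}

#' Parse GFF3 text into genome feature records
#'
#' Comment (`#`) lines and `##` directives are skipped; an embedded `##FASTA`
#' section terminates parsing. Attribute values are percent-decoded. Input
#' order is preserved. All malformed data lines are collected and reported in
#' a single error naming their line numbers.
#'
#' @param x a file path, or a character vector of GFF3 lines / text
#' @return list of [genome_feature] records (empty list for header-only input)
#' @export
parse_gff <- function(x) {
  lines <- .read_lines_or_text(x)
  records <- vector("list", length(lines))
  errors <- character(0)
  n <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "##FASTA")) break
    if (startsWith(line, "#")) next
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) != 9L) {
      errors <- c(errors, sprintf("line %d: expected 9 tab-separated columns, got %d",
                                  ln, length(cols)))
      next
    }
    start <- suppressWarnings(as.numeric(cols[4]))
    end <- suppressWarnings(as.numeric(cols[5]))
    if (is.na(start) || is.na(end)) {
      errors <- c(errors, sprintf("line %d: non-numeric coordinates '%s'..'%s'",
                                  ln, cols[4], cols[5]))
      next
    }
    score <- if (cols[6] == ".") NA_real_ else suppressWarnings(as.numeric(cols[6]))
    if (cols[6] != "." && is.na(score)) {
      errors <- c(errors, sprintf("line %d: non-numeric score '%s'", ln, cols[6]))
      next
    }
    rec <- tryCatch(
      genome_feature(seqid = cols[1], source = cols[2], ftype = cols[3],
                     start = start, end = end, score = score,
                     strand = cols[7],
                     attributes = .parse_attributes(cols[9], ln), line = ln),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) { errors <- c(errors, rec); next }
    rec$phase <- cols[8]
    n <- n + 1L
    records[[n]] <- rec
  }
  if (length(errors))
    stop("malformed GFF3 input:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  records[seq_len(n)]
}

#' Serialize genome feature records as GFF3 text
#'
#' Inverse of [parse_gff()]: `parse_gff(write_gff(x))` reproduces every field,
#' including attributes (values percent-encoded where GFF3 requires).
#'
#' @param records list of [genome_feature]
#' @param path optional file path; when given the text is also written there
#' @return character vector of GFF3 lines, invisibly when `path` is given
#' @export
write_gff <- function(records, path = NULL) {
  lines <- c("##gff-version 3", vapply(records, function(r) {
    at <- if (length(r$attributes))
      paste(.gff_encode(names(r$attributes)), .gff_encode(unname(r$attributes)),
            sep = "=", collapse = ";") else "."
    paste(r$seqid, r$source, r$ftype, .num_str(r$start), .num_str(r$end),
          if (is.na(r$score)) "." else .num_str(r$score),
          r$strand, if (is.null(r$phase)) "." else r$phase, at, sep = "\t")
  }, character(1)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Split parsed records into backbones and drawable features
#'
#' Records whose type is one of the configured backbone types (default
#' `"chromosome"`) become backbones, in input order; everything else becomes a
#' feature, annotated with its resolved glyph style and grouped by
#' (glyph kind, class). At least one backbone record is required.
#'
#' @param records list of [genome_feature] from [parse_gff()]
#' @param config a render configuration from [load_config()]
#' @return a `feature_collection`: list with `backbones` (data.frame: seqid,
#'   start, end, label), `features` (list of records, each carrying a
#'   `$style`), `groups` (named list of feature indices per "kind|class"),
#'   and `class_colors`
#' @export
partition_features <- function(records, config = default_config()) {
  btypes <- config$general$backbone_type
  is_bb <- vapply(records, function(r) r$ftype %in% btypes, logical(1))
  if (!any(is_bb))
    stop("no chromosome records: input must contain at least one record of type ",
         paste(sQuote(btypes), collapse = "/"), call. = FALSE)
  bbs <- records[is_bb]
  seqids <- vapply(bbs, `[[`, character(1), "seqid")
  if (anyDuplicated(seqids))
    stop("duplicate backbone seqid(s): ",
         paste(unique(seqids[duplicated(seqids)]), collapse = ", "),
         call. = FALSE)
  backbones <- data.frame(
    seqid = seqids,
    start = vapply(bbs, `[[`, numeric(1), "start"),
    end = vapply(bbs, `[[`, numeric(1), "end"),
    label = vapply(seq_along(bbs), function(i) {
      nm <- feature_attr(bbs[[i]], "Name")
      if (is.na(nm) || !nzchar(nm)) seqids[i] else nm
    }, character(1)),
    stringsAsFactors = FALSE)
  bad <- backbones$end <= backbones$start
  if (any(bad))
    stop("backbone(s) with end <= start: ",
         paste(backbones$seqid[bad], collapse = ", "), call. = FALSE)

  features <- records[!is_bb]
  class_colors <- assign_class_colors(features, config)
  features <- lapply(features, function(f) {
    f$style <- resolve_style(f, config, class_colors)
    f
  })
  keys <- vapply(features, function(f)
    paste(f$style$glyph, .feature_class(f), sep = "|"), character(1))
  groups <- split(seq_along(features), factor(keys, levels = unique(keys)))
  structure(list(backbones = backbones, features = features,
                 groups = groups, class_colors = class_colors),
            class = "feature_collection")
}

#' @export
print.feature_collection <- function(x, ...) {
  cat(sprintf("<feature_collection> %d backbone(s), %d feature(s), %d group(s)\n",
              nrow(x$backbones), length(x$features), length(x$groups)))
  invisible(x)
}

.feature_class <- function(f) {
  cl <- feature_attr(f, "class")
  if (is.na(cl) || !nzchar(cl)) f$ftype else cl
}

.locator <- function(f) {
  if (!is.na(f$line)) sprintf("line %d (%s %s..%s)", f$line, f$seqid,
                              .num_str(f$start), .num_str(f$end))
  else sprintf("%s %s..%s", f$seqid, .num_str(f$start), .num_str(f$end))
}

#' Validate a feature collection against its backbones
#'
#' Reports (never throws): an error for every feature whose seqid matches no
#' backbone, and for every feature not contained within its backbone's
#' coordinate span; a warning for every feature that requests a text label but
#' carries no Name attribute. A collection is renderable iff `errors` is empty.
#'
#' @param collection a `feature_collection` from [partition_features()]
#' @return a `validation_report`: list with data.frames `errors` and
#'   `warnings` (columns `locator`, `rule`, `message`)
#' @export
validate_collection <- function(collection) {
  bb <- collection$backbones
  err <- list(); wrn <- list()
  for (f in collection$features) {
    i <- match(f$seqid, bb$seqid)
    if (is.na(i)) {
      err[[length(err) + 1L]] <- c(.locator(f), "unknown-seqid",
        sprintf("feature seqid '%s' matches no backbone", f$seqid))
      next
    }
    if (f$start < bb$start[i] || f$end > bb$end[i])
      err[[length(err) + 1L]] <- c(.locator(f), "out-of-bounds",
        sprintf("feature [%s, %s] outside backbone %s [%s, %s]",
                .num_str(f$start), .num_str(f$end), f$seqid,
                .num_str(bb$start[i]), .num_str(bb$end[i])))
    if (!is.null(f$style) && f$style$label != "none" &&
        is.na(feature_attr(f, "Name")))
      wrn[[length(wrn) + 1L]] <- c(.locator(f), "missing-name",
        "label requested but record has no Name attribute")
  }
  as_df <- function(x) {
    if (!length(x)) return(data.frame(locator = character(0),
                                      rule = character(0),
                                      message = character(0),
                                      stringsAsFactors = FALSE))
    m <- do.call(rbind, x)
    data.frame(locator = m[, 1], rule = m[, 2], message = m[, 3],
               stringsAsFactors = FALSE)
  }
  structure(list(errors = as_df(err), warnings = as_df(wrn)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    for (i in seq_len(nrow(x$errors)))
      cat("  ERROR [", x$errors$rule[i], "] ", x$errors$locator[i], ": ",
          x$errors$message[i], "\n", sep = "")
  }
  invisible(x)
}
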