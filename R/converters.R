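#' @title BLAST converters
#' @description Two preparation utilities for display-ready GFF: lifting
#'   tabular BLAST hits onto genomic coordinates through a peptide/gene
#'   location GFF (or a plain query-to-peptide id map), and collapsing runs
#'   of adjacent HSPs from the same query into single intervals with a
#'   gap-threshold sliding window.
#' @name converters
NULL

#' Read NCBI BLAST tabular output (12-column outfmt 6)
#'
#' Minus-strand subject coordinates (start > end) are normalized to
#' start <= end with strand recorded as `"-"`.
#'
#' @param x file path or character vector of lines
#' @return data.frame with columns qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore, strand
#' @export
read_blast_table <- function(x) {
  lines <- .read_lines_or_text(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = numeric(0),
                      mismatch = numeric(0), gapopen = numeric(0),
                      qstart = numeric(0), qend = numeric(0),
                      sstart = numeric(0), send = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("BLAST tabular line(s) without 12 fields: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  col <- function(i) vapply(parts, `[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v))
      stop("non-numeric ", what, " in BLAST tabular input (line ",
           which(is.na(v))[1], ")", call. = FALSE)
    v
  }
  d <- data.frame(qseqid = col(1), sseqid = col(2), pident = num(3, "pident"),
                  length = num(4, "length"), mismatch = num(5, "mismatch"),
                  gapopen = num(6, "gapopen"), qstart = num(7, "qstart"),
                  qend = num(8, "qend"), sstart = num(9, "sstart"),
                  send = num(10, "send"), evalue = num(11, "evalue"),
                  bitscore = num(12, "bitscore"), stringsAsFactors = FALSE)
  rev <- d$sstart > d$send
  tmp <- d$sstart[rev]; d$sstart[rev] <- d$send[rev]; d$send[rev] <- tmp
  d$strand <- ifelse(rev, "-", "+")
  d
}

#' Read a two-column query-id to peptide-id map
#'
#' Whitespace- or tab-delimited; many-to-many pairs allowed.
#'
#' @param x file path or character vector of lines
#' @return data.frame with columns `qseqid`, `pepid`
#' @export
read_idmap <- function(x) {
  lines <- .read_lines_or_text(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("id map line(s) without exactly 2 columns: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  data.frame(qseqid = vapply(parts, `[`, character(1), 1),
             pepid = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# index peptide records by Name (falling back to ID), case as given
.peptide_index <- function(peptides) {
  ids <- vapply(peptides, function(p) {
    nm <- feature_attr(p, "Name")
    if (is.na(nm) || !nzchar(nm)) nm <- feature_attr(p, "ID")
    if (is.na(nm)) "" else nm
  }, character(1))
  keep <- nzchar(ids)
  split(which(keep), ids[keep])
}

#' Lift BLAST hits (or id pairs) onto genomic coordinates
#'
#' For each hit (or id-map pair) whose subject/peptide id matches a located
#' peptide, emits one GFF feature at the peptide's genomic seqid/start/end
#' with `Name` and `class` set to the query id. For BLAST input the hit
#' e-value is carried in the score column (0.0 is the best possible value).
#' Matching is many-to-many: a query hitting a peptide with several locations
#' yields one feature per location. Unmatched subjects are skipped and
#' counted; zero matches overall is an error (usually an id-format mismatch).
#'
#' @param hits data.frame from [read_blast_table()], or `NULL`
#' @param idmap data.frame from [read_idmap()], or `NULL` (exactly one of
#'   `hits`/`idmap` must be given)
#' @param peptides list of [genome_feature] giving peptide/gene locations,
#'   with `Name` (or `ID`) matching the subject/peptide ids
#' @param source source tag for emitted records
#' @return list with `features` (list of [genome_feature]) and `skipped`
#'   (count of unmatched input rows)
#' @export
blast_to_gff <- function(hits = NULL, idmap = NULL, peptides,
                         source = "blast") {
  if (is.null(hits) == is.null(idmap))
    stop("provide exactly one of 'hits' or 'idmap'", call. = FALSE)
  index <- .peptide_index(peptides)
  pairs <- if (!is.null(hits))
    data.frame(q = hits$qseqid, s = hits$sseqid, score = hits$evalue,
               stringsAsFactors = FALSE)
  else data.frame(q = idmap$qseqid, s = idmap$pepid, score = NA_real_,
                  stringsAsFactors = FALSE)
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    locs <- index[[pairs$s[i]]]
    if (is.null(locs)) { skipped <- skipped + 1L; next }
    for (j in locs) {
      p <- peptides[[j]]
      out[[length(out) + 1L]] <- genome_feature(
        seqid = p$seqid, source = source, ftype = "match",
        start = p$start, end = p$end, score = pairs$score[i],
        strand = p$strand,
        attributes = c(Name = pairs$q[i], class = pairs$q[i]))
    }
  }
  if (!length(out))
    stop("zero matches: no subject/peptide id in the input matches a ",
         "located peptide (check id formats)", call. = FALSE)
  list(features = out, skipped = skipped)
}

#' Collapse adjacent HSPs within a sliding window
#'
#' Within each (seqid, Name) group, features are sorted by start and any run
#' in which every gap (next start minus previous end) is at most `window`
#' units is merged into a single feature spanning the run. A merged feature
#' keeps the group's Name and seqid, gains an `hsp_count` attribute, and its
#' score becomes the best (minimum) e-value among members with a score.
#' Singleton runs pass through unchanged. Features never merge across seqid
#' or query Name. The operation is idempotent, and the output feature count
#' is non-increasing in `window`.
#'
#' @param features list of [genome_feature] carrying `Name` attributes
#' @param window maximum gap in backbone units (>= 0)
#' @return list of [genome_feature], grouped runs merged, group order by
#'   first appearance
#' @export
cluster_hsps <- function(features, window) {
  if (length(window) != 1L || is.na(window) || window < 0)
    stop("window must be a single number >= 0", call. = FALSE)
  if (!length(features)) return(features)
  keys <- vapply(features, function(f)
    paste(f$seqid, feature_attr(f, "Name", default = ""), sep = "\r"),
    character(1))
  out <- list()
  for (grp in split(seq_along(features), factor(keys, levels = unique(keys)))) {
    fs <- features[grp]
    ord <- order(vapply(fs, `[[`, numeric(1), "start"),
                 vapply(fs, `[[`, numeric(1), "end"))
    fs <- fs[ord]
    run <- list(fs[[1]])
    flush <- function(run) {
      if (length(run) == 1L) return(run[[1]])
      starts <- vapply(run, `[[`, numeric(1), "start")
      ends <- vapply(run, `[[`, numeric(1), "end")
      scores <- vapply(run, `[[`, numeric(1), "score")
      prev_n <- sum(vapply(run, function(f) {
        n <- feature_attr(f, "hsp_count")
        if (is.na(n)) 1L else as.integer(n)
      }, integer(1)))
      strands <- unique(vapply(run, `[[`, character(1), "strand"))
      f1 <- run[[1]]
      at <- f1$attributes
      at <- at[names(at) != "hsp_count"]
      at["hsp_count"] <- as.character(prev_n)
      genome_feature(seqid = f1$seqid, source = f1$source, ftype = f1$ftype,
                     start = min(starts), end = max(ends),
                     score = if (all(is.na(scores))) NA_real_
                             else min(scores, na.rm = TRUE),
                     strand = if (length(strands) == 1L) strands else ".",
                     attributes = at)
    }
    if (length(fs) > 1L) for (i in 2:length(fs)) {
      prev_end <- max(vapply(run, `[[`, numeric(1), "end"))
      if (fs[[i]]$start - prev_end <= window) run[[length(run) + 1L]] <- fs[[i]]
      else { out[[length(out) + 1L]] <- flush(run); run <- list(fs[[i]]) }
    }
    out[[length(out) + 1L]] <- flush(run)
  }
  out
}
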