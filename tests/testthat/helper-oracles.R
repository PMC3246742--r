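# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: interval merging by pairwise transitive closure,
# bin counting by explicit per-interval scans, containment by a direct
# double loop.

# transitive-closure interval merger: repeatedly merge any pair of intervals
# whose gap is <= window, until no pair qualifies (order-independent)
bf_merge <- function(iv, window) {
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i >= j) next
        gap <- max(iv[i, 1], iv[j, 1]) - min(iv[i, 2], iv[j, 2])
        if (gap <= window) {
          newiv <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- rbind(iv[-c(i, j), , drop = FALSE], newiv)
          iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) return(iv)
  }
}

# per-interval midpoint counter (half-open bins, last bin closed at end)
bf_bin_counts <- function(mids, start, end, bin) {
  nbins <- as.integer(ceiling((end - start) / bin))
  counts <- integer(nbins)
  for (k in seq_len(nbins)) {
    lo <- start + (k - 1) * bin
    hi <- start + k * bin
    counts[k] <- if (k == nbins) sum(mids >= lo & mids <= end)
                 else sum(mids >= lo & mids < hi)
  }
  counts
}

# direct containment / seqid checker for a feature collection
bf_collection_valid <- function(collection) {
  bb <- collection$backbones
  for (f in collection$features) {
    i <- match(f$seqid, bb$seqid)
    if (is.na(i)) return(FALSE)
    if (f$start < bb$start[i] || f$end > bb$end[i]) return(FALSE)
  }
  TRUE
}

# random GFF record with awkward attribute values (forces percent-encoding)
random_record <- function(seqids = c("chr1", "chr2", "Gm09")) {
  seqid <- sample(seqids, 1)
  start <- round(stats::runif(1, 1, 1e6), 3)
  end <- start + round(stats::runif(1, 0, 1e5), 3)
  nat <- sample(0:3, 1)
  at <- character(0)
  if (nat > 0) {
    keys <- sample(c("Name", "class", "tag", "note", "x1"), nat)
    vals <- replicate(nat, paste(sample(c(letters, ";", "=", "%", ",", " ",
                                          "&"), 6, replace = TRUE),
                                 collapse = ""))
    at <- stats::setNames(vals, keys)
  }
  genome_feature(seqid = seqid,
                 source = sample(c(".", "synth", "blast"), 1),
                 ftype = sample(c("gene", "marker", "match"), 1),
                 start = start, end = end,
                 score = if (stats::runif(1) < 0.5) NA_real_
                         else signif(stats::runif(1, 0, 1), 4),
                 strand = sample(c("+", "-", ".", "?"), 1),
                 attributes = at)
}

record_fields_equal <- function(a, b) {
  identical(a$seqid, b$seqid) && identical(a$source, b$source) &&
    identical(a$ftype, b$ftype) && isTRUE(all.equal(a$start, b$start)) &&
    isTRUE(all.equal(a$end, b$end)) &&
    ((is.na(a$score) && is.na(b$score)) ||
       isTRUE(all.equal(a$score, b$score))) &&
    identical(a$strand, b$strand) && identical(a$attributes, b$attributes)
}

# minimal one-chromosome genome used by several smoke tests
minimal_gff <- function() {
  c("##gff-version 3",
    "chr1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=chr1",
    "chr1\t.\tcentromere\t400\t600\t.\t.\t.\tName=cen1",
    "chr1\t.\tgene\t100\t200\t.\t+\t.\tName=g1;class=a",
    "chr1\t.\tgene\t700\t900\t.\t-\t.\tName=g2;class=b")
}

# list of genome_feature from interval rows for clustering tests
intervals_to_features <- function(iv, seqid = "chr1", name = "q1",
                                  scores = NULL) {
  lapply(seq_len(nrow(iv)), function(i)
    genome_feature(seqid = seqid, source = "blast", ftype = "match",
                   start = iv[i, 1], end = iv[i, 2],
                   score = if (is.null(scores)) NA_real_ else scores[i],
                   attributes = c(Name = name, class = name)))
}
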