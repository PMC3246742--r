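#' @title Seeded synthetic-genome generator
#' @description Produces GFF genomes, BLAST tables and id maps with known
#'   ground truth, so layout, binning, clustering and the converters can be
#'   tested without downloading any real genome. The default shape emulates a
#'   maize-scale genome: 10 chromosomes of 150-300 Mbp, a centromere near the
#'   middle of each, gene models depleted around the pericentromere, synteny
#'   blocks pairing chromosomes, and per-query HSP chains with known gaps.
#'   Only coordinates and counts are simulated, never sequence content.
#' @name fixtures
NULL

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic genome
#'
#' @param n_chrom number of chromosomes
#' @param span_range chromosome length range in units (bp-scale by default)
#' @param centromere_frac range of the centromere midpoint as a fraction of
#'   the chromosome span
#' @param genes_per_chrom gene models per chromosome
#' @param gene_density `"uniform"` or `"pericentromere_depleted"` (genes near
#'   the centromere are accepted with probability 0.15)
#' @param synteny_per_chrom synteny blocks per chromosome, each assigned a
#'   partner chromosome and colored by class `synteny_<partner>`
#' @param n_queries BLAST queries
#' @param hsps_per_query HSPs per query chain (consecutive on one chromosome)
#' @param hsp_gap_range range of the gap between consecutive HSPs, in units
#' @param seed RNG seed; identical specs give byte-identical outputs
#' @return a `genome_spec`
#' @export
genome_spec <- function(n_chrom = 10, span_range = c(1.5e8, 3e8),
                        centromere_frac = c(0.35, 0.65),
                        genes_per_chrom = 100,
                        gene_density = c("pericentromere_depleted", "uniform"),
                        synteny_per_chrom = 3, n_queries = 5,
                        hsps_per_query = 4, hsp_gap_range = c(1e3, 5e4),
                        seed = 1) {
  gene_density <- match.arg(gene_density)
  stopifnot(n_chrom >= 1, all(span_range > 0), genes_per_chrom >= 0,
            synteny_per_chrom >= 0, n_queries >= 0, hsps_per_query >= 1,
            all(hsp_gap_range >= 0))
  structure(list(n_chrom = n_chrom, span_range = span_range,
                 centromere_frac = centromere_frac,
                 genes_per_chrom = genes_per_chrom,
                 gene_density = gene_density,
                 synteny_per_chrom = synteny_per_chrom,
                 n_queries = n_queries, hsps_per_query = hsps_per_query,
                 hsp_gap_range = hsp_gap_range, seed = seed),
            class = "genome_spec")
}

#' Generate a synthetic genome with ground truth
#'
#' @param spec a [genome_spec()]
#' @param dir optional directory; when given, writes `backbones.gff`,
#'   `features.gff`, `blast.tsv`, `idmap.tsv` and `truth_*.tsv` there
#' @return list with `backbone_gff` and `feature_gff` (GFF3 line vectors),
#'   `blast` (12-column tabular lines), `idmap` (2-column lines), and `truth`:
#'   `chrom` (data.frame seqid/start/end/centromere/counts), `gene_mids`
#'   (named list of gene midpoints per seqid), `chains` (list per query:
#'   `qseqid`, `seqid`, `intervals` matrix, `gaps`), `seed`
#' @export
generate_genome <- function(spec, dir = NULL) {
  out <- .with_seed(spec$seed, {
    seqids <- sprintf("chr%02d", seq_len(spec$n_chrom))
    spans <- round(stats::runif(spec$n_chrom, spec$span_range[1],
                                spec$span_range[2]))
    bb_records <- lapply(seq_len(spec$n_chrom), function(i)
      genome_feature(seqid = seqids[i], source = "synth",
                     ftype = "chromosome", start = 1, end = spans[i],
                     attributes = c(Name = seqids[i])))

    feats <- list()
    cen <- matrix(0, spec$n_chrom, 2)
    gene_mids <- stats::setNames(vector("list", spec$n_chrom), seqids)
    for (i in seq_len(spec$n_chrom)) {
      mid <- stats::runif(1, spec$centromere_frac[1], spec$centromere_frac[2]) *
        spans[i]
      half <- stats::runif(1, 0.01, 0.025) * spans[i]
      cen[i, ] <- round(c(max(1, mid - half), min(spans[i], mid + half)))
      feats[[length(feats) + 1L]] <- genome_feature(
        seqid = seqids[i], source = "synth", ftype = "centromere",
        start = cen[i, 1], end = cen[i, 2],
        attributes = c(Name = paste0(seqids[i], "_cen")))

      mids <- numeric(0)
      avoid_lo <- mid - 0.1 * spans[i]; avoid_hi <- mid + 0.1 * spans[i]
      while (length(mids) < spec$genes_per_chrom) {
        m <- stats::runif(1, 2500, spans[i] - 2500)
        if (spec$gene_density == "pericentromere_depleted" &&
            m > avoid_lo && m < avoid_hi && stats::runif(1) > 0.15) next
        mids <- c(mids, m)
      }
      mids <- round(mids)
      lens <- round(stats::runif(spec$genes_per_chrom, 500, 5000))
      gstart <- pmax(1, mids - lens %/% 2)
      gend <- pmin(spans[i], gstart + lens)
      for (k in seq_len(spec$genes_per_chrom))
        feats[[length(feats) + 1L]] <- genome_feature(
          seqid = seqids[i], source = "synth", ftype = "gene",
          start = gstart[k], end = gend[k],
          attributes = c(Name = sprintf("%s_g%03d", seqids[i], k),
                         class = "gene"))
      gene_mids[[i]] <- (gstart + gend) / 2
    }

    n_syn <- 0L
    if (spec$synteny_per_chrom > 0 && spec$n_chrom > 1) {
      for (i in seq_len(spec$n_chrom)) for (k in seq_len(spec$synteny_per_chrom)) {
        partner <- sample(setdiff(seq_len(spec$n_chrom), i), 1)
        len <- stats::runif(1, 0.05, 0.15) * spans[i]
        s <- round(stats::runif(1, 1, spans[i] - len))
        n_syn <- n_syn + 1L
        feats[[length(feats) + 1L]] <- genome_feature(
          seqid = seqids[i], source = "synth", ftype = "synteny_block",
          start = s, end = round(s + len),
          attributes = c(Name = sprintf("syn%03d", n_syn),
                         class = paste0("synteny_", seqids[partner])))
      }
    }

    blast <- character(0)
    chains <- list()
    idmap <- character(0)
    if (spec$n_queries > 0) {
      for (q in seq_len(spec$n_queries)) {
        qid <- sprintf("q%02d", q)
        ci <- sample(spec$n_chrom, 1)
        gaps <- round(stats::runif(spec$hsps_per_query - 1,
                                   spec$hsp_gap_range[1],
                                   spec$hsp_gap_range[2]))
        lens <- round(stats::runif(spec$hsps_per_query, 200, 2000))
        total <- sum(lens) + sum(gaps)
        s0 <- round(stats::runif(1, 1, max(1, spans[ci] - total - 1)))
        starts <- s0 + cumsum(c(0, utils::head(lens, -1) + gaps))
        ends <- starts + lens
        ev <- 10^(-round(stats::runif(spec$hsps_per_query, 5, 50)))
        qpos <- 1
        for (h in seq_len(spec$hsps_per_query)) {
          blast <- c(blast, paste(qid, seqids[ci],
                                  sprintf("%.2f", stats::runif(1, 80, 100)),
                                  lens[h], round(lens[h] * 0.05), 0,
                                  qpos, qpos + lens[h] - 1,
                                  starts[h], ends[h],
                                  .num_str(ev[h]),
                                  round(lens[h] * 1.8), sep = "\t"))
          qpos <- qpos + lens[h]
        }
        chains[[qid]] <- list(qseqid = qid, seqid = seqids[ci],
                              intervals = cbind(start = starts, end = ends),
                              gaps = gaps)
        # id map: each query also maps to one generated gene (peptide proxy)
        gi <- sample(spec$genes_per_chrom, 1)
        idmap <- c(idmap, paste(qid, sprintf("%s_g%03d", seqids[ci], gi),
                                sep = "\t"))
      }
    }

    truth <- list(
      seed = spec$seed,
      chrom = data.frame(seqid = seqids, start = 1, end = spans,
                         cen_start = cen[, 1], cen_end = cen[, 2],
                         n_genes = spec$genes_per_chrom,
                         n_synteny = if (spec$n_chrom > 1)
                           spec$synteny_per_chrom else 0,
                         stringsAsFactors = FALSE),
      gene_mids = gene_mids, chains = chains)
    list(backbone_gff = write_gff(bb_records),
         feature_gff = write_gff(feats), blast = blast, idmap = idmap,
         truth = truth)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(out$backbone_gff, file.path(dir, "backbones.gff"))
    writeLines(out$feature_gff, file.path(dir, "features.gff"))
    writeLines(out$blast, file.path(dir, "blast.tsv"))
    writeLines(out$idmap, file.path(dir, "idmap.tsv"))
    tr <- out$truth
    utils::write.table(tr$chrom, file.path(dir, "truth_chrom.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gm <- data.frame(seqid = rep(names(tr$gene_mids),
                                 lengths(tr$gene_mids)),
                     mid = unlist(tr$gene_mids, use.names = FALSE))
    utils::write.table(gm, file.path(dir, "truth_gene_mids.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ch <- do.call(rbind, lapply(tr$chains, function(c0)
      data.frame(qseqid = c0$qseqid, seqid = c0$seqid,
                 start = c0$intervals[, 1], end = c0$intervals[, 2],
                 stringsAsFactors = FALSE)))
    if (!is.null(ch))
      utils::write.table(ch, file.path(dir, "truth_chains.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  out
}

#' Brute-force per-bin gene counts from generator truth
#'
#' Counts midpoints interval by interval (`lo <= mid < hi`, last bin closed
#' at the backbone end) — an oracle independent of the renderer's bin-index
#' arithmetic.
#'
#' @param truth the `truth` component of [generate_genome()] output
#' @param seqid chromosome id
#' @param bin_size bin width in units
#' @return integer vector of per-bin counts
#' @export
truth_bin_counts <- function(truth, seqid, bin_size) {
  row <- truth$chrom[truth$chrom$seqid == seqid, ]
  stopifnot(nrow(row) == 1)
  mids <- truth$gene_mids[[seqid]]
  span <- row$end - row$start
  nbins <- as.integer(ceiling(span / bin_size))
  counts <- integer(nbins)
  for (k in seq_len(nbins)) {
    lo <- row$start + (k - 1) * bin_size
    hi <- if (k == nbins) row$end else row$start + k * bin_size
    counts[k] <- if (k == nbins) sum(mids >= lo & mids <= hi)
                 else sum(mids >= lo & mids < hi)
  }
  counts
}
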