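coll_of <- function(lines, cfg = default_config())
  partition_features(parse_gff(lines), cfg)

pixels <- function(cv) genoglyph:::canvas_pixels(cv)

test_that("histogram binning: midpoint rule, half-open bins, truncated tail", {
  bb <- data.frame(seqid = "c1", start = 1, end = 1e6)
  mk <- function(mid) genome_feature("c1", ".", "gene", mid, mid)
  series <- bin_histogram(lapply(c(100, 250, 399999, 400001), mk), bb, 400000)
  expect_equal(series$counts, c(3L, 1L, 0L))
  expect_length(series$counts, 3)          # ceil(1e6 / 4e5) bins

  expect_equal(bin_histogram(list(), bb, 400000)$counts, c(0L, 0L, 0L))

  # a midpoint exactly on the backbone end lands in the last bin
  series <- bin_histogram(list(mk(1e6)), bb, 400000)
  expect_equal(series$counts, c(0L, 0L, 1L))
})

test_that("histogram counts conserve and match a brute-force counter", {
  set.seed(202)
  for (trial in 1:40) {
    span <- stats::runif(1, 1e3, 1e7)
    start <- sample(c(0, 1), 1)
    bb <- data.frame(seqid = "c1", start = start, end = start + span)
    n <- sample(0:60, 1)
    feats <- replicate(n, {
      s <- stats::runif(1, bb$start, bb$end)
      e <- min(bb$end, s + stats::runif(1, 0, span / 20))
      genome_feature("c1", ".", "gene", s, e)
    }, simplify = FALSE)
    bin <- stats::runif(1, span / 30, span / 2)
    series <- bin_histogram(feats, bb, bin)
    expect_equal(sum(series$counts), n)
    mids <- vapply(feats, function(f) (f$start + f$end) / 2, numeric(1))
    expect_equal(series$counts, bf_bin_counts(mids, bb$start, bb$end, bin))
  }
})

test_that("histogram bars normalize globally across chromosomes", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c2\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c2",
         # c1: 3 genes in bin 1, 1 in bin 2; c2: 1 gene in bin 1
         sprintf("c1\t.\tgene\t%d\t%d\t.\t+\t.\tName=a%d;class=g",
                 c(10, 20, 30, 600), c(12, 22, 32, 602), 1:4),
         "c2\t.\tgene\t40\t42\t.\t+\t.\tName=b1;class=g")
  ini <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[rule genes]", "match_class = g", "glyph = histogram",
               "bin_size = 500", "max_bar_length = 60"), ini)
  cfg <- load_config(ini)
  r <- render_genome(coll_of(g, cfg), cfg)
  bars <- r$drawn[r$drawn$glyph == "histogram", ]
  lens <- bars$x2 - bars$x1
  # counts 3, 1, 1 with shared max 3 -> lengths 60, 20, 20 (+-1 px raster)
  expect_equal(sort(lens, decreasing = TRUE), c(60, 20, 20), tolerance = 0.03)
})

test_that("backbone, centromere and range geometry follow the affine map", {
  cfg <- default_config()
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tcentromere\t400\t600\t.\t.\t.\tName=cen",
         "c1\t.\tgene\t1\t500\t.\t+\t.\tName=g1;class=a")
  r <- render_genome(coll_of(g, cfg), cfg)
  d <- r$drawn
  bbrow <- d[d$glyph == "backbone", ]
  # bar width and drawn length
  expect_equal(bbrow$x2 - bbrow$x1, cfg$general$chrom_width)
  expect_equal(bbrow$y2 - bbrow$y1, round(r$frame$backbones$drawn_len[1]),
               tolerance = 1)
  cen <- d[d$glyph == "centromere", ]
  # overhang 4 px each side over a 16 px bar
  expect_equal(cen$x2 - cen$x1,
               cfg$general$chrom_width + 2 * cfg$glyphs$centromere$overhang)
  expect_equal(cen$y2 - cen$y1, round(200 / 999 * r$frame$backbones$drawn_len[1]),
               tolerance = 1)
  rng <- d[d$glyph == "range", ]
  # [1,500] on a span-999 backbone: half the drawn length, left of center
  expect_equal(rng$y2 - rng$y1, round(r$frame$backbones$drawn_len[1] / 2),
               tolerance = 1)
  expect_lt(rng$x2, r$frame$backbones$x_center[1])
})

test_that("overlapping ranges stack outward; disjoint ranges share a column", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tgene\t1\t500\t.\t+\t.\tName=r1;class=a",
         "c1\t.\tgene\t100\t600\t.\t+\t.\tName=r2;class=a",
         "c1\t.\tgene\t700\t900\t.\t+\t.\tName=r3;class=a")
  r <- render_genome(coll_of(g), default_config())
  d <- r$drawn[r$drawn$glyph == "range", ]
  d <- d[match(c("r1", "r2", "r3"), d$name), ]
  expect_true(d$x1[2] < d$x1[1])            # overlapping: next column outward
  expect_equal(d$x1[3], d$x1[1])            # disjoint: same column as r1
  # no two bars in the same column overlap in y (brute force)
  same_col <- which(d$x1 == d$x1[1])
  for (i in same_col) for (j in same_col)
    if (i < j) expect_false(d$y1[i] <= d$y2[j] && d$y1[j] <= d$y2[i])
})

test_that("coincident position glyphs displace outward by size + gap", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tSNP\t500\t500\t.\t+\t.\tName=p1;class=s",
         "c1\t.\tSNP\t500\t500\t.\t+\t.\tName=p2;class=s",
         "c1\t.\tSNP\t50\t50\t.\t+\t.\tName=p3;class=s")
  cfg <- default_config()
  r <- render_genome(coll_of(g, cfg), cfg)
  d <- r$drawn[r$drawn$glyph == "position", ]
  d <- d[match(c("p1", "p2", "p3"), d$name), ]
  st <- cfg$glyphs$position
  expect_equal(d$x1[2] - d$x1[1], st$size + st$stack_gap)
  expect_equal(d$x1[3], d$x1[1])            # far-away glyph keeps column 1
  expect_equal(d$x2[1] - d$x1[1], st$size)
})

test_that("markers are ticks outward from the bar edge on the offset side", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tmarker\t250\t250\t.\t.\t.\tName=m1;class=m")
  ini <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[rule m]", "match_type = marker", "glyph = marker"), ini)
  cfg <- load_config(ini)
  r <- render_genome(coll_of(g, cfg), cfg)
  m <- r$drawn[r$drawn$glyph == "marker", ]
  edge <- r$frame$backbones$x_center[1] + cfg$general$chrom_width / 2
  expect_gte(m$x1, floor(edge))             # strictly right of the bar edge
  expect_equal(m$x2 - m$x1, cfg$glyphs$marker$tick_length)
  expect_equal(m$y1, m$y2)
})

test_that("border bands span the bar width and alpha-blend over it", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tregion\t100\t200\t.\t.\t.\tName=b1;class=b")
  ini <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[rule b]", "match_class = b", "glyph = border",
               "color = red", "transparency = 0.5"), ini)
  cfg <- load_config(ini)
  r <- render_genome(coll_of(g, cfg), cfg)
  b <- r$drawn[r$drawn$glyph == "border", ]
  expect_equal(b$x2 - b$x1, cfg$general$chrom_width)
  px <- pixels(r$genome)
  mid <- c(round((b$y1 + b$y2) / 2), round((b$x1 + b$x2) / 2))
  # red at alpha .5 over the gray55 bar: r = .5*1 + .5*.55
  expect_equal(px[mid[1], mid[2], 1], 0.5 + 0.5 * 0.55, tolerance = 0.02)
})

test_that("rect glyph pixel coverage matches its bounding box exactly", {
  cv <- genoglyph:::canvas_new(40, 30, "white")
  genoglyph:::cv_rect(cv, 5, 7, 12, 19, parse_color("red"))
  px <- pixels(cv)
  changed <- which(px[, , 1] != 1 | px[, , 2] != 1 | px[, , 3] != 1,
                   arr.ind = TRUE)
  expect_equal(range(changed[, "row"]), c(7, 19))
  expect_equal(range(changed[, "col"]), c(5, 12))
  expect_equal(nrow(changed), (19 - 7 + 1) * (12 - 5 + 1))
})

test_that("render draw-order fixture yields one row per drawn feature", {
  set.seed(31)
  lines <- c("c1\t.\tchromosome\t1\t10000\t.\t.\t.\tName=c1",
             "c2\t.\tchromosome\t1\t8000\t.\t.\t.\tName=c2",
             "c1\t.\tcentromere\t4000\t5000\t.\t.\t.\tName=cen1",
             "c2\t.\tcentromere\t3000\t4000\t.\t.\t.\tName=cen2")
  for (i in 1:100) {
    sq <- sample(c("c1", "c2"), 1)
    s <- sample(1:7000, 1)
    lines <- c(lines, sprintf("%s\t.\tgene\t%d\t%d\t.\t+\t.\tName=f%03d;class=%s",
                              sq, s, s + sample(10:800, 1), i,
                              sample(c("a", "b"), 1)))
  }
  r <- render_genome(coll_of(lines), default_config())
  expect_equal(nrow(r$drawn), 104)          # 2 backbones + 2 cen + 100 ranges
  expect_setequal(unique(r$drawn$glyph), c("backbone", "centromere", "range"))
  # containment: every box inside the image
  expect_true(all(r$drawn$x1 >= 1 & r$drawn$x2 <= r$frame$width &
                  r$drawn$y1 >= 1 & r$drawn$y2 <= r$frame$height))
  # empty feature set renders backbones only
  r0 <- render_genome(coll_of(lines[1:2]), default_config())
  expect_equal(nrow(r0$drawn), 2)
  expect_equal(nrow(r0$legend_rows), 1)     # backbone entry only
})

test_that("legend has one row per distinct glyph/class, first-appearance order", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tcentromere\t400\t600\t.\t.\t.\tName=cen",
         sprintf("c1\t.\tgene\t%d\t%d\t.\t+\t.\tName=s%d;class=synteny_Gm15",
                 c(10, 30, 700), c(220, 240, 910), 1:3))
  r <- render_genome(coll_of(g), default_config())
  expect_equal(nrow(r$legend_rows), 3)      # backbone, centromere, synteny
  expect_equal(r$legend_rows$class[1], "backbone")
  expect_equal(sum(r$legend_rows$class == "synteny_Gm15"), 1)
})

test_that("features without a Name get synthesized unique ids", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tgene\t100\t200\t.\t+\t.\tclass=a",
         "c1\t.\tgene\t100\t200\t.\t+\t.\tclass=a")
  r <- render_genome(coll_of(g), default_config())
  nm <- r$drawn$name[r$drawn$glyph == "range"]
  expect_length(unique(nm), 2)
  expect_match(nm, "^c1:100-200:")
})

test_that("rendering is deterministic: identical inputs, identical pixels", {
  spec <- genome_spec(n_chrom = 3, genes_per_chrom = 25, seed = 5)
  gen <- generate_genome(spec)
  lines <- c(gen$backbone_gff, gen$feature_gff)
  r1 <- render_genome(coll_of(lines), default_config())
  r2 <- render_genome(coll_of(lines), default_config())
  expect_identical(pixels(r1$genome), pixels(r2$genome))
  expect_identical(pixels(r1$legend), pixels(r2$legend))
  expect_identical(r1$drawn, r2$drawn)
})

test_that("invalid collections are refused with the offending records named", {
  g <- c("c1\t.\tchromosome\t1\t1000\t.\t.\t.\tName=c1",
         "c1\t.\tgene\t900\t1200\t.\t+\t.\tName=bad;class=a")
  expect_error(render_genome(coll_of(g), default_config()),
               "out-of-bounds")
})
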