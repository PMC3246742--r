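bb_df <- function(...) {
  rows <- list(...)
  data.frame(seqid = vapply(rows, `[[`, character(1), 1),
             start = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
             end = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
             label = vapply(rows, `[[`, character(1), 1),
             stringsAsFactors = FALSE)
}

# config with fixed drawable height: margins chosen so drawable = 500 px
cfg_drawable <- function(drawable = 500) {
  cfg <- default_config()
  cfg$general$margin <- 40
  # drawable = image_height - margin_top - margin_bottom;
  # margin_top = margin + label strip
  label_h <- unname(text_extent("X", cfg$general$font_size)[2]) + 4
  cfg$general$image_height <- drawable + 2 * cfg$general$margin + label_h
  cfg
}

test_that("shared scale fits the longest backbone to the drawable height", {
  cfg <- cfg_drawable(500)
  fr <- compute_frame(bb_df(list("c1", 1, 1000)), cfg)
  expect_equal(fr$scale, 500 / 999)
  expect_equal(fr$backbones$drawn_len, 500)

  fr2 <- compute_frame(bb_df(list("c1", 1, 1000), list("c2", 1, 500)), cfg)
  expect_equal(fr2$scale, 500 / 999)                     # shared scale
  expect_equal(fr2$backbones$drawn_len[1], 500)
  expect_equal(fr2$backbones$drawn_len[2], 499 * 500 / 999)
  # proportionality: drawn ratio == span ratio
  expect_equal(fr2$backbones$drawn_len[1] / fr2$backbones$drawn_len[2],
               999 / 499, tolerance = 1e-9)
})

test_that("a fixed scale is honored and overflow is fatal with a hint", {
  cfg <- cfg_drawable(500)
  cfg$general$pixels_per_unit <- 1
  fr <- compute_frame(bb_df(list("c1", 0, 100)), cfg)
  expect_equal(fr$backbones$drawn_len, 100)
  expect_equal(fr$scale, 1)

  err <- tryCatch(compute_frame(bb_df(list("c1", 1, 5000)), cfg),
                  error = conditionMessage)
  expect_match(err, "overflows")
  expect_match(err, "image_height >=")
})

test_that("backbones are laid out left-to-right, top-aligned, evenly spaced", {
  fr <- compute_frame(bb_df(list("a", 1, 100), list("b", 1, 80),
                            list("c", 1, 90)), default_config())
  x <- fr$backbones$x_center
  expect_true(all(diff(x) == default_config()$general$chrom_spacing))
  expect_equal(length(unique(fr$backbones$y_top)), 1)
  expect_true(all(fr$backbones$y_top + fr$backbones$drawn_len
                  <= fr$height - fr$margin_bottom + 1e-9))
})

test_that("to_pixel is the exact affine map with its anchors", {
  cfg <- cfg_drawable(500)
  fr <- compute_frame(bb_df(list("c1", 1, 1000)), cfg)
  y0 <- fr$backbones$y_top[1]
  expect_equal(to_pixel(fr, "c1", 1)[["y"]], y0)
  expect_equal(to_pixel(fr, "c1", 1000)[["y"]], y0 + 500)
  expect_equal(to_pixel(fr, "c1", 500.5)[["y"]], y0 + 250)
  expect_equal(to_pixel(fr, "c1", 500.5)[["x"]], fr$backbones$x_center[1])
  expect_error(to_pixel(fr, "nope", 5), "unknown backbone")
  expect_error(to_pixel(fr, "c1", 2000), "outside backbone")
})

test_that("affine correctness and monotonicity on randomized geometry", {
  set.seed(314)
  for (trial in 1:60) {
    span <- stats::runif(1, 10, 1e8)
    start <- stats::runif(1, 0, 100)
    cfg <- cfg_drawable(round(stats::runif(1, 100, 900)))
    fr <- compute_frame(bb_df(list("c1", start, start + span)), cfg)
    pos <- sort(stats::runif(5, start, start + span))
    y <- vapply(pos, function(p) to_pixel(fr, "c1", p)[["y"]], numeric(1))
    # independent closed form
    y_ref <- fr$backbones$y_top[1] + (pos - start) * fr$scale
    expect_true(all(abs(y - y_ref) < 1e-9))
    expect_true(all(diff(y) > 0))  # strictly increasing in pos
  }
})

test_that("ruler steps follow the 1-2-5 decade rule with 4-10 majors", {
  cfg <- default_config()
  fr <- compute_frame(bb_df(list("c1", 1, 50000001)), cfg)  # span 50M
  tk <- ruler_ticks(fr, cfg)
  mj <- tk$pos[tk$major]
  expect_equal(mj, seq(0, 5e7, by = 1e7))
  expect_equal(tk$label[tk$major], c("0", "10M", "20M", "30M", "40M", "50M"))

  fr <- compute_frame(bb_df(list("c1", 0, 100)), cfg)
  tk <- ruler_ticks(fr, cfg)
  expect_equal(tk$pos[tk$major], seq(0, 100, by = 20))

  fr <- compute_frame(bb_df(list("c1", 0, 1)), cfg)
  tk <- ruler_ticks(fr, cfg)
  expect_equal(tk$pos[tk$major], seq(0, 1, by = 0.2))

  # property: any span yields 4..10 majors, strictly increasing, in range
  set.seed(8)
  for (span in 10^stats::runif(30, -2, 9)) {
    fr <- compute_frame(bb_df(list("c1", 0, span)), cfg)
    tk <- ruler_ticks(fr, cfg)
    nmj <- sum(tk$major)
    expect_gte(nmj, 4); expect_lte(nmj, 10)
    expect_true(all(diff(tk$pos) > 0))
    expect_true(all(tk$pos >= 0 & tk$pos <= span))
  }
})

test_that("label collision: greedy downward nudge, clamping, dropping", {
  cfg <- default_config()
  fr <- compute_frame(bb_df(list("c1", 1, 1000)), cfg)
  h <- unname(text_extent("A", cfg$general$font_size)[2])
  gap <- cfg$general$label_gap

  # disjoint anchors stay at their preferred positions
  cand <- data.frame(text = c("aa", "bb"), x = c(10, 10), y = c(100, 300),
                     side = "c1/right", stringsAsFactors = FALSE)
  out <- place_labels(cand, fr, cfg)
  expect_equal(out$y1, c(100, 300))

  # identical anchors: second shifted down by exactly one height + gap
  cand$y <- c(100, 100)
  out <- place_labels(cand, fr, cfg)
  expect_equal(out$y1, c(100, 100 + h + gap))

  # bottom-edge anchor is clamped fully inside
  cand <- data.frame(text = "zz", x = 10, y = fr$height - 2,
                     side = "c1/right", stringsAsFactors = FALSE)
  out <- place_labels(cand, fr, cfg)
  expect_lte(out$y2, fr$height)
  expect_true(out$kept)

  # labels that cannot fit are dropped with a warning naming them
  cand <- data.frame(text = c("l1", "l2"), x = c(10, 10),
                     y = rep(fr$height - 1, 2), side = "c1/right",
                     stringsAsFactors = FALSE)
  expect_warning(out <- place_labels(cand, fr, cfg), "l2")
  expect_false(out$kept[2])
})

test_that("retained labels on one side never overlap (brute force)", {
  set.seed(55)
  cfg <- default_config()
  fr <- compute_frame(bb_df(list("c1", 1, 1000)), cfg)
  for (trial in 1:20) {
    n <- sample(2:15, 1)
    cand <- data.frame(text = sprintf("lab%02d", seq_len(n)),
                       x = rep(10, n),
                       y = stats::runif(n, 1, fr$height - 5),
                       side = sample(c("c1/left", "c1/right"), n,
                                     replace = TRUE),
                       stringsAsFactors = FALSE)
    out <- suppressWarnings(place_labels(cand, fr, cfg))
    kept <- which(out$kept)
    for (i in kept) for (j in kept) {
      if (i >= j || cand$side[i] != cand$side[j]) next
      overlap <- out$y1[i] < out$y2[j] && out$y1[j] < out$y2[i]
      expect_false(overlap)
    }
    expect_true(all(out$y1[kept] >= 0 & out$y2[kept] <= fr$height))
  }
})
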