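test_that("distance_histogram bins nearest distances per anchor", {
  anchors <- gr("chr1", c(1000, 5000, 9000), c(1000, 5000, 9000))
  self <- distance_histogram(anchors, anchors, 50, 10)
  zero_bin <- which(head(self$bin_edges, -1) <= 0 & self$bin_edges[-1] > 0)
  expect_equal(self$counts[zero_bin], 3)
  expect_equal(sum(self$counts), 3)

  far <- gr("chr1", 50000, 50000)
  none <- distance_histogram(anchors, far, 50, 10)
  expect_equal(sum(none$counts), 0)
  expect_equal(none$n_anchors, 3)
  expect_error(distance_histogram(anchors, far, 50, 0), "bin_width")
  expect_error(distance_histogram(anchors, far, 50, 7), "divide")
})

test_that("distance_histogram equals per-anchor brute-force nearest search", {
  set.seed(21)
  anchors <- gr("chr1", sort(sample(1000:99000, 20)), strand = sample(c("+", "-"), 20, replace = TRUE))
  sites <- gr("chr1", sort(sample(1000:99000, 40)))
  hw <- 5000
  bw <- 500
  h <- distance_histogram(anchors, sites, hw, bw)
  ac <- interval_centers(anchors)
  sc <- interval_centers(sites)
  neg <- as.character(GenomicRanges::strand(anchors)) == "-"
  brute <- numeric(2 * hw / bw)
  in_range <- 0
  for (i in seq_along(ac)) {
    d_or <- if (neg[i]) ac[i] - sc else sc - ac[i]
    best <- d_or[order(abs(d_or), d_or)][1] # tie -> the upstream side
    if (best >= -hw && best < hw) {
      bin <- floor((best + hw) / bw) + 1
      brute[bin] <- brute[bin] + 1
      in_range <- in_range + 1
    }
  }
  expect_equal(h$counts, brute, ignore_attr = TRUE)
  expect_equal(sum(h$counts), in_range) # nearest-only accounting
})

test_that("density_profile normalizes to the uniform expectation", {
  genome <- c(chr1 = 1e6)
  set.seed(31)
  sites <- gr("chr1", sample(1e6, 10000, replace = TRUE), genome = genome)
  anchors <- gr("chr1", sample(seq(2000, 998000), 100), genome = genome)
  prof <- density_profile(anchors, sites, half_window = 500, bin_width = 100)
  # null calibration: every bin within 3 SE of density 1
  se <- sqrt(prof$expected_per_bin) / prof$expected_per_bin
  expect_true(all(abs(prof$density - 1) < 3 * se))

  # planted offset: all mass lands in the [0, 10) bin with the hand
  # normalizer n_anchors * n_sites * bin / G
  a2 <- gr("chr1", c(1000, 2000), c(1000, 2000), genome = genome)
  s2 <- gr("chr1", c(1005, 2005), c(1005, 2005), genome = genome)
  p2 <- density_profile(a2, s2, half_window = 50, bin_width = 10)
  bin0 <- which(head(p2$bin_edges, -1) == 0)
  expect_equal(p2$raw_counts[bin0], 2)
  expect_equal(p2$expected_per_bin, 2 * 2 * 10 / 1e6)
  expect_equal(p2$density[bin0], 2 / (2 * 2 * 10 / 1e6))
  expect_equal(sum(p2$raw_counts), 2)

  # minus-strand anchors flip the axis
  a3 <- gr("chr1", c(1000, 2000), c(1000, 2000), strand = "-", genome = genome)
  p3 <- density_profile(a3, s2, half_window = 50, bin_width = 10)
  bin_neg <- which(head(p3$bin_edges, -1) == -10)
  expect_equal(p3$raw_counts[bin_neg], 2)

  expect_error(density_profile(a2, a2[0], 50, 10), "empty site set")
})

test_that("self density profile peaks at the zero bin", {
  set.seed(8)
  genome <- c(chr1 = 2e5)
  x <- gr("chr1", sample(1000:199000, 300), genome = genome)
  prof <- density_profile(x, x, half_window = 1000, bin_width = 100)
  bin0 <- which(head(prof$bin_edges, -1) <= 0 & prof$bin_edges[-1] > 0)
  expect_equal(which.max(prof$density), bin0)
})

test_that("fisher_test_2x2 matches enumeration and fisher.test", {
  sym <- fisher_test_2x2(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  t1 <- fisher_test_2x2(8, 2, 1, 9)
  expect_equal(t1$p_value, enumerate_fisher_p(8, 2, 1, 9), tolerance = 1e-12)
  expect_equal(t1$p_value,
               stats::fisher.test(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)
  expect_equal(t1$odds_ratio, (8 * 9) / (2 * 1))
  expect_true(t1$ci_low <= t1$odds_ratio && t1$odds_ratio <= t1$ci_high)

  # doubling the enriched cell strictly decreases p
  expect_lt(fisher_test_2x2(16, 2, 1, 9)$p_value, t1$p_value)

  # zero margin -> uninformative
  degen <- fisher_test_2x2(0, 5, 0, 7)
  expect_equal(degen$p_value, 1)
  expect_true(is.na(degen$odds_ratio))
})

test_that("fisher_overlap builds the foreground/background-restricted table", {
  genome <- c(chr1 = 10000)
  # 4 a-sites: two overlap b, one of each overlap class inside the background
  a <- gr("chr1", c(100, 2000, 5000, 7000), c(109, 2009, 5009, 7009),
          genome = genome)
  b <- gr("chr1", c(105, 5005), c(114, 5014), genome = genome)
  bg <- gr("chr1", 4000, 8000, genome = genome)
  fo <- fisher_overlap(a, b, bg, w = 0)
  expect_equal(unname(fo$table), c(2, 2, 1, 1))
  expect_error(fisher_overlap(a, b, bg[0]), "non-empty")
})

test_that("chip_peak_intersection equals triple-loop brute force", {
  sets <- list(x = random_intervals(100, toy_genome, seed = 41),
               y = random_intervals(100, toy_genome, seed = 42),
               z = random_intervals(100, toy_genome, seed = 43))
  w <- 50
  vc <- chip_peak_intersection(sets, w)
  ov <- function(g1, g2, w) {
    # brute-force per-interval co-occupancy
    vapply(seq_along(g1), function(i) {
      chr <- as.character(GenomicRanges::seqnames(g1))[i]
      s <- GenomicRanges::start(g1)[i] - w
      e <- GenomicRanges::end(g1)[i] + w
      any(as.character(GenomicRanges::seqnames(g2)) == chr &
            GenomicRanges::start(g2) <= e & GenomicRanges::end(g2) >= s)
    }, TRUE)
  }
  expect_equal(unname(vc$groups[["x&y"]]$counts["x"]),
               sum(ov(sets$x, sets$y, w)))
  expect_equal(unname(vc$groups[["x&y"]]$counts["y"]),
               sum(ov(sets$y, sets$x, w)))
  triple_x <- sum(ov(sets$x, sets$y, w) & ov(sets$x, sets$z, w))
  expect_equal(unname(vc$groups[["x&y&z"]]$counts["x"]), triple_x)
  # triple co-occupancy cannot exceed any pairwise count for the same parent
  expect_lte(unname(vc$groups[["x&y&z"]]$counts["x"]),
             min(unname(vc$groups[["x&y"]]$counts["x"]),
                 unname(vc$groups[["x&z"]]$counts["x"])))

  ident <- chip_peak_intersection(list(a = sets$x, b = sets$x), 0)
  expect_equal(unname(ident$groups[["a&b"]]$counts["a"]), 100)
  expect_equal(unname(ident$groups[["a&b"]]$percents["a"]), 100)
  far <- list(a = gr("chr1", 1, 10), b = gr("chr1", 5000, 5010))
  expect_equal(unname(chip_peak_intersection(far, 0)$groups[["a&b"]]$counts),
               c(0, 0))

  js <- jsonlite::fromJSON(venn_to_json(vc))
  expect_equal(js$groups$`x&y&z`$counts$x, triple_x)
})
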