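test_that("make_genome is seeded, GC-controlled and bit-reproducible", {
  cfg <- sim_config(seed = 99, genome_length = 2e4, n_chroms = 2)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(names(g1), c("chr1", "chr2"))

  gc_only <- make_genome(sim_config(seed = 1, genome_length = 5000,
                                    n_chroms = 1, gc = 1))
  expect_true(grepl("^[GC]+$", as.character(gc_only[[1]])))

  big <- make_genome(sim_config(seed = 3, genome_length = 1e6, n_chroms = 1,
                                gc = 0.41))
  af <- Biostrings::alphabetFrequency(big)[1, c("G", "C")]
  gc_hat <- sum(af) / 1e6
  se <- sqrt(0.41 * 0.59 / 1e6)
  expect_lt(abs(gc_hat - 0.41), 3 * se)
})

test_that("plant_motif_pairs writes recoverable consensus pairs", {
  cfg <- sim_config(seed = 5, n_pairs_phased = 30, n_pairs_unphased = 30,
                    genome_length = 4e5)
  none <- sim_config(seed = 5, n_pairs_phased = 0, n_pairs_unphased = 0,
                     genome_length = 4e5)
  g <- make_genome(cfg)
  expect_identical(as.character(plant_motif_pairs(g, none)$genome),
                   as.character(g))

  planted <- plant_motif_pairs(g, cfg)
  tr <- planted$truth
  expect_equal(nrow(tr), 60)
  # planted distance grid matches the request exactly at jitter 0
  expect_true(all(tr$d[tr$class == "phased"] %in% c(10, 20, 30, 40)))
  expect_true(all(tr$d[tr$class == "unphased"] %in% c(15, 25, 35, 45)))
  expect_true(all(abs(tr$b_center - tr$a_center) == tr$d))
  # both strands are exercised
  expect_equal(sort(unique(tr$a_strand)), c("+", "-")[order(c("+", "-"))])

  mm <- bundled_motifs()
  ha <- scan_sequence(planted$genome, mm[[1]], "high")
  hb <- scan_sequence(planted$genome, mm[[2]], "high")
  key_a <- paste(as.character(GenomicRanges::seqnames(ha)), interval_centers(ha))
  key_b <- paste(as.character(GenomicRanges::seqnames(hb)), interval_centers(hb))
  expect_true(all(paste(tr$chrom, tr$a_center) %in% key_a))
  expect_true(all(paste(tr$chrom, tr$b_center) %in% key_b))
})

test_that("summits are centered on planted sites with half-normal spread", {
  cfg <- sim_config(seed = 11, n_pairs_phased = 150, n_pairs_unphased = 150,
                    genome_length = 1e6, summit_jitter = 20)
  planted <- plant_motif_pairs(make_genome(cfg), cfg)
  genome <- genome_lengths(planted$genome)
  summits <- make_summits(planted$truth, cfg, genome)
  expect_length(summits, nrow(planted$truth))
  truth_sites <- gr(planted$truth$chrom, planted$truth$a_center,
                    genome = genome)
  d <- abs(nearest_center_distance(summits, truth_sites, oriented = FALSE))
  # mean |displacement| of Normal(0, sigma) is sigma * sqrt(2/pi)
  expected <- 20 * sqrt(2 / pi)
  se <- 20 * sqrt(1 - 2 / pi) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 4 * se) # rounding adds slight slack

  zero <- sim_config(seed = 11, n_pairs_phased = 50, n_pairs_unphased = 0,
                     genome_length = 2e5, summit_jitter = 0)
  pl0 <- plant_motif_pairs(make_genome(zero), zero)
  s0 <- make_summits(pl0$truth, zero, genome_lengths(pl0$genome))
  b0 <- gr(pl0$truth$chrom, pl0$truth$a_center,
           genome = genome_lengths(pl0$genome))
  prof <- density_profile(s0, b0, half_window = 100, bin_width = 10)
  bin0 <- which(head(prof$bin_edges, -1) == 0)
  expect_equal(which.max(prof$density), bin0)
})

test_that("make_gwas plants the requested in-region fractions", {
  genome <- c(chr1 = 250000, chr2 = 250000)
  map <- uniform_mappability(genome)
  regions <- gr(rep(names(genome), each = 10),
                rep(seq(5000, 230000, length.out = 10), 2),
                rep(seq(5000, 230000, length.out = 10) + 1999, 2),
                genome = genome)
  traits <- data.frame(name = c("full", "null", "half"),
                       n_snps = c(50L, 80L, 60L), f = c(1, 0, 0.5))
  cfg <- sim_config(seed = 31, traits = traits)
  gw <- make_gwas(cfg, regions, genome, map)
  expect_equal(as.vector(table(gw$catalog$trait)[c("full", "null", "half")]),
               c(50, 80, 60)) # counts per trait exact
  snps <- gr(gw$catalog$chrom, gw$catalog$pos, genome = genome)
  # note: gr() sorts, so recompute membership trait-wise
  for (t in traits$name) {
    sub <- gw$catalog[gw$catalog$trait == t, ]
    inside <- sum(GenomicRanges::countOverlaps(
      gr(sub$chrom, sub$pos, genome = genome), regions) > 0)
    f <- traits$f[traits$name == t]
    n <- traits$n_snps[traits$name == t]
    expect_gte(inside, round(f * n)) # planted plus chance background hits
  }
  full <- gw$catalog[gw$catalog$trait == "full", ]
  inside_full <- sum(GenomicRanges::countOverlaps(
    gr(full$chrom, full$pos, genome = genome), regions) > 0)
  expect_equal(inside_full, 50)
  res <- binomial_enrichment(regions, gw$catalog, map)
  expect_equal(res$trait[1], "full")
  expect_lt(res$p_value[1], 1e-50)

  expect_true(all(gw$ld$r2 >= 0 & gw$ld$r2 <= 1))
  expect_true(all(gw$ld$lead_rsid %in% gw$catalog$rsid))
})

test_that("make_expression plants block structure at the requested strength", {
  exact <- sim_config(seed = 41, expr = list(n_blocks = 3, rows_per_block = 5,
                                             n_samples = 12, within_r = 1,
                                             noise_sd = 0))
  m <- make_expression(exact)
  cl <- hierarchical_cluster(dissimilarity(correlation_matrix(m)$r), k = 3)
  expect_true(same_partition(attr(m, "block"), cl$labels))

  one <- make_expression(sim_config(seed = 42,
                                    expr = list(n_blocks = 1, rows_per_block = 6,
                                                n_samples = 10, within_r = 0.9,
                                                noise_sd = 1)))
  cl1 <- hierarchical_cluster(dissimilarity(correlation_matrix(one)$r), k = 1)
  expect_equal(unname(unique(cl1$labels)), 1L)

  cal <- sim_config(seed = 43, expr = list(n_blocks = 4, rows_per_block = 10,
                                           n_samples = 50, within_r = 0.8,
                                           noise_sd = 1))
  mc <- make_expression(cal)
  r <- correlation_matrix(mc)$r
  blocks <- attr(mc, "block")
  within <- abs(r[outer(blocks, blocks, "==") & upper.tri(r)])
  expect_lt(abs(mean(within) - 0.8), 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 17, genome_length = 1e5, n_pairs_phased = 10,
                    n_pairs_unphased = 10)
  p1 <- plant_motif_pairs(make_genome(cfg), cfg)
  p2 <- plant_motif_pairs(make_genome(cfg), cfg)
  expect_identical(p1$truth, p2$truth)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  e1 <- make_expression(cfg)
  e2 <- make_expression(cfg)
  expect_identical(e1, e2)
})
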