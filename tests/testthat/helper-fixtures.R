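# In-code fixtures shared across the suite. All coordinates in these
# helpers are 1-based closed (the GRanges convention); BED text written by
# helpers uses 0-based half-open as usual.

gr <- function(chrom, start, end = start, strand = "*", genome = NULL, ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = rep_len(strand, length(chrom)), ...)
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  sort(gr)
}

toy_genome <- c(chr1 = 100000, chr2 = 100000)

write_bed_lines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# a deterministic 6-bp test matrix with a strong consensus ACGTCA
toy_motif <- function(pseudocount = 0.8) {
  counts <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("A", "C", "G", "T", "C", "A")
  for (i in seq_along(consensus)) counts[consensus[i], i] <- 17
  motif_matrix(counts, id = "TOY0001.1", name = "toy", pseudocount = pseudocount)
}

random_intervals <- function(n, genome, max_width = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n, 1, genome[chrom] - max_width))
  width <- sample(max_width, n, replace = TRUE)
  gr(chrom, start, start + width - 1, genome = genome)
}

# brute-force per-base boolean coverage mask of a chromosome
coverage_mask <- function(grx, chrom, len) {
  mask <- logical(len)
  sel <- as.character(GenomicRanges::seqnames(grx)) == chrom
  for (i in which(sel)) {
    mask[GenomicRanges::start(grx)[i]:GenomicRanges::end(grx)[i]] <- TRUE
  }
  mask
}

# independent all-window PWM scorer: explicit per-base loops on both strands
brute_force_scan <- function(seq_chr, m, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(toupper(seq_chr), "")[[1]]
  L <- ncol(m$counts)
  hits <- list()
  for (start in seq_len(length(bases) - L + 1)) {
    win <- bases[start:(start + L - 1)]
    if (any(!win %in% names(comp))) next
    fwd <- 0
    rev_ <- 0
    for (i in seq_len(L)) {
      fwd <- fwd + m$log_odds[win[i], i]
      rev_ <- rev_ + m$log_odds[comp[[win[L + 1 - i]]], i]
    }
    if (fwd >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = start, strand = "+",
                                             score = fwd)
    if (rev_ >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = start, strand = "-",
                                             score = rev_)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, hits)
}

# exhaustive two-sided Fisher p via explicit binomial-coefficient products
enumerate_fisher_p <- function(a, b, c_, d_) {
  m1 <- a + b
  m2 <- c_ + d_
  k <- a + c_
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  probs <- exp(logp)
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# map cluster labels onto truth blocks; TRUE iff the partition is identical
# up to relabeling
same_partition <- function(truth, labels) {
  tab <- table(truth, labels)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
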