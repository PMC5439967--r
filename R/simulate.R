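# Seeded synthetic-data generator. Plants every structure the pipeline is
# designed to detect -- motif pairs at controlled 10 bp-grid spacings,
# ChIP-like summits jittered around planted sites, trait SNP sets with a
# planted in-region fraction, mappability masks, block-correlated
# expression matrices -- and emits a truth table per generator as the
# contract between simulation and tests.

#' Simulation configuration
#'
#' Bundles the generator parameters with their defaults: a 1 Mb two-
#' chromosome genome at human-like GC, 200 phased + 200 unphased planted
#' motif pairs (10 bp-grid spacings), summit jitter 25 bp, ten traits of
#' 100 SNPs with one planted enriched trait, a fully mappable genome, and a
#' 4-block expression matrix with within-block correlation 0.9.
#'
#' @param seed Integer seed; every generator derives its RNG stream from it.
#' @param genome_length Total genome length in bp (split over chromosomes).
#' @param n_chroms Number of chromosomes.
#' @param gc GC fraction of the background sequence.
#' @param n_pairs_phased,n_pairs_unphased Planted pair counts per class.
#' @param pair_jitter Uniform jitter (in bp, `0..2`) added to the planted
#'   center distances.
#' @param min_pair_gap Minimum gap between planted pair spans in bp.
#' @param summit_jitter SD (bp) of the Gaussian summit displacement.
#' @param n_decoy_summits Extra uniformly placed decoy summits.
#' @param n_tss Number of oriented synthetic TSS.
#' @param traits Data.frame with columns `name`, `n_snps`, `f` (planted
#'   fraction of SNPs forced into the target regions). Default: trait
#'   `planted` with `f = 0.3` plus nine null traits, 100 SNPs each.
#' @param mappable_fraction_sim Fraction of the genome kept mappable (a
#'   striped mask is generated when < 1).
#' @param expr List: `n_blocks`, `rows_per_block`, `n_samples`, `within_r`,
#'   `noise_sd`.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 1e6, n_chroms = 2L,
                       gc = 0.41, n_pairs_phased = 200L,
                       n_pairs_unphased = 200L, pair_jitter = 0L,
                       min_pair_gap = 150L, summit_jitter = 25,
                       n_decoy_summits = 0L, n_tss = 200L,
                       traits = NULL,
                       mappable_fraction_sim = 1,
                       expr = list(n_blocks = 4L, rows_per_block = 10L,
                                   n_samples = 20L, within_r = 0.9,
                                   noise_sd = 1)) {
  if (is.null(traits)) {
    traits <- data.frame(
      name = c("planted", paste0("null_", sprintf("%02d", 1:9))),
      n_snps = 100L, f = c(0.3, rep(0, 9)))
  }
  stopifnot(is_count(seed), genome_length > 0, n_chroms >= 1,
            gc >= 0, gc <= 1, pair_jitter >= 0, pair_jitter <= 2,
            all(traits$f >= 0 & traits$f <= 1), all(traits$n_snps >= 0),
            mappable_fraction_sim > 0, mappable_fraction_sim <= 1)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_chroms = as.integer(n_chroms), gc = gc,
                 n_pairs_phased = as.integer(n_pairs_phased),
                 n_pairs_unphased = as.integer(n_pairs_unphased),
                 pair_jitter = as.integer(pair_jitter),
                 min_pair_gap = as.integer(min_pair_gap),
                 summit_jitter = summit_jitter,
                 n_decoy_summits = as.integer(n_decoy_summits),
                 n_tss = as.integer(n_tss), traits = traits,
                 mappable_fraction_sim = mappable_fraction_sim,
                 expr = expr),
            class = "SimConfig")
}

# distinct, fixed sub-seeds per generator so each is reproducible on its own
sim_seed <- function(cfg, k) set.seed(cfg$seed * 13L + k)

#' Bundled motif matrices
#'
#' Loads the two motifs shipped with the package: the classic 6-bp
#' dioxin-response-element (AHR-ARNT heterodimer) count matrix, and a
#' synthetic 12-bp E-box (CAGCTG-core) matrix standing in for the
#' TCF12/TCF21 bHLH motif, constructed for simulation since the curated
#' bHLH profile is not redistributable here. The E-box matrix is labelled
#' synthetic in the bundled file.
#'
#' @return Named list of two `MotifMatrix` objects (`MA0006.1`, `SYNT0001.1`).
#' @export
bundled_motifs <- function() {
  path <- system.file("extdata", "motifs_synthetic.jaspar",
                      package = "motifcoloc")
  read_jaspar(path)
}

#' Generate an iid background genome
#'
#' @param cfg A `SimConfig`.
#' @return A `DNAStringSet` of `n_chroms` chromosomes (`chr1`, `chr2`, ...)
#'   with iid bases at the configured GC fraction; deterministic under the
#'   seed.
#' @export
make_genome <- function(cfg) {
  sim_seed(cfg, 1L)
  len <- floor(cfg$genome_length / cfg$n_chroms)
  p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
         T = (1 - cfg$gc) / 2)
  seqs <- vapply(seq_len(cfg$n_chroms), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = ""),
    "")
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(cfg$n_chroms))))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# start such that the planted site's integer center equals `center`
start_for_center <- function(center, L) center - floor((L - 1) / 2)

#' Plant motif pairs at controlled spacings into a genome
#'
#' Writes the consensus of motif `a` at collision-free random positions and
#' the consensus of motif `b` at a center distance drawn from the phased
#' grid \{10, 20, 30, 40\} bp or the unphased grid \{15, 25, 35, 45\} bp
#' (plus optional jitter), on a random side. The unphased grid starts at
#' 15 bp because a 5 bp center separation would force the two consensus
#' sequences to overlap physically given the motif widths. Site strands
#' alternate deterministically to exercise strand handling. Consensus
#' planting guarantees recovery by high-stringency scanning.
#'
#' @param seqs Genome `DNAStringSet` (from [make_genome()]).
#' @param cfg A `SimConfig`.
#' @param motif_a,motif_b `MotifMatrix` objects; default [bundled_motifs()].
#' @return List: `genome` (mutated `DNAStringSet`) and `truth` (data.frame
#'   with chrom, centers, starts, `d`, `class`, strands).
#' @export
plant_motif_pairs <- function(seqs, cfg, motif_a = NULL, motif_b = NULL) {
  if (is.null(motif_a) || is.null(motif_b)) {
    mm <- bundled_motifs()
    motif_a <- motif_a %||% mm[[1L]]
    motif_b <- motif_b %||% mm[[2L]]
  }
  sim_seed(cfg, 2L)
  n_pairs <- cfg$n_pairs_phased + cfg$n_pairs_unphased
  if (n_pairs == 0L)
    return(list(genome = seqs, truth = empty_truth()))
  La <- motif_length(motif_a)
  Lb <- motif_length(motif_b)
  cons_a <- consensus_string(motif_a)
  cons_b <- consensus_string(motif_b)
  lens <- genome_lengths(seqs)
  if ((La + Lb + 45 + cfg$min_pair_gap) * n_pairs > sum(lens))
    stop_arg("genome too small for the requested number of pairs")
  classes <- c(rep("phased", cfg$n_pairs_phased),
               rep("unphased", cfg$n_pairs_unphased))
  classes <- sample(classes) # interleave the two classes along the genome
  d0 <- ifelse(classes == "phased",
               sample(c(10, 20, 30, 40), n_pairs, replace = TRUE),
               sample(c(15, 25, 35, 45), n_pairs, replace = TRUE))
  jit <- if (cfg$pair_jitter > 0)
    sample(seq(-cfg$pair_jitter, cfg$pair_jitter), n_pairs, replace = TRUE)
  else rep(0L, n_pairs)
  d <- d0 + jit
  side <- sample(c(-1L, 1L), n_pairs, replace = TRUE)
  half_span <- 45 + La + Lb # conservative span bound for collision checks
  chrom <- sample(names(lens), n_pairs, replace = TRUE,
                  prob = lens / sum(lens))
  occupied <- lapply(lens, function(...) numeric(0))
  a_center <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    ok <- FALSE
    for (try in 1:100) {
      cand <- sample(seq(half_span + 1, lens[[chrom[i]]] - half_span), 1L)
      if (all(abs(occupied[[chrom[i]]] - cand) >
              (2 * half_span + cfg$min_pair_gap))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_arg("placement collision: genome too crowded for pairs")
    occupied[[chrom[i]]] <- c(occupied[[chrom[i]]], cand)
    a_center[i] <- cand
  }
  b_center <- a_center + side * d
  a_strand <- rep_len(c("+", "-"), n_pairs)
  b_strand <- rep_len(c("+", "-", "-", "+"), n_pairs)
  chars <- as.character(seqs)
  a_start <- start_for_center(a_center, La)
  b_start <- start_for_center(b_center, Lb)
  for (i in seq_len(n_pairs)) {
    sa <- if (a_strand[i] == "+") cons_a else revcomp_chr(cons_a)
    sb <- if (b_strand[i] == "+") cons_b else revcomp_chr(cons_b)
    substr(chars[[chrom[i]]], a_start[i], a_start[i] + La - 1L) <- sa
    substr(chars[[chrom[i]]], b_start[i], b_start[i] + Lb - 1L) <- sb
  }
  truth <- data.frame(chrom = chrom, a_center = a_center,
                      b_center = b_center, a_start = a_start,
                      b_start = b_start, d = abs(d), class = classes,
                      a_strand = a_strand, b_strand = b_strand,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$a_center), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = Biostrings::DNAStringSet(chars), truth = truth)
}

empty_truth <- function() {
  data.frame(chrom = character(0), a_center = integer(0),
             b_center = integer(0), a_start = integer(0),
             b_start = integer(0), d = integer(0), class = character(0),
             a_strand = character(0), b_strand = character(0))
}

#' Jittered summits around planted sites
#'
#' A width-1 summit at each planted `a`-site center displaced by
#' `Normal(0, summit_jitter)` (rounded, clipped to the chromosome), plus
#' optional uniform decoy summits, emulating ChIP-seq summit calls around
#' true binding sites.
#'
#' @param truth Truth table from [plant_motif_pairs()].
#' @param cfg A `SimConfig`.
#' @param genome Named chromosome lengths.
#' @return A sorted `GRanges` of width-1 summits.
#' @export
make_summits <- function(truth, cfg, genome) {
  sim_seed(cfg, 3L)
  pos <- chrom <- NULL
  if (nrow(truth) > 0L) {
    jit <- round(rnorm(nrow(truth), 0, cfg$summit_jitter))
    pos <- pmin(pmax(truth$a_center + jit, 1), genome[truth$chrom])
    chrom <- truth$chrom
  }
  if (cfg$n_decoy_summits > 0L) {
    dchr <- sample(names(genome), cfg$n_decoy_summits, replace = TRUE,
                   prob = genome / sum(genome))
    dpos <- floor(runif(cfg$n_decoy_summits, 1, genome[dchr] + 1))
    chrom <- c(chrom, dchr)
    pos <- c(pos, dpos)
  }
  new_intervals(chrom, pos, pos, genome = genome)
}

#' Oriented synthetic TSS set
#'
#' Uniformly placed width-1 TSS with random strand and gene names, for
#' exercising oriented metaprofiles and nearest-gene assignment.
#'
#' @param cfg A `SimConfig`.
#' @param genome Named chromosome lengths.
#' @return A sorted `GRanges` with `name` metadata.
#' @export
make_tss <- function(cfg, genome) {
  sim_seed(cfg, 4L)
  n <- cfg$n_tss
  chrom <- sample(names(genome), n, replace = TRUE, prob = genome / sum(genome))
  pos <- floor(runif(n, 1, genome[chrom] + 1))
  gr <- new_intervals(chrom, pos, pos,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      genome = genome)
  S4Vectors::mcols(gr)$name <- sprintf("gene%04d", seq_len(n))
  gr
}

# uniform positions over an interval union, by cumulative-width inversion
sample_positions <- function(gr, n) {
  if (length(gr) == 0L || n == 0L)
    return(data.frame(chrom = character(0), pos = numeric(0)))
  w <- GenomicRanges::width(gr)
  total <- sum(as.numeric(w))
  off <- floor(runif(n, 0, total)) # 0-based offset into the union
  cum <- cumsum(as.numeric(w))
  idx <- findInterval(off, c(0, cum), rightmost.closed = FALSE)
  within <- off - c(0, cum)[idx]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[idx],
             pos = GenomicRanges::start(gr)[idx] + within)
}

#' Striped mappability mask
#'
#' Alternating mappable/unmappable stripes covering approximately the
#' configured mappable fraction, emulating a uniqueness mask.
#'
#' @param cfg A `SimConfig`.
#' @param genome Named chromosome lengths.
#' @param stripe Stripe period in bp (default 1000).
#' @return A `MappabilityTrack`.
#' @export
make_mappability <- function(cfg, genome, stripe = 1000) {
  frac <- cfg$mappable_fraction_sim
  if (frac >= 1) return(uniform_mappability(genome))
  keep <- max(1, round(stripe * frac))
  chroms <- starts <- ends <- NULL
  for (chr in names(genome)) {
    s <- seq(1, genome[[chr]], by = stripe)
    e <- pmin(s + keep - 1, genome[[chr]])
    chroms <- c(chroms, rep(chr, length(s)))
    starts <- c(starts, s)
    ends <- c(ends, e)
  }
  mappability_track(new_intervals(chroms, starts, ends, genome = genome))
}

#' Trait SNP sets with a planted in-region fraction, plus an LD table
#'
#' Per trait, `round(f * n_snps)` SNPs are placed uniformly inside the
#' intersection of the target regions with the mappable genome, and the
#' remainder uniformly over the whole mappable genome; `f = 0` gives a pure
#' null trait. Each lead SNP receives 0-3 linked synthetic SNPs within
#' 50 kb with r-squared drawn from a mixture (60 percent Uniform(0.8, 1),
#' 40 percent Uniform(0, 0.8)).
#'
#' @param cfg A `SimConfig`.
#' @param regions Target regions (`GRanges`) for the planted fractions.
#' @param map A `MappabilityTrack` (default: all-mappable from `genome`).
#' @param genome Named chromosome lengths.
#' @return List: `catalog` (a `GwasCatalog`) and `ld` (LD data.frame).
#' @export
make_gwas <- function(cfg, regions, genome, map = NULL) {
  sim_seed(cfg, 5L)
  if (is.null(map)) map <- uniform_mappability(genome)
  region_universe <- GenomicRanges::intersect(merge_intervals(regions),
                                              map$mappable,
                                              ignore.strand = TRUE)
  rows <- list()
  counter <- 0L
  for (t in seq_len(nrow(cfg$traits))) {
    tname <- cfg$traits$name[t]
    n <- cfg$traits$n_snps[t]
    f <- cfg$traits$f[t]
    k <- round(f * n)
    if (k > 0L && length(region_universe) == 0L)
      stop_arg("planted fraction > 0 but regions have no mappable bases")
    planted <- sample_positions(region_universe, k)
    background <- sample_positions(map$mappable, n - k)
    df <- rbind(planted, background)
    if (nrow(df) == 0L) next
    rows[[tname]] <- data.frame(
      trait = tname, chrom = df$chrom, pos = df$pos,
      rsid = sprintf("rs%07d", counter + seq_len(nrow(df))))
    counter <- counter + nrow(df)
  }
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  class(catalog) <- c("GwasCatalog", "data.frame")
  n_link <- sample(0:3, nrow(catalog), replace = TRUE)
  lead <- rep(seq_len(nrow(catalog)), n_link)
  m <- length(lead)
  ld <- data.frame(lead_rsid = catalog$rsid[lead],
                   chrom = catalog$chrom[lead],
                   pos = pmin(pmax(catalog$pos[lead] +
                                     sample(c(-1, 1), m, replace = TRUE) *
                                     floor(runif(m, 1, 5e4)), 1),
                              genome[catalog$chrom[lead]]),
                   rsid = sprintf("rs%07d", counter + seq_len(m)),
                   r2 = ifelse(runif(m) < 0.6, runif(m, 0.8, 1),
                               runif(m, 0, 0.8)))
  rownames(ld) <- NULL
  list(catalog = catalog, ld = ld)
}

#' Block-correlated expression matrix
#'
#' Rows load on one of `n_blocks` latent sample factors with alternating
#' sign (so within-block correlations exercise the absolute value in
#' `D = 1 - |r|`), plus independent Gaussian noise:
#' `row = s * (sqrt(w) * z_block + sqrt(1 - w) * noise_sd * e)` with
#' `w = within_r`. With `noise_sd = 1` the expected within-block `|r|`
#' equals `within_r`; with `noise_sd = 0` it is exactly 1.
#'
#' @param cfg A `SimConfig`.
#' @return Numeric matrix with a `block` attribute (integer truth labels).
#' @export
make_expression <- function(cfg) {
  sim_seed(cfg, 6L)
  e <- cfg$expr
  nr <- e$n_blocks * e$rows_per_block
  z <- matrix(rnorm(e$n_blocks * e$n_samples), e$n_blocks, e$n_samples)
  block <- rep(seq_len(e$n_blocks), each = e$rows_per_block)
  sign_ <- rep_len(c(1, -1), nr)
  w <- e$within_r
  noise <- matrix(rnorm(nr * e$n_samples), nr, e$n_samples)
  m <- sign_ * (sqrt(w) * z[block, , drop = FALSE] +
                  sqrt(1 - w) * e$noise_sd * noise)
  dimnames(m) <- list(sprintf("P%03d", seq_len(nr)),
                      sprintf("S%02d", seq_len(e$n_samples)))
  attr(m, "block") <- block
  m
}
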