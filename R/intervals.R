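# Interval data model: GRanges is the universal coordinate currency for
# sites, summits, peaks, SNPs and mappability masks. All plain-text I/O uses
# the BED convention (0-based half-open); internally coordinates follow the
# GenomicRanges convention (1-based closed). The two agree on every derived
# quantity used here (centers, distances, covered lengths).

#' Read a chromosome-length table
#'
#' Reads a two-column TSV (`chrom`, `length` in bp, no header) into a named
#' integer vector suitable for the `genome` argument of [read_bed()] and the
#' simulation functions.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  if (!file.exists(path)) stop_arg("genome table not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (nrow(df) == 0L) stop_arg("empty genome table: ", path)
  if (anyNA(df$length) || any(df$length <= 0))
    stop_arg("genome table has non-positive or non-numeric lengths: ", path)
  setNames(df$length, df$chrom)
}

#' Write a chromosome-length table
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_genome_table <- function(genome, path) {
  write.table(data.frame(names(genome), unname(genome)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(unname(genome)))
}

# deterministic (chrom, start, end) order, chromosomes lexicographic
sort_intervals <- function(gr) {
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr))]
}

new_intervals <- function(chrom, start1, end1, strand = "*", genome = NULL,
                          ...) {
  seqlv <- unique(c(if (!is.null(genome)) names(genome), chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = seqlv),
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = rep_len(strand, length(chrom)), ...)
  if (!is.null(genome))
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)[GenomeInfoDb::seqlevels(gr)]
  sort_intervals(gr)
}

#' Read a BED file into a GRanges
#'
#' Parses 3- to 6-column BED (0-based half-open) into a sorted `GRanges`
#' (1-based closed, the GenomicRanges convention). Strand defaults to `*`
#' when absent or `.`; the name and score columns are kept as metadata
#' columns when present.
#'
#' @param path Path to the BED file.
#' @param genome Optional named vector of chromosome lengths; when supplied,
#'   the result carries `seqlengths` and out-of-bounds intervals are an error.
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_arg("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_intervals(character(0), integer(0), integer(0),
                         genome = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 6L)
  if (length(bad))
    stop_arg("BED parse error at line ", bad[1L], ": expected 3-6 columns, got ",
             nf[bad[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s0) | is.na(e0) | s0 != floor(s0) | e0 != floor(e0))
  if (length(bad))
    stop_arg("BED parse error at line ", bad[1L], ": non-integer coordinates")
  bad <- which(s0 >= e0 | s0 < 0)
  if (length(bad))
    stop_arg("BED parse error at line ", bad[1L], ": start >= end or negative")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  name[name == "."] <- NA_character_
  score_chr <- ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA, score_chr)))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- new_intervals(chrom, s0 + 1, e0, strand = strand, genome = genome,
                      name = name, score = score)
  if (!is.null(genome)) {
    sl <- GenomeInfoDb::seqlengths(gr)[as.character(GenomicRanges::seqnames(gr))]
    if (any(GenomicRanges::end(gr) > sl, na.rm = TRUE))
      stop_arg("BED interval beyond chromosome end in ", path)
  }
  gr
}

#' Write a GRanges to BED
#'
#' Emits BED6 when strand or metadata are informative, BED3 otherwise.
#' Coordinates are converted back to 0-based half-open; [read_bed()] of the
#' output reproduces the input (bit-exact on columns 1-3 for sorted input).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param bed3 Force plain 3-column output.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, bed3 = FALSE) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE)
  e0 <- format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE)
  if (bed3) {
    df <- data.frame(chrom, s0, e0)
  } else {
    mc <- S4Vectors::mcols(gr)
    name <- if ("name" %in% names(mc)) as.character(mc$name) else NA_character_
    name[is.na(name)] <- "."
    score <- if ("score" %in% names(mc)) mc$score else NA_real_
    score_chr <- ifelse(is.na(score), ".", formatC(score, format = "f", digits = 2))
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    df <- data.frame(chrom, s0, e0, name, score_chr, strand)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Extend intervals symmetrically
#'
#' Grows every interval by `w` bp on both sides (the window extension used
#' before overlap and enrichment computations), clipping at chromosome
#' bounds when lengths are known. Overlapping results are deliberately not
#' merged; see [merge_intervals()].
#'
#' @param gr A `GRanges`.
#' @param w Extension in bp (>= 0).
#' @return The extended `GRanges`.
#' @export
extend_regions <- function(gr, w) {
  if (!is_count(w)) stop_arg("w must be a single non-negative integer")
  if (w == 0 || length(gr) == 0L) return(gr)
  s <- pmax(GenomicRanges::start(gr) - w, 1)
  sl <- GenomeInfoDb::seqlengths(gr)[as.character(GenomicRanges::seqnames(gr))]
  e <- GenomicRanges::end(gr) + w
  e <- ifelse(is.na(sl), e, pmin(e, sl))
  GenomicRanges::ranges(gr) <- IRanges::IRanges(start = s, end = e)
  sort_intervals(gr)
}

#' Merge overlapping and bookended intervals
#'
#' @param gr A `GRanges`.
#' @return Strand-agnostic reduced `GRanges`; total covered length invariant.
#' @export
merge_intervals <- function(gr) {
  sort_intervals(GenomicRanges::reduce(gr, ignore.strand = TRUE))
}

#' Total covered length of an interval set
#'
#' @param gr A `GRanges` (merged internally first).
#' @return Covered length in bp.
#' @export
covered_length <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

#' Integer centers of intervals
#'
#' The center of an interval is the base `floor((start + end) / 2)`
#' (1-based), i.e. the lower-median base; width-1 intervals are their own
#' center.
#'
#' @param gr A `GRanges`.
#' @return Numeric vector of center positions.
#' @export
interval_centers <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}

#' Count query intervals overlapping a subject set within a window
#'
#' Counts intervals of `a` whose `w`-extension intersects at least one
#' interval of `b`; each `a` interval counts at most once.
#'
#' @param a,b `GRanges` on a shared genome.
#' @param w Window extension in bp applied to `a` (default 0 = direct overlap).
#' @return Integer count.
#' @export
overlap_count <- function(a, b, w = 0) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  sum(GenomicRanges::countOverlaps(extend_regions(a, w), b,
                                   ignore.strand = TRUE) > 0L)
}

#' Signed oriented distance to the nearest interval center
#'
#' For each anchor, the signed center-to-center distance to the nearest
#' interval of `b` (`center(b) - center(anchor)`); when the anchor is on the
#' minus strand the sign is flipped so that positive means downstream of the
#' anchor. Equidistant left/right neighbours break to the negative
#' (upstream) side. Anchors on chromosomes absent from `b` get `NA`.
#'
#' @param anchors,b `GRanges` on a shared genome.
#' @param oriented Flip sign for minus-strand anchors (default `TRUE`).
#' @return Numeric vector, one signed distance (or `NA`) per anchor.
#' @export
nearest_center_distance <- function(anchors, b, oriented = TRUE) {
  out <- rep(NA_real_, length(anchors))
  if (length(anchors) == 0L || length(b) == 0L) return(out)
  ac <- interval_centers(anchors)
  achr <- as.character(GenomicRanges::seqnames(anchors))
  bc <- interval_centers(b)
  bchr <- as.character(GenomicRanges::seqnames(b))
  neg <- oriented & as.character(GenomicRanges::strand(anchors)) == "-"
  for (chr in unique(achr)) {
    ai <- which(achr == chr)
    sc <- sort(bc[bchr == chr])
    if (length(sc) == 0L) next
    x <- ac[ai]
    i <- findInterval(x, sc)
    d_left <- ifelse(i >= 1L, sc[pmax(i, 1L)] - x, -Inf)
    d_right <- ifelse(i < length(sc), sc[pmin(i + 1L, length(sc))] - x, Inf)
    d <- ifelse(abs(d_left) <= abs(d_right), d_left, d_right)
    # orient, then re-apply the upstream tie-break on the oriented distance
    d_o <- ifelse(neg[ai], -d, d)
    tie <- abs(d_left) == abs(d_right) & is.finite(d_left) & is.finite(d_right)
    d_o[tie] <- -abs(d_left[tie])
    out[ai] <- d_o
  }
  out
}

#' Restrict intervals to those whose centers fall in a region union
#'
#' @param gr A `GRanges` to filter.
#' @param regions Region set; membership is tested for the interval center.
#' @return The filtered `GRanges`.
#' @export
filter_by_center <- function(gr, regions) {
  if (length(gr) == 0L) return(gr)
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                    IRanges::IRanges(interval_centers(gr), width = 1))
  keep <- GenomicRanges::countOverlaps(centers, regions, ignore.strand = TRUE) > 0L
  gr[keep]
}

#' Read a (possibly line-wrapped, multi-record) FASTA genome
#'
#' @param path FASTA path.
#' @return A `DNAStringSet`, upper-cased; alphabet restricted to A,C,G,T,N.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_arg("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  af <- Biostrings::alphabetFrequency(seqs)
  extra <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0)) stop_arg("FASTA contains letters outside {A,C,G,T,N}: ", path)
  # keep only the identifier token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Chromosome lengths of a genome sequence
#'
#' @param seqs A `DNAStringSet` as returned by [read_genome_fasta()].
#' @return Named numeric vector of lengths.
#' @export
genome_lengths <- function(seqs) {
  setNames(as.numeric(Biostrings::width(seqs)), names(seqs))
}
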