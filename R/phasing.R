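# Rotational phasing of co-localized site pairs. Two sites separated by a
# multiple of the ~10 bp DNA helical pitch sit on the same face of the double
# helix ("phased", capable of direct protein-protein contact); separations of
# 5 bp plus a multiple of 10 put them on opposite faces ("unphased").

PHASE_LEVELS <- c("phased", "unphased", "unclassified")

#' Classify a center-to-center distance by rotational phase
#'
#' With `r = d mod 10`: phased when `min(r, 10 - r) <= tolerance` (distance
#' near a multiple of 10 bp, including `d = 0`), unphased when
#' `|r - 5| <= tolerance` (near 5, 15, 25, ... bp), otherwise unclassified.
#' The classification is periodic in 10 bp. Tolerances above 2 bp would let
#' the two classes overlap and are rejected.
#'
#' @param d Non-negative distances in bp (vectorized).
#' @param tolerance Allowed deviation in bp, in `[0, 2]` (default 1; 0
#'   reproduces the literal multiples-only rule).
#' @return Factor with levels `phased`, `unphased`, `unclassified`.
#' @export
classify_pair <- function(d, tolerance = 1) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || is.na(tolerance) ||
      tolerance < 0 || tolerance > 2)
    stop_arg("tolerance must be in [0, 2]")
  if (any(d < 0, na.rm = TRUE)) stop_arg("distances must be non-negative")
  r <- d %% 10
  cls <- ifelse(pmin(r, 10 - r) <= tolerance, "phased",
                ifelse(abs(r - 5) <= tolerance, "unphased", "unclassified"))
  factor(cls, levels = PHASE_LEVELS)
}

#' Pair co-localized sites and partition them by rotational phase
#'
#' Each `a` site is paired with its nearest `b` site (center-to-center,
#' unsigned) within `max_d`; an `a` site pairs at most once while `b` sites
#' may pair multiply. Pair regions (the union span of the two sites) are
#' emitted into the `phased` or `unphased` set according to
#' [classify_pair()]; unclassified pairs are kept in the pair table only.
#'
#' @param a_sites,b_sites Site sets (`GRanges`) on a shared genome.
#' @param max_d Maximum pairing distance in bp (default 45, the largest
#'   informative spacing of the 10 bp phase grid).
#' @param tolerance Passed to [classify_pair()].
#' @return A list: `pairs` (data.frame with chrom, site coordinates,
#'   centers, `d`, `phase_class`), `phased` and `unphased` (`GRanges` of
#'   pair-span regions).
#' @export
partition_pairs <- function(a_sites, b_sites, max_d = 45, tolerance = 1) {
  if (!is_count(max_d)) stop_arg("max_d must be a non-negative integer")
  d_signed <- nearest_center_distance(a_sites, b_sites, oriented = FALSE)
  keep <- which(!is.na(d_signed) & abs(d_signed) <= max_d)
  genome <- GenomeInfoDb::seqlengths(a_sites)
  genome <- if (all(is.na(genome))) NULL else genome[!is.na(genome)]
  empty <- new_intervals(character(0), integer(0), integer(0), genome = genome)
  if (length(keep) == 0L) {
    return(list(pairs = data.frame(chrom = character(0), a_start = integer(0),
                                   a_end = integer(0), b_start = integer(0),
                                   b_end = integer(0), a_center = integer(0),
                                   b_center = integer(0), d = integer(0),
                                   phase_class = factor(character(0),
                                                        levels = PHASE_LEVELS)),
                phased = empty, unphased = empty))
  }
  a <- a_sites[keep]
  ac <- interval_centers(a)
  # recover the partner b site: the nearest center at the recorded distance
  bc_target <- ac + d_signed[keep]
  achr <- as.character(GenomicRanges::seqnames(a))
  b_centers <- interval_centers(b_sites)
  bchr <- as.character(GenomicRanges::seqnames(b_sites))
  b_idx <- integer(length(keep))
  for (chr in unique(achr)) {
    ai <- which(achr == chr)
    bi <- which(bchr == chr)
    key <- match(bc_target[ai], b_centers[bi])
    b_idx[ai] <- bi[key]
  }
  b <- b_sites[b_idx]
  d <- abs(d_signed[keep])
  cls <- classify_pair(d, tolerance)
  pairs <- data.frame(
    chrom = achr,
    a_start = GenomicRanges::start(a), a_end = GenomicRanges::end(a),
    b_start = GenomicRanges::start(b), b_end = GenomicRanges::end(b),
    a_center = ac, b_center = interval_centers(b),
    d = d, phase_class = cls)
  span <- new_intervals(achr,
                        pmin(pairs$a_start, pairs$b_start),
                        pmax(pairs$a_end, pairs$b_end),
                        genome = genome, name = as.character(cls))
  list(pairs = pairs,
       phased = span[S4Vectors::mcols(span)$name == "phased"],
       unphased = span[S4Vectors::mcols(span)$name == "unphased"])
}

#' Fraction of planted pairs recovered with the correct phase class
#'
#' Matches recovered pairs to a truth table by (chrom, a-site center); a
#' planted pair that was not recovered, or recovered with the wrong class,
#' counts as an error.
#'
#' @param truth Truth table from [plant_motif_pairs()].
#' @param pairs The `pairs` data.frame from [partition_pairs()].
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_phasing_recovery <- function(truth, pairs) {
  if (nrow(truth) == 0L) stop_arg("empty truth table")
  m <- match(paste(truth$chrom, truth$a_center),
             paste(pairs$chrom, pairs$a_center))
  got <- as.character(pairs$phase_class[m])
  mean(!is.na(got) & got == truth$class)
}

#' Write the pair table as TSV
#'
#' @param pairs The `pairs` data.frame from [partition_pairs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign each region to its nearest gene TSS
#'
#' Maps every region to the gene whose TSS center is nearest to the region
#' center; distance ties break to the lexicographically smallest gene name.
#'
#' @param regions `GRanges` of regions.
#' @param tss `GRanges` of transcription start sites carrying gene names in
#'   the `name` metadata column (or as `names(tss)`).
#' @return Character vector of gene names, one per region (`NA` when the
#'   region's chromosome has no TSS).
#' @export
assign_nearest_gene <- function(regions, tss) {
  if (length(tss) == 0L) stop_arg("tss set must be non-empty")
  genes <- S4Vectors::mcols(tss)$name
  if (is.null(genes)) genes <- names(tss)
  if (is.null(genes) || anyNA(genes)) stop_arg("tss must carry gene names")
  genes <- as.character(genes)
  rc <- interval_centers(regions)
  rchr <- as.character(GenomicRanges::seqnames(regions))
  tc <- interval_centers(tss)
  tchr <- as.character(GenomicRanges::seqnames(tss))
  out <- rep(NA_character_, length(regions))
  for (chr in unique(rchr)) {
    ti <- which(tchr == chr)
    if (length(ti) == 0L) next
    ri <- which(rchr == chr)
    # order ties so the first minimum is the lexicographically smallest gene
    o <- ti[order(tc[ti], genes[ti])]
    for (k in ri) {
      dist <- abs(tc[o] - rc[k])
      cand <- o[dist == min(dist)]
      out[k] <- min(genes[cand])
    }
  }
  out
}
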