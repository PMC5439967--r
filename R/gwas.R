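# GWAS-SNP enrichment in region sets: the binomial statistic b(x; n, p)
# with n = SNPs in a trait, x = trait SNPs inside the (extended, merged)
# regions and p = the fraction of the uniquely mappable genome covered by
# those regions; plus LD expansion of lead SNPs and the two-proportion
# z-test used to compare site families.

#' Read a GWAS-catalog-style SNP table
#'
#' Expects the GWAS Catalog column dialect: `CHR_ID`, `CHR_POS`, `SNPS`,
#' `DISEASE/TRAIT` (tab-separated, header). Rows with a missing chromosome
#' or position are skipped with a warning stating the count; duplicate
#' (trait, rsid) records collapse to one.
#'
#' @param path Path to the TSV.
#' @return A `GwasCatalog`: data.frame with columns `trait`, `chrom`, `pos`
#'   (1-based SNP position), `rsid`.
#' @export
read_gwas_catalog <- function(path) {
  if (!file.exists(path)) stop_arg("GWAS catalog not found: ", path)
  df <- read.delim(path, check.names = TRUE, colClasses = "character")
  need <- c("CHR_ID", "CHR_POS", "SNPS", "DISEASE.TRAIT")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_arg("GWAS catalog missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$CHR_POS))
  drop <- is.na(pos) | !nzchar(df$CHR_ID)
  if (any(drop))
    warning(sum(drop), " row(s) without usable coordinates skipped",
            call. = FALSE)
  out <- data.frame(trait = df$DISEASE.TRAIT[!drop], chrom = df$CHR_ID[!drop],
                    pos = pos[!drop], rsid = df$SNPS[!drop],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("trait", "rsid")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GwasCatalog", "data.frame")
  out
}

#' Construct a GWAS catalog from vectors
#'
#' @param trait,chrom,pos,rsid Per-SNP fields; recycled to a common length.
#' @return A `GwasCatalog` data.frame (deduplicated on trait + rsid).
#' @export
gwas_catalog <- function(trait, chrom, pos, rsid) {
  out <- data.frame(trait = trait, chrom = chrom, pos = pos, rsid = rsid,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("trait", "rsid")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GwasCatalog", "data.frame")
  out
}

#' Write a GWAS catalog in the GWAS Catalog column dialect
#'
#' @param catalog A `GwasCatalog`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gwas_catalog <- function(catalog, path) {
  df <- data.frame(CHR_ID = catalog$chrom, CHR_POS = catalog$pos,
                   SNPS = catalog$rsid, check.names = FALSE)
  df[["DISEASE/TRAIT"]] <- catalog$trait
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD table
#'
#' Columns: `lead_rsid`, `chrom`, `pos`, `rsid`, `r2` (TSV, header).
#'
#' @param path Path to the TSV.
#' @return Data.frame with those columns; `r2` validated to `[0, 1]`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop_arg("LD table not found: ", path)
  df <- read.delim(path, colClasses = c(lead_rsid = "character",
                                        chrom = "character", pos = "numeric",
                                        rsid = "character", r2 = "numeric"))
  need <- c("lead_rsid", "chrom", "pos", "rsid", "r2")
  if (length(setdiff(need, names(df))))
    stop_arg("LD table missing required column(s)")
  if (any(df$r2 < 0 | df$r2 > 1, na.rm = TRUE))
    stop_arg("LD r2 values must lie in [0, 1]")
  df
}

#' Expand lead SNPs by linkage disequilibrium
#'
#' Augments each trait with the linked SNPs of its lead SNPs having
#' `r2 > r2_min` (strict, matching the "lead plus LD r2>0.8" convention);
#' duplicate rsids and duplicate positions within a trait are dropped.
#'
#' @param catalog A `GwasCatalog`.
#' @param ld LD table (see [read_ld_table()]).
#' @param r2_min Strict lower bound on r2 (default 0.8).
#' @return The expanded `GwasCatalog`.
#' @export
ld_expand <- function(catalog, ld, r2_min = 0.8) {
  if (!is.numeric(r2_min) || r2_min < 0 || r2_min > 1)
    stop_arg("r2_min must be in [0, 1]")
  if (is.null(ld) || nrow(ld) == 0L) return(catalog)
  ld <- ld[ld$r2 > r2_min, , drop = FALSE]
  if (nrow(ld) == 0L) return(catalog)
  add <- merge(catalog[, c("trait", "rsid")], ld,
               by.x = "rsid", by.y = "lead_rsid")
  if (nrow(add) == 0L) return(catalog)
  out <- rbind(catalog,
               data.frame(trait = add$trait, chrom = add$chrom, pos = add$pos,
                          rsid = add$rsid.y, stringsAsFactors = FALSE))
  out <- out[!duplicated(out[, c("trait", "rsid")]), , drop = FALSE]
  out <- out[!duplicated(out[, c("trait", "chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GwasCatalog", "data.frame")
  out
}

#' Build a mappability track
#'
#' @param mappable `GRanges` of uniquely mappable intervals.
#' @return A `MappabilityTrack`: merged intervals plus the total mappable
#'   length.
#' @export
mappability_track <- function(mappable) {
  m <- merge_intervals(mappable)
  structure(list(mappable = m, total_mappable = covered_length(m)),
            class = "MappabilityTrack")
}

#' All-mappable track for a genome
#'
#' The default when no mappability mask is supplied (synthetic genomes are
#' fully mappable by construction).
#'
#' @param genome Named vector of chromosome lengths.
#' @return A `MappabilityTrack` covering every base.
#' @export
uniform_mappability <- function(genome) {
  mappability_track(new_intervals(names(genome), 1, unname(genome),
                                  genome = genome))
}

#' Fraction of the mappable genome covered by a region set
#'
#' `p = covered_length(merge(regions) intersect mappable) / total_mappable`;
#' the background success probability of the binomial enrichment test.
#'
#' @param regions `GRanges`.
#' @param map A `MappabilityTrack`.
#' @return Probability in `[0, 1]`.
#' @export
mappable_fraction <- function(regions, map) {
  if (!is(map, "MappabilityTrack")) stop_arg("map must be a MappabilityTrack")
  if (map$total_mappable <= 0) stop_arg("total mappable length is zero")
  inter <- GenomicRanges::intersect(merge_intervals(regions), map$mappable,
                                    ignore.strand = TRUE)
  covered_length(inter) / map$total_mappable
}

#' Upper binomial tail P(X >= x) for X ~ Bin(n, p)
#'
#' The enrichment p-value of the binomial overlap statistic `b(x; n, p)`:
#' the probability of observing `x` or more of the `n` trait SNPs inside
#' regions covering mappable fraction `p`.
#'
#' @param x Observed overlap count(s) (vectorized).
#' @param n Total trait SNP count.
#' @param p Background success probability in `[0, 1]`.
#' @return Tail probability in `[0, 1]`; `x = 0` gives 1.
#' @export
binomial_tail <- function(x, n, p) {
  if (any(p < 0 | p > 1)) stop_arg("p must be in [0, 1]")
  if (any(x < 0 | x > n)) stop_arg("x must satisfy 0 <= x <= n")
  pbinom(x - 1, n, p, lower.tail = FALSE)
}

catalog_snp_granges <- function(catalog, genome = NULL) {
  new_intervals(catalog$chrom, catalog$pos, catalog$pos, genome = genome,
                name = catalog$rsid, trait = catalog$trait)
}

#' Binomial enrichment of trait SNPs in a region set
#'
#' Regions are extended by `w` and merged (so overlapping windows are not
#' double counted), then per trait: `x` = SNPs inside the extended union,
#' `n` = trait SNP count, `p` = [mappable_fraction()] of the extended union.
#' The p-value is the upper binomial tail `P(X >= x)` for `X ~ Bin(n, p)`
#' and the fold change is `x / (n p)`. Benjamini-Hochberg q-values across
#' traits are appended as a convenience; the statistic itself is the raw
#' binomial tail.
#'
#' @param regions `GRanges` of regions (e.g. ChIP-seq peaks or phased site
#'   spans).
#' @param catalog A `GwasCatalog`.
#' @param map A `MappabilityTrack`; defaults to an all-mappable track built
#'   from the `seqlengths` of `regions`.
#' @param w Symmetric window extension in bp (default 0).
#' @return A `BinomialEnrichment` data.frame with columns `trait`, `window`,
#'   `x`, `n`, `p`, `fold`, `p_value`, `q_value`, sorted by `p_value`.
#' @export
binomial_enrichment <- function(regions, catalog, map = NULL, w = 0) {
  if (!is_count(w)) stop_arg("w must be a single non-negative integer")
  if (is.null(map)) {
    sl <- GenomeInfoDb::seqlengths(regions)
    if (anyNA(sl) || length(sl) == 0L)
      stop_arg("supply a MappabilityTrack or seqlengths on the regions")
    map <- uniform_mappability(sl)
  }
  ext <- merge_intervals(extend_regions(regions, w))
  p <- mappable_fraction(ext, map)
  traits <- unique(catalog$trait)
  n_all <- table(catalog$trait)
  snps <- catalog_snp_granges(catalog) # sorted; group by its own trait column
  inside <- GenomicRanges::countOverlaps(snps, ext, ignore.strand = TRUE) > 0L
  x_all <- tapply(inside, S4Vectors::mcols(snps)$trait, sum)
  keep <- traits[n_all[traits] > 0]
  if (length(keep) < length(traits))
    warning("skipping ", length(traits) - length(keep), " empty trait(s)",
            call. = FALSE)
  n <- as.integer(n_all[keep])
  x <- as.integer(x_all[keep])
  p_value <- binomial_tail(x, n, p)
  fold <- ifelse(n * p > 0, x / (n * p), NA_real_)
  out <- data.frame(trait = keep, window = w, x = x, n = n, p = p,
                    fold = fold, p_value = p_value,
                    q_value = p.adjust(p_value, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("BinomialEnrichment", "data.frame")
  out
}

#' Binomial enrichment over a sweep of window sizes
#'
#' Runs [binomial_enrichment()] for each window and stacks the results.
#' The default sweep covers the +/-1 kb, 2 kb, 5 kb and 10 kb windows used
#' for region-SNP overlap scans.
#'
#' @param regions,catalog,map As in [binomial_enrichment()].
#' @param windows Integer vector of window half-widths in bp.
#' @return A `BinomialEnrichment` data.frame over all windows.
#' @export
binomial_enrichment_sweep <- function(regions, catalog, map = NULL,
                                      windows = c(1000, 2000, 5000, 10000)) {
  res <- lapply(windows, function(w)
    binomial_enrichment(regions, catalog, map = map, w = w))
  out <- do.call(rbind, res)
  class(out) <- c("BinomialEnrichment", "data.frame")
  out
}

#' Two-proportion z-test
#'
#' Pooled-variance z-score test for the difference of two proportions
#' `x1/n1` and `x2/n2`, with two-sided normal p-value. A degenerate pooled
#' proportion (0 or 1) yields `z = 0`, `p = 1`.
#'
#' @param x1,n1,x2,n2 Success and total counts (integers, `0 <= x <= n`,
#'   `n > 0`).
#' @return A list with `z`, `p_value`, and the two proportions.
#' @export
ztest_proportions <- function(x1, n1, x2, n2) {
  for (v in list(x1, n1, x2, n2)) if (!is_count(v))
    stop_arg("counts must be non-negative integers")
  if (n1 <= 0 || n2 <= 0) stop_arg("n1 and n2 must be positive")
  if (x1 > n1 || x2 > n2) stop_arg("x must not exceed n")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
  }
  list(z = z, p_value = p, prop1 = p1, prop2 = p2)
}
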