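# Spatial co-localization statistics: nearest-distance histograms around
# anchors, globally normalized density profiles (fold over the genome-wide
# uniform expectation, so 1.0 is the null level), Fisher exact overlap
# enrichment against an open-chromatin background, and Venn-style ChIP peak
# co-occupancy counts.

#' Histogram of nearest-site distances around anchors
#'
#' For each anchor, the signed oriented distance to its nearest site (see
#' [nearest_center_distance()]) is binned when it falls inside
#' `[-half_window, half_window)`; anchors with no site in range contribute
#' nothing (nearest-only accounting).
#'
#' @param anchors,sites `GRanges` on a shared genome.
#' @param half_window Half-width of the window in bp.
#' @param bin_width Bin width in bp; must divide `2 * half_window`.
#' @param oriented Flip distances for minus-strand anchors.
#' @return A `DistanceHistogram` object (bin edges, counts, anchor count).
#' @export
distance_histogram <- function(anchors, sites, half_window, bin_width,
                               oriented = TRUE) {
  check_binning(half_window, bin_width)
  d <- nearest_center_distance(anchors, sites, oriented = oriented)
  d <- d[!is.na(d) & d >= -half_window & d < half_window]
  nbins <- as.integer(2 * half_window / bin_width)
  counts <- tabulate(floor((d + half_window) / bin_width) + 1L, nbins)
  structure(list(half_window = half_window, bin_width = bin_width,
                 bin_edges = seq(-half_window, half_window, by = bin_width),
                 counts = counts, n_anchors = length(anchors)),
            class = "DistanceHistogram")
}

check_binning <- function(half_window, bin_width) {
  if (!is_count(bin_width) || bin_width <= 0)
    stop_arg("bin_width must be a positive integer")
  if (!is_count(half_window) || half_window <= 0)
    stop_arg("half_window must be a positive integer")
  if ((2 * half_window) %% bin_width != 0)
    stop_arg("bin_width must divide 2 * half_window")
}

#' @export
print.DistanceHistogram <- function(x, ...) {
  cat("DistanceHistogram: +/-", x$half_window, "bp in", x$bin_width,
      "bp bins;", sum(x$counts), "of", x$n_anchors, "anchors in range\n")
  invisible(x)
}

#' @export
as.data.frame.DistanceHistogram <- function(x, ...) {
  data.frame(bin_start = head(x$bin_edges, -1L),
             bin_end = x$bin_edges[-1L], count = x$counts)
}

#' Globally normalized site density profile around anchors
#'
#' Counts all site centers (not nearest-only) in bins relative to each
#' anchor center, flipping the axis for minus-strand anchors when
#' `oriented`. Counts are normalized to the genome-wide uniform expectation
#' `n_anchors * n_sites * bin_width / G`, so a uniformly random site set has
#' expected density 1 in every bin; this is the "normalized globally to the
#' average number of sites per window" convention of summit/TSS
#' metaprofiles.
#'
#' @param anchors,sites `GRanges` on a shared genome.
#' @param half_window,bin_width Window geometry in bp.
#' @param oriented Flip bins for minus-strand anchors (default `TRUE`).
#' @param genome_length Normalizing length `G`; defaults to the total of the
#'   known `seqlengths`, and may be set to a mappable length instead.
#' @return A `DensityProfile` object with raw counts, the per-bin expected
#'   count, and the normalized density.
#' @export
density_profile <- function(anchors, sites, half_window, bin_width,
                            oriented = TRUE, genome_length = NULL) {
  check_binning(half_window, bin_width)
  if (length(sites) == 0L)
    stop_arg("density normalizer undefined: empty site set")
  if (is.null(genome_length)) {
    sl <- GenomeInfoDb::seqlengths(anchors)
    if (anyNA(sl) || length(sl) == 0L)
      stop_arg("genome_length unknown: supply it or set seqlengths")
    genome_length <- sum(as.numeric(sl))
  }
  nbins <- as.integer(2 * half_window / bin_width)
  counts <- numeric(nbins)
  ac <- interval_centers(anchors)
  achr <- as.character(GenomicRanges::seqnames(anchors))
  flip <- oriented & as.character(GenomicRanges::strand(anchors)) == "-"
  sc_all <- interval_centers(sites)
  schr <- as.character(GenomicRanges::seqnames(sites))
  for (chr in unique(achr)) {
    sc <- sort(sc_all[schr == chr])
    if (length(sc) == 0L) next
    ai <- which(achr == chr)
    lo <- findInterval(ac[ai] - half_window - 1, sc)
    hi <- findInterval(ac[ai] + half_window, sc)
    for (k in seq_along(ai)) {
      if (hi[k] <= lo[k]) next
      rel <- sc[(lo[k] + 1L):hi[k]] - ac[ai[k]]
      if (flip[ai[k]]) rel <- -rel
      rel <- rel[rel >= -half_window & rel < half_window]
      if (length(rel))
        counts <- counts + tabulate(floor((rel + half_window) / bin_width) + 1L,
                                    nbins)
    }
  }
  expected <- length(anchors) * length(sites) * bin_width / genome_length
  structure(list(half_window = half_window, bin_width = bin_width,
                 bin_edges = seq(-half_window, half_window, by = bin_width),
                 raw_counts = counts, expected_per_bin = expected,
                 density = counts / expected, n_anchors = length(anchors),
                 n_sites = length(sites), genome_length = genome_length),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat("DensityProfile: +/-", x$half_window, "bp in", x$bin_width,
      "bp bins;", x$n_anchors, "anchors,", x$n_sites, "sites\n")
  cat(sprintf("expected count/bin %.3f; density range [%.2f, %.2f]\n",
              x$expected_per_bin, min(x$density), max(x$density)))
  invisible(x)
}

#' @export
as.data.frame.DensityProfile <- function(x, ...) {
  data.frame(bin_start = head(x$bin_edges, -1L), bin_end = x$bin_edges[-1L],
             count = x$raw_counts, density = x$density)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by summation of hypergeometric point probabilities at most
#' that of the observed table (with a small relative slack against floating
#' point, the convention of the classical test); sample odds ratio
#' `(a*d)/(b*c)` with a Woolf (log-OR normal) 95 percent interval. With any
#' zero margin the table is uninformative: p = 1, odds ratio undefined.
#'
#' @param a,b,c_,d_ Non-negative integer cells: foreground
#'   overlap/non-overlap, background overlap/non-overlap.
#' @return A `FisherResult` list: `table`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
fisher_test_2x2 <- function(a, b, c_, d_) {
  cells <- c(a = a, b = b, c = c_, d = d_)
  if (any(!vapply(cells, is_count, TRUE)))
    stop_arg("table cells must be non-negative integers")
  m1 <- a + b; m2 <- c_ + d_; k <- a + c_
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d_) == 0) {
    return(structure(list(table = cells, odds_ratio = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, p_value = 1),
                     class = "FisherResult"))
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  or <- (a * d_) / (b * c_) # Inf/NaN when a zero cell is involved
  if (all(cells > 0)) {
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(table = cells, odds_ratio = or, ci_low = ci[1L],
                 ci_high = ci[2L], p_value = p), class = "FisherResult")
}

#' @export
print.FisherResult <- function(x, ...) {
  cat(sprintf("Fisher 2x2 [%d %d / %d %d]: OR = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"],
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Fisher exact overlap enrichment against a background region set
#'
#' Builds the 2x2 table: `a` = sites of `a_sites` whose `w`-extension hits
#' `b_sites`, `b` = the rest; `c`, `d` = the same counts after restricting
#' both site sets to intervals whose centers fall inside the merged
#' background union (e.g. combined open-chromatin regions). Direct overlap
#' is `w = 0` (intervals share at least one bp).
#'
#' @param a_sites,b_sites Site sets (`GRanges`).
#' @param background Background region set (`GRanges`), non-empty.
#' @param w Window extension in bp (default 0).
#' @return A list with the `ContingencyTable2x2` (`table`) and the
#'   `FisherResult` (`result`).
#' @export
fisher_overlap <- function(a_sites, b_sites, background, w = 0) {
  if (length(background) == 0L) stop_arg("background must be non-empty")
  bg <- merge_intervals(background)
  a_in <- filter_by_center(a_sites, bg)
  b_in <- filter_by_center(b_sites, bg)
  a <- overlap_count(a_sites, b_sites, w)
  c_ <- overlap_count(a_in, b_in, w)
  res <- fisher_test_2x2(a, length(a_sites) - a, c_, length(a_in) - c_)
  list(table = res$table, result = res)
}

#' Venn-style co-occupancy counts for 2-3 peak sets
#'
#' For every pair (and the triple, if three sets are given), counts per
#' member set the intervals whose `w`-extension intersects at least one
#' interval in every other set of the group, with percentages relative to
#' each parent set.
#'
#' @param sets Named list of 2-3 `GRanges`.
#' @param w Window extension in bp (default 0 = full-interval overlap).
#' @return A `VennCounts` object: list of groups, each with per-set counts
#'   and percentages plus set sizes.
#' @export
chip_peak_intersection <- function(sets, w = 0) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop_arg("sets must be a named list of 2-3 GRanges")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_arg("sets must be named")
  nm <- names(sets)
  groups <- utils::combn(nm, 2L, simplify = FALSE)
  if (length(nm) == 3L) groups <- c(groups, list(nm))
  out <- lapply(groups, function(g) {
    per_set <- lapply(g, function(s) {
      ext <- extend_regions(sets[[s]], w)
      hit <- rep(TRUE, length(ext))
      for (o in setdiff(g, s)) {
        hit <- hit & GenomicRanges::countOverlaps(ext, sets[[o]],
                                                  ignore.strand = TRUE) > 0L
      }
      n <- sum(hit)
      list(count = n, percent = 100 * n / max(1L, length(ext)))
    })
    names(per_set) <- g
    list(members = g, counts = vapply(per_set, `[[`, 0, "count"),
         percents = vapply(per_set, `[[`, 0, "percent"))
  })
  names(out) <- vapply(groups, paste, "", collapse = "&")
  structure(list(groups = out,
                 sizes = vapply(sets, length, 0L)),
            class = "VennCounts")
}

#' @export
print.VennCounts <- function(x, ...) {
  cat("Co-occupancy counts (sizes:",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), ")\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(" ", g, ":",
        paste(sprintf("%s=%d (%.1f%%)", names(gr$counts), gr$counts,
                      gr$percents), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize Venn counts to JSON
#'
#' @param x A `VennCounts` object.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
venn_to_json <- function(x, path = NULL) {
  payload <- list(sizes = as.list(x$sizes),
                  groups = lapply(x$groups, function(g)
                    list(members = g$members, counts = as.list(g$counts),
                         percents = as.list(g$percents))))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
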