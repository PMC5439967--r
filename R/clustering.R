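# Correlation-dissimilarity hierarchical clustering of an
# expression/proteomics matrix (rows = proteins or genes, columns =
# samples): Pearson correlation on pairwise-complete observations,
# Bonferroni-corrected p-values, dissimilarity D = 1 - |r|, agglomerative
# clustering on D.

#' Pairwise Pearson correlations with Bonferroni-corrected p-values
#'
#' Correlates the rows of the matrix on pairwise-complete columns. Pairs
#' with fewer than `min_complete` shared observations, and rows with zero
#' variance, get `NA` correlations. The two-sided p-value comes from the
#' t-distribution with `n - 2` degrees of freedom; the Bonferroni factor is
#' the number of distinct off-diagonal pairs.
#'
#' @param m Numeric matrix, >= 2 rows and >= 3 columns; `NA`s allowed.
#' @param min_complete Minimum pairwise-complete observations (default 3).
#' @return List with matrices `r`, `p`, `p_adj` and the pairwise count
#'   matrix `n`.
#' @export
correlation_matrix <- function(m, min_complete = 3) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 3L)
    stop_arg("need >= 2 rows and >= 3 columns")
  r <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs",
                            method = "pearson"))
  n <- crossprod(!is.na(t(m)))
  r[n < min_complete] <- NA
  zero_var <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2L || isTRUE(all.equal(stats::var(x), 0))
  })
  if (any(zero_var)) {
    r[zero_var, ] <- NA
    r[, zero_var] <- NA
  }
  diag(r)[!zero_var & diag(n) >= min_complete] <- 1
  df <- n - 2
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), pmax(df, 1))
  p[abs(r) >= 1] <- 0 # exact +/-1 correlations
  p[is.na(r)] <- NA
  diag(p) <- 0
  n_pairs <- choose(nrow(m), 2)
  p_adj <- pmin(p * n_pairs, 1)
  list(r = r, p = p, p_adj = p_adj, n = n)
}

#' Correlation dissimilarity D = 1 - |r|
#'
#' Anti-correlated rows are as close as correlated ones: the dissimilarity
#' discriminates all correlated pairs regardless of sign. Undefined
#' correlations propagate as `NA`.
#'
#' @param r Correlation matrix with values in `[-1, 1]`.
#' @return A `DissimilarityMatrix` (symmetric, zero diagonal for
#'   self-correlation 1, values in `[0, 1]`).
#' @export
dissimilarity <- function(r) {
  r <- as.matrix(r)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop_arg("correlations must lie in [-1, 1]")
  D <- 1 - abs(r)
  D[D < 0] <- 0
  structure(D, class = c("DissimilarityMatrix", class(D)))
}

#' Agglomerative clustering on a dissimilarity matrix
#'
#' Hierarchical clustering (via [stats::hclust()]) on `D`, cut into `k`
#' groups. Undefined dissimilarities are replaced by the maximal value 1
#' (with a warning): rows with too few shared observations are treated as
#' unrelated.
#'
#' @param D Dissimilarity matrix (e.g. from [dissimilarity()]).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @param k Number of clusters, `1 <= k <= nrow(D)`.
#' @return List with `labels` (named integer cluster ids), the `hclust`
#'   tree, and `heights`.
#' @export
hierarchical_cluster <- function(D, linkage = c("complete", "average", "single"),
                                 k = 2) {
  linkage <- match.arg(linkage)
  D <- unclass(as.matrix(D))
  if (!is_count(k) || k < 1 || k > nrow(D))
    stop_arg("k must be an integer in [1, nrow(D)]")
  offdiag <- D[upper.tri(D) | lower.tri(D)]
  if (anyNA(offdiag)) {
    warning("undefined dissimilarities set to 1", call. = FALSE)
    D[is.na(D)] <- 1
    diag(D) <- 0
  }
  if (nrow(D) == 1L) {
    return(list(labels = setNames(1L, rownames(D)), tree = NULL,
                heights = numeric(0)))
  }
  hc <- hclust(as.dist(D), method = linkage)
  list(labels = cutree(hc, k = k), tree = hc, heights = hc$height)
}

#' Export a cluster tree in Newick format
#'
#' @param tree An `hclust` object (from [hierarchical_cluster()]).
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
tree_to_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Read an expression/proteomics matrix TSV
#'
#' Rows = proteins/genes (first column = row label), header = samples.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_arg("expression matrix not found: ", path)
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write an expression/proteomics matrix TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
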