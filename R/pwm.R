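# JASPAR count matrices and log-odds genome scanning.
#
# A motif is stored as its raw 4 x L count matrix plus the derived log-odds
# scorer
#   lo[b, i] = log2( (counts[b,i] + pc * bg[b]) / (colsum[i] + pc) / bg[b] )
# with pseudocount pc distributed by the background frequencies bg. Scanning
# reports every window on either strand whose summed log-odds reaches the
# threshold; the two stringency tiers are fractions of the dynamic score
# range (0.90 high, 0.80 low).

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif count matrix with its log-odds scorer
#'
#' @param counts 4 x L numeric matrix of base counts; rows A, C, G, T.
#' @param id Matrix accession (e.g. `"MA0006.1"`).
#' @param name Factor name.
#' @param background Base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Positive pseudocount, distributed by background
#'   frequency (default 0.8, common JASPAR practice).
#' @return A `MotifMatrix` object.
#' @export
motif_matrix <- function(counts, id = "motif", name = id,
                         background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_arg("counts must have 4 rows (A, C, G, T)")
  rownames(counts) <- DNA_BASES
  if (any(counts < 0) || anyNA(counts)) stop_arg("counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop_arg("every position needs a positive count")
  if (length(background) != 4L || any(background <= 0))
    stop_arg("background must be 4 positive frequencies")
  background <- background / sum(background)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop_arg("pseudocount must be > 0")
  csum <- colSums(counts)
  lo <- log2(sweep(counts + pseudocount * background, 2, csum + pseudocount, "/") /
               background)
  structure(list(id = id, name = name, counts = counts,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount, log_odds = lo),
            class = "MotifMatrix")
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cat("MotifMatrix", x$id, paste0("(", x$name, ")"),
      "length", ncol(x$counts), "\n")
  cat("consensus:", consensus_string(x), "\n")
  cat(sprintf("score range: [%.3f, %.3f] bits\n", min_score(x), max_score(x)))
  invisible(x)
}

#' Motif length in bp
#' @param m A `MotifMatrix`.
#' @return Integer length.
#' @export
motif_length <- function(m) ncol(m$counts)

#' Maximum attainable log-odds score
#' @param m A `MotifMatrix`.
#' @return Score in bits.
#' @export
max_score <- function(m) sum(apply(m$log_odds, 2, max))

#' Minimum attainable log-odds score
#' @param m A `MotifMatrix`.
#' @return Score in bits.
#' @export
min_score <- function(m) sum(apply(m$log_odds, 2, min))

#' Consensus sequence (highest-count base per position)
#' @param m A `MotifMatrix`.
#' @return Character string of length `motif_length(m)`.
#' @export
consensus_string <- function(m) {
  paste(DNA_BASES[apply(m$counts, 2, which.max)], collapse = "")
}

#' Reverse-complement a motif matrix
#' @param m A `MotifMatrix`.
#' @return A `MotifMatrix` scoring the opposite strand.
#' @export
reverse_complement_matrix <- function(m) {
  counts <- m$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(m$counts))), drop = FALSE]
  rownames(counts) <- DNA_BASES
  motif_matrix(counts, id = m$id, name = m$name,
               background = m$background, pseudocount = m$pseudocount)
}

#' Read JASPAR PFM text
#'
#' Parses the JASPAR 2016 PFM format: a `>ID name` header followed by four
#' rows `A [ 3 0 ... ]` (brackets optional).
#'
#' @param path Path to the PFM text file.
#' @param background,pseudocount Passed to [motif_matrix()].
#' @return A named list of `MotifMatrix` objects (names = accessions).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  if (!file.exists(path)) stop_arg("JASPAR file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  out <- list()
  if (length(headers) == 0L) return(out)
  bounds <- c(headers, length(lines) + 1L)
  for (h in seq_along(headers)) {
    hline <- sub("^>\\s*", "", lines[headers[h]])
    toks <- strsplit(hline, "\\s+")[[1]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    body <- lines[seq(headers[h] + 1L, bounds[h + 1L] - 1L)]
    if (length(body) != 4L)
      stop_arg("JASPAR parse error for ", id, ": expected 4 base rows, got ",
               length(body))
    rows <- lapply(body, function(l) {
      base <- sub("^([ACGTacgt]).*$", "\\1", l)
      nums <- gsub("[][ACGTacgt]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) stop_arg("JASPAR parse error for ", id, ": bad row '", l, "'")
      list(base = toupper(base), vals = vals)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES))
      stop_arg("JASPAR parse error for ", id, ": missing base row")
    lens <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(lens)) != 1L)
      stop_arg("JASPAR parse error for ", id, ": rows of unequal length")
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- bases
    counts <- counts[DNA_BASES, , drop = FALSE]
    out[[id]] <- motif_matrix(counts, id = id, name = name,
                              background = background,
                              pseudocount = pseudocount)
  }
  out
}

#' Write motifs in JASPAR PFM text format
#'
#' @param motifs A `MotifMatrix` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(motifs, path) {
  if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id, " ", m$name), con)
    for (b in DNA_BASES) {
      writeLines(paste0(b, "  [ ",
                        paste(format(m$counts[b, ], trim = TRUE), collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}

#' Score threshold for a stringency tier
#'
#' Maps the stringency token to a threshold
#' `min_score + f * (max_score - min_score)` with `f = 0.90` (high) or
#' `f = 0.80` (low).
#'
#' @param m A `MotifMatrix`.
#' @param stringency `"high"` or `"low"`.
#' @return Threshold in bits.
#' @export
score_threshold <- function(m, stringency = c("high", "low")) {
  stringency <- match.arg(stringency)
  f <- c(high = 0.90, low = 0.80)[[stringency]]
  min_score(m) + f * (max_score(m) - min_score(m))
}

#' Exact score distribution of a motif under its background model
#'
#' Dynamic-programming convolution of the per-position log-odds values under
#' the independent background model, on a discretized score grid. Exact up
#' to the grid granularity; practical for motif lengths well beyond the
#' enumeration limit.
#'
#' @param m A `MotifMatrix`.
#' @param granularity Score grid step in bits (default 1e-3).
#' @return A data.frame with columns `score` and `prob`, ascending scores.
#' @export
pwm_score_distribution <- function(m, granularity = 1e-3) {
  lo_i <- round(m$log_odds / granularity)
  offset <- -sum(apply(lo_i, 2, min)) # shift per-position minima to >= 0
  lo_i <- sweep(lo_i, 2, apply(lo_i, 2, min))
  span <- sum(apply(lo_i, 2, max))
  probs <- numeric(span + 1)
  probs[1L] <- 1
  for (i in seq_len(ncol(lo_i))) {
    nxt <- numeric(length(probs))
    for (b in 1:4) {
      sh <- lo_i[b, i]
      nxt[(sh + 1):length(probs)] <-
        nxt[(sh + 1):length(probs)] +
        m$background[b] * probs[seq_len(length(probs) - sh)]
    }
    probs <- nxt
  }
  keep <- probs > 0
  data.frame(score = ((which(keep) - 1) - offset) * granularity,
             prob = probs[keep])
}

#' Score threshold achieving a match p-value
#'
#' Smallest score whose upper-tail probability under the background model is
#' at most `p` (per strand, per position).
#'
#' @param m A `MotifMatrix`.
#' @param p Match p-value in (0, 1).
#' @param granularity Passed to [pwm_score_distribution()].
#' @return Threshold in bits.
#' @export
pvalue_threshold <- function(m, p, granularity = 1e-3) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop_arg("p must be in (0, 1)")
  d <- pwm_score_distribution(m, granularity)
  tail_p <- rev(cumsum(rev(d$prob)))
  i <- which(tail_p <= p)
  if (length(i) == 0L) return(max_score(m) + granularity)
  d$score[min(i)]
}

encode_bases <- function(seq_chr) {
  x <- match(strsplit(seq_chr, "", fixed = TRUE)[[1]], DNA_BASES)
  x # NA encodes N (and is propagated into window scores)
}

# summed log-odds of every window of length L; NA where a window contains N
score_windows <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(L)) {
    s <- s + lo[, i][codes[i:(i + n - 1L)]]
  }
  s
}

#' Scan a genome sequence with a motif on both strands
#'
#' Every window (forward and reverse strand) scoring at or above the
#' threshold is reported; windows containing N are skipped. Reverse-strand
#' hits are reported on forward coordinates with strand `-`. Overlapping
#' hits are all reported (no greedy masking), because downstream
#' co-localization statistics need complete site lists.
#'
#' @param seqs A `DNAStringSet` (see [read_genome_fasta()]) or single
#'   character string.
#' @param m A `MotifMatrix`.
#' @param stringency `"high"` (threshold at 90 percent of the score range) or
#'   `"low"` (80 percent); ignored when `threshold` is given.
#' @param threshold Explicit score threshold in bits, overriding
#'   `stringency`.
#' @return A sorted `GRanges` of hits with metadata columns `score` (bits)
#'   and `matrix_id`.
#' @export
scan_sequence <- function(seqs, m, stringency = c("high", "low"),
                          threshold = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(c(chr = toupper(seqs)))
  thr <- if (is.null(threshold)) score_threshold(m, match.arg(stringency)) else threshold
  L <- motif_length(m)
  rc <- reverse_complement_matrix(m)
  hits <- list()
  for (chr in names(seqs)) {
    codes <- encode_bases(as.character(seqs[[chr]]))
    for (str in c("+", "-")) {
      lo <- if (str == "+") m$log_odds else rc$log_odds
      sc <- score_windows(codes, lo)
      pos <- which(!is.na(sc) & sc >= thr)
      if (length(pos)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chr, start = pos, end = pos + L - 1L, strand = str,
          score = sc[pos])
      }
    }
  }
  genome <- genome_lengths(seqs)
  if (length(hits) == 0L) {
    return(new_intervals(character(0), integer(0), integer(0), genome = genome,
                         score = numeric(0), matrix_id = character(0)))
  }
  df <- do.call(rbind, hits)
  new_intervals(df$chrom, df$start, df$end, strand = df$strand,
                genome = genome, score = df$score, matrix_id = m$id)
}

#' Export motif hits as BED6
#'
#' Score column carries the log-odds score rounded to 2 decimals; the name
#' column carries the matrix accession.
#'
#' @param hits `GRanges` from [scan_sequence()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  mid <- S4Vectors::mcols(hits)$matrix_id
  gr <- hits
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$name <- if (is.null(mid)) "." else mid
  S4Vectors::mcols(gr)$score <- round(S4Vectors::mcols(hits)$score, 2)
  write_bed(gr, path)
}
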