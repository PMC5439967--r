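---
title: "Motif co-localization, rotational phasing and GWAS enrichment with motifcoloc"
author: "motifcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif co-localization, rotational phasing and GWAS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcoloc)
```

# Overview

`motifcoloc` implements a complete computational workflow for asking whether
two transcription factors co-occupy the genome in a way that permits a
physical or functional partnership. The motivating system is the bHLH
factor TCF21 and the dioxin receptor heterodimer AHR-ARNT in coronary
artery smooth muscle cells, but every stage is generic:

1. **PWM scanning** — parse JASPAR count matrices, build log-odds scorers,
   and call predicted binding sites genome-wide at two stringency tiers.
2. **Spatial co-localization** — nearest-site distance histograms and
   globally normalized density metaprofiles of one site set around another
   (or around ChIP-seq summits / oriented TSS), plus Fisher exact overlap
   enrichment against an open-chromatin background universe.
3. **Rotational phasing** — classify co-localized site pairs by whether
   their spacing is a multiple of the ~10 bp DNA helical pitch (same face
   of the double helix, direct contact possible) or offset by ~5 bp
   (opposite faces, only indirect contact possible).
4. **GWAS-SNP enrichment** — the binomial overlap statistic `b(x; n, p)`
   with mappability correction, a window sweep, LD expansion of lead SNPs,
   and a two-proportion z-test for comparing site families.
5. **Correlation-dissimilarity clustering** — Pearson correlation with
   Bonferroni correction, `D = 1 - |r|`, and agglomerative clustering, the
   workflow used for plaque proteomics matrices.
6. **Synthetic data** — a seeded generator that plants all of the above
   structures so the full pipeline is testable without any downloads.

Intervals are carried as `GenomicRanges::GRanges` throughout, 1-based
closed as usual in Bioconductor; all plain-text interval I/O is BED
(0-based half-open) and conversion happens only at the file boundary. The
center of an interval `[start, end]` is the deterministic lower-median
base `floor((start + end) / 2)`, so width-1 summits and SNPs are their own
centers and no derived distance depends on the coordinate convention.

# Site prediction

A JASPAR count matrix with counts `c[b, i]`, background frequencies `bg`
(uniform by default) and pseudocount `pc` (default 0.8, distributed by
background frequency, common JASPAR practice) yields the log-odds scorer

```
lo[b, i] = log2( (c[b, i] + pc * bg[b]) / (colsum[i] + pc) / bg[b] )
```

in bits. `scan_sequence()` reports every window on either strand whose
summed log-odds reaches the threshold; windows containing N are skipped,
minus-strand hits are reported on forward coordinates, and overlapping
hits are all kept because the downstream co-localization statistics need
complete site lists.

The source analyses used a genome-wide scanner at two unstated cutoffs, so
the stringency tiers here are defined reproducibly relative to the
dynamic range of each matrix: `threshold = min + f * (max - min)` with
`f = 0.90` ("high") or `f = 0.80` ("low"). The low tier is a superset of
the high tier by construction. An explicit bit threshold, or a match
p-value cutoff computed exactly against the background model
(`pvalue_threshold()`, a dynamic-programming convolution of the
per-position score distributions on a discretized grid, default step
1e-3 bits), can be used instead. Because the tiers are scanner-specific,
absolute genome-wide hit counts from other scanners are not comparable;
all downstream statistics are invariant to that choice in the sense that
they are computed from whichever site lists are supplied.

```{r, eval = FALSE}
motifs <- bundled_motifs()      # DRE (MA0006.1) + synthetic E-box stand-in
genome <- read_genome_fasta("genome.fa")
hits_dre <- scan_sequence(genome, motifs[[1]], stringency = "high")
```

The bundled motif file carries the classic 6-bp dioxin-response-element
count matrix (consensus TGCGTG) and a **synthetic** 12-bp E-box matrix
(CACGTG core with sharpened flanks) standing in for the curated bHLH
profile, which is not redistributable with the package. The file is named
`motifs_synthetic.jaspar` to make the provenance explicit.

# Co-localization statistics

`distance_histogram()` bins, per anchor, the signed oriented distance to
the *nearest* site (each anchor contributes at most once). Equidistant
left/right neighbours break deterministically to the upstream side so
histograms are reproducible.

`density_profile()` counts *all* site centers around each anchor and
normalizes globally: the expected count per bin under a uniform site
distribution is `n_anchors * n_sites * bin_width / G`, so density 1.0 is
the null level in every bin. `G` defaults to the total genome length and
may be set to the mappable length instead; with the default the profile
is the plain fold-over-uniform used by summit metaprofile tools.

`fisher_overlap()` forms the 2x2 table the way the source reports it
("x sites overlapping; y overlapping within the background"): foreground
rows from the whole-genome site sets, background rows from the same sets
restricted to sites whose centers fall in the merged background union
(e.g. combined open-chromatin regions). The two-sided p-value is computed
by summation of hypergeometric point probabilities; the odds ratio is the
sample `(a d)/(b c)` with a Woolf log-OR 95% interval, chosen because it
is closed-form and deterministic (the conditional-MLE interval is
deliberately out of scope). Degenerate margins give p = 1 and an
undefined odds ratio rather than an error.

# Rotational phasing

With `r = d mod 10`, a pair at center distance `d` is **phased** when
`min(r, 10 - r) <= tolerance` and **unphased** when
`|r - 5| <= tolerance`; anything else is unclassified, and `d = 0` is
phased (the limit of the n x 10 bp rule). The default tolerance is 1 bp:
the listed spacings are exact multiples, but real spacings jitter, and
±1 bp keeps the two classes maximally separated; tolerance 0 reproduces
the literal rule and tolerances above 2 bp are rejected because the
classes would overlap. Classification is periodic in 10 bp.

`partition_pairs()` pairs each a-site with its nearest b-site within
`max_d` (default 45 bp, the largest informative spacing of the grid —
beyond that the phase classes recycle without new information). Pairing
is one pair per a-site; b-sites may pair multiply, matching the
nearest-site framing of the distance histograms. Pair spans are emitted
as `phased`/`unphased` region sets for downstream gene assignment
(`assign_nearest_gene()`, ties to the lexicographically smallest gene so
results are deterministic) and GWAS enrichment.

# GWAS-SNP binomial enrichment

For a region set and one trait with `n` SNPs, of which `x` fall inside
the regions after extension by `w` bp and merging (merging first, so
overlapping windows are never double-counted and `p` stays a
probability):

```
p        = mappable length inside regions / total mappable length
p_value  = P(X >= x),  X ~ Binomial(n, p)
fold     = x / (n p)
```

SNP membership uses the single base position. The mappability track
defaults to all-mappable, which is exact for synthetic genomes; real
analyses should supply a uniqueness mask. The window sweep defaults to
±1, 2, 5 and 10 kb, the union of the window lists used in the source
analyses. Benjamini-Hochberg q-values are appended across traits as a
modern convenience; the statistic itself is the raw binomial tail.
`ld_expand()` augments lead SNPs with linked SNPs at `r2 > 0.8` (strict)
before testing. `ztest_proportions()` is the pooled-variance two-sample
z-test for comparing overlap rates of two site families, with the
degenerate pooled proportions 0 and 1 mapped to z = 0, p = 1.

# Correlation-dissimilarity clustering

`correlation_matrix()` uses pairwise-complete observations with a minimum
of 3 shared samples per pair (proteomics matrices are sparse; pairs below
the minimum, and zero-variance rows, are flagged undefined rather than
silently numeric). P-values come from the t-distribution with `n - 2`
degrees of freedom and are Bonferroni-corrected by the number of distinct
pairs. `dissimilarity()` is `D = 1 - |r|`, which treats anti-correlated
rows as close — the transform that "best discriminates all correlated
pairs". `hierarchical_cluster()` runs agglomerative clustering with
complete linkage by default (the heatmap routine behind the original
figure does not state its linkage; complete is its common default and the
choice is configurable), replaces undefined dissimilarities by the
maximal value 1, and cuts at a user-chosen `k`. The source figure's exact
cluster memberships depend on that unstated linkage and k, so they are
not a validation surface; planted-block recovery is.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and
are not tuning knobs:

- **Genome**: 1 Mb over 2 chromosomes, iid bases at GC 0.41 (human-like).
- **Planted pairs**: 200 phased (spacings {10, 20, 30, 40} bp) and 200
  unphased (spacings {15, 25, 35, 45} bp), consensus sequences written
  into the genome with alternating strands and a minimum 150 bp gap
  between pair spans. The unphased grid starts at 15 bp rather than 5 bp
  because, at the bundled motif widths (6 and 12 bp), a 5 bp center
  separation would force the two consensus sequences to occupy the same
  bases; 15, 25, 35, 45 preserve the 5-mod-10 class. Consensus planting
  guarantees that high-stringency scanning recovers every planted site;
  chance decoy hits in the background sequence are retained as realistic
  noise.
- **Summits**: one width-1 summit per planted site, displaced by
  Normal(0, 25 bp) — a typical summit-call accuracy — plus optional
  uniform decoys.
- **Traits**: ten traits of 100 SNPs; one trait has a planted fraction
  `f` of its SNPs forced into the target regions (default f = 0.3,
  i.e. 5x a background probability of 0.06), the rest are uniform over
  the mappable genome. Each lead SNP gets 0-3 linked SNPs within 50 kb
  with r² from a 60/40 mixture of Uniform(0.8, 1) and Uniform(0, 0.8).
- **Expression**: rows load on block factors with alternating sign, so
  `row = s (sqrt(w) z_block + sqrt(1 - w) noise_sd e)`; with
  `noise_sd = 1` the expected within-block `|r|` equals `within_r`
  (default 0.9), and `noise_sd = 0` gives exactly 1.

Every generator derives its RNG stream from the single configured seed
(distinct fixed sub-streams per generator) and emits a truth table; the
truth tables are the contract between simulation and tests. What the
simulations deliberately do *not* emulate: nucleotide composition
heterogeneity and repeats, realistic LD block structure, chromatin-state
dependence of binding, and read-level noise. Passing the planted-recovery
tests therefore demonstrates correctness of the statistics and the
pipeline plumbing, not performance on real genomes.

# Numerical and design choices

- Distance ties break upstream; gene-assignment ties break
  lexicographically; chromosome order is lexicographic — every output is
  byte-reproducible under a fixed seed.
- Windows running off chromosome ends are clipped, not rejected, matching
  how extension-then-overlap behaves on real genomes.
- Direct overlap of two motif hits means sharing at least one base
  (`w = 0`); co-occupancy of ChIP peak sets is computed on full intervals
  by default, with a window option, since the source does not state which
  was used.
- The Fisher p-value sums hypergeometric probabilities at most
  `(1 + 1e-7)` times the observed table's probability, the classical
  convention, and matches exhaustive enumeration to 1e-12 for margins up
  to 60 (tested).
- The binomial tail is computed by `pbinom`; it matches direct pmf
  summation to 1e-12 for n up to 2000 (tested) and is monotone in x.
- Problem sizes in the test and acceptance runs (1 Mb genomes, 1000 null
  traits of 500 SNPs, 100 enrichment replicates) were chosen so each
  statistical property is measured with comfortable margins while a full
  run stays in the minutes range on one core.

# Known limitations

- Stringency tiers are relative to each matrix's score range; absolute
  hit counts are not comparable across scanners, and the source's
  genome-wide counts are not reproducible without its exact cutoffs.
- The Woolf confidence interval is a large-sample approximation and is
  reported as NA when any cell is zero.
- `partition_pairs()` lets b-sites pair multiply; in extremely dense site
  sets this can inflate phased/unphased region counts relative to a
  one-to-one matching.
- LD expansion trusts the supplied r² table; no LD is computed from
  genotypes.
- The CLI is a thin wrapper (`run_cli()`, `exec/motifcoloc`) over the
  functions documented here; workflow-manager integration is out of
  scope.
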