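# motifcoloc

Genome-wide co-localization analysis for transcription factor binding
sites, in R. The package grew out of the question of whether the coronary
artery disease factor TCF21 and the environmental sensor AHR-ARNT (the
dioxin receptor heterodimer) co-occupy regulatory DNA in vascular smooth
muscle cells — but every stage takes generic inputs (FASTA, JASPAR PFMs,
BED, GWAS-catalog TSV) and is reusable for any pair of factors.

It is aimed at regulatory genomicists who have predicted sites, ChIP-seq
summits or ATAC-seq peaks in hand and want the statistics around them:
where do two site families sit relative to each other, is their overlap
enriched above an open-chromatin background, does their spacing respect
the DNA helical pitch, and do the co-localized loci concentrate GWAS risk
variants.

## What it computes

**Site prediction.** JASPAR count matrices become log-odds scorers
(`lo[b,i] = log2((c[b,i] + pc·bg_b) / (Σ_b c[b,i] + pc) / bg_b)`, bits);
`scan_sequence()` calls sites on both strands at a high (90% of score
range) or low (80%) stringency tier, or at an explicit/bit p-value
threshold.

**Spatial statistics.** Nearest-site distance histograms around oriented
anchors; density metaprofiles normalized so that a uniform site set has
density 1 in every bin (`expected = n_anchors · n_sites · bin / G`);
Fisher exact overlap tests in the "x overlapping; y overlapping within
the background" style with Woolf 95% CIs; Venn-style co-occupancy counts
for 2–3 ChIP peak sets.

**Rotational phasing.** A pair of sites at center distance `d` with
`r = d mod 10` is *phased* when `min(r, 10−r) ≤ tol` (same face of the
double helix — spacings 10, 20, 30, 40 bp — direct protein contact
possible) and *unphased* when `|r−5| ≤ tol` (opposite faces — 5, 15, 25,
35, 45 bp). `partition_pairs()` splits co-localized sites into the two
region sets.

**GWAS enrichment.** Per trait: `x` = SNPs inside the (window-extended,
merged) regions, `n` = trait SNPs, `p` = mappable fraction of the genome
covered by the regions; p-value = binomial upper tail `P(X ≥ x)`,
fold = `x/(np)`, window sweep ±1/2/5/10 kb, LD expansion at `r² > 0.8`,
and a two-proportion z-test for comparing families of sites.

**Proteomics clustering.** Pearson correlation (pairwise-complete,
Bonferroni-corrected p), dissimilarity `D = 1 − |r|`, agglomerative
clustering with Newick export.

**Synthetic data.** A seeded generator plants motif pairs at controlled
spacings, jittered summits, trait SNP sets with a planted in-region
fraction, mappability masks and block-correlated expression matrices,
each with a truth table — the whole pipeline runs and is tested without
any downloads.

## Worked example

Simulate a 1 Mb genome with 200 phased + 200 unphased planted pairs, scan
it, classify the pairs, and test a planted GWAS trait against nine nulls:

```r
library(motifcoloc)

cfg     <- sim_config(seed = 42)
planted <- plant_motif_pairs(make_genome(cfg), cfg)
motifs  <- bundled_motifs()          # DRE (MA0006.1) + synthetic E-box
hits_a  <- scan_sequence(planted$genome, motifs[[1]], stringency = "high")
hits_b  <- scan_sequence(planted$genome, motifs[[2]], stringency = "high")

pairs <- partition_pairs(hits_a, hits_b, max_d = 45, tolerance = 1)
table(pairs$pairs$phase_class)
#>       phased     unphased unclassified
#>          209          204           15
evaluate_phasing_recovery(planted$truth, pairs$pairs)
#> [1] 1
```

All 400 planted pairs are recovered with the correct phase class; the
handful of extra pairs come from chance motif matches in the background
sequence. The unphased pair regions then serve as target regions for SNP
enrichment:

```r
genome  <- genome_lengths(planted$genome)
map     <- uniform_mappability(genome)
regions <- extend_regions(pairs$unphased, 200)
gw      <- make_gwas(cfg, regions, genome, map)   # one planted trait, f = 0.3
res     <- binomial_enrichment(regions, gw$catalog, map, w = 0)
head(res, 3)
#>     trait window  x   n      p fold  p_value  q_value
#> 1 planted      0 38 100 0.0879 4.32 1.66e-15 1.66e-14
#> 2 null_02      0 14 100 0.0879 1.59 5.51e-02 2.75e-01
#> 3 null_09      0 10 100 0.0879 1.14 3.84e-01 8.82e-01
```

The planted trait (30 of its 100 SNPs forced into the regions, the rest
uniform) is the clear winner: 38 SNPs observed in regions covering 8.8%
of the genome, a 4.3-fold excess. Comparing two site families' per-mil
overlap rates with risk loci uses the z-test:

```r
z <- ztest_proportions(456, round(456 / 0.00038), 7, round(7 / 0.00012))
#> z = 3.20, p = 0.0014
```

A command-line front end wraps the same functions:

```sh
exec/motifcoloc all --seed 42 --out run42/   # simulate -> scan -> coloc ->
                                             # phase -> enrich -> cluster
```

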