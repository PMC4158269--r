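# darkislands

Most genes in prokaryotic pangenomes belong to the "cloud" of rare,
narrowly distributed families, and the bulk of that cloud — ORFans and small
uncharacterized ortholog families — is genomic dark matter: rarely studied,
yet enriched in mobile elements, defense systems, and membrane/secretory
machinery. `darkislands` implements a complete pipeline for mining this dark
matter in archaeal (or any prokaryotic) genome collections:

1. **Flagging.** From ortholog-family (arCOG-style) assignments, a gene is
   *dark matter* iff it is an ORFan, or its family occurs in at most
   `max_spread = 5` genomes and is annotated `uncharacterized` or
   `virus_related`. Everything else is the negative set.
2. **Island detection.** Sliding a window of *w* = 5 consecutive genes along
   each replicon, every window with ≥ 4 dark genes is an *island seed*;
   overlapping seeds (sharing ≥ 1 gene) are merged into *dark-matter
   islands*. A *large-island* variant slides *w* = 20 windows tolerating ≤ 5
   negative-set genes, targeting integrated proviruses.
3. **Characterization.** Per-genome island fractions; protein-feature
   statistics (transmembrane, signal-peptide, low-complexity fractions)
   against length-matched background samples; thermophile vs mesophile
   contrasts via Pearson χ² on 2×2 tables and Welch *t* on log protein
   lengths; Parzen (Gaussian-kernel) length densities; mapping of known
   virus/plasmid labels and cross-mapping against defense islands.
4. **Integrated-element boundaries.** Maximal perfect direct repeats
   (k-mer anchoring + ungapped extension, exact contract) are called as
   attachment sites (attL/attR) when one copy overlaps a tRNA gene and/or
   lies adjacent to an integrase gene — the canonical signature of
   site-specific integration — optionally scanning for split-integrase
   fragments at the element termini.
5. **Synthetic pangenomes.** A seeded generator emits multi-genome gene and
   family tables with core/shell/cloud spread structure, planted dark
   islands, feature enrichments, lifestyle contrasts and att-site-flanked
   elements — together with the exact planted truth, so every stage of the
   pipeline is testable without external data.

## Worked example

```r
library(darkislands)

sim   <- generate_pangenome(generator_config(n_genomes = 10,
                                             genes_per_genome = 500,
                                             seed = 42))
flags <- flag_dark_matter(sim$genes, sim$families)
genes <- sim$genes; genes$is_dark <- flags$is_dark
isl   <- find_islands(genes)            # 5-gene windows, >= 4 dark, merged
head(isl[, c("island_id", "first_index", "last_index", "n_genes", "n_dark")], 4)
#>            island_id first_index last_index n_genes n_dark
#> 1 small_G001_chr_120         120        129      10      8
#> 2 small_G001_chr_144         144        153      10      8
#> 3 small_G001_chr_225         225        235      11      9
#> 4 small_G002_chr_140         140        149      10      8

head(genome_island_fraction(isl, genes), 3)
#>   genome_id n_genes n_island_genes fraction
#> 1      G001     500             31    0.062
#> 2      G002     500             30    0.060
#> 3      G003     500             30    0.060

feature_summary(genes[genes$is_dark, ], "dark")
#> Feature summary 'dark': 488 genes | TM 26.0% | signal 2.9% |
#>   low-complexity 10.0% | median length 124 codons
```

488 of 5000 genes are flagged dark (the 5% background plus three planted
8-gene islands per genome); every planted island is recovered, each padded
by the window rule to ~10 genes, so ~6% of each genome sits in islands. The
dark set shows the configured transmembrane enrichment (≈26% here vs the
18% background at this sample size).

Element-boundary calling on a replicon carrying a planted 9.5-kb element
flanked by 55-nt att repeats, with the proximal repeat overlapping a tRNA
gene:

```r
att   <- simulate_att_replicon(replicon_length = 12000,
                               element_length = 9500, repeat_length = 55,
                               seed = 1)
call_elements(att$sequence, att$genes)[, c("span_start", "span_end",
                                           "length", "evidence")]
#>   span_start span_end length                        evidence
#> 1        261     9760     55 trna_overlap,integrase_adjacent
```

A thin CLI wrapping the same functions is installed at `exec/darkislands`
(subcommands `simulate`, `flag`, `islands`, `attscan`).

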