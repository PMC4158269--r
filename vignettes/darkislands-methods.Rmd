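---
title: "Dark-matter islands and integrated elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-matter islands and integrated elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkislands)
```

## The problem

In prokaryotic pangenomes, gene families split into a near-universal *core*,
a broad *shell*, and a *cloud* of rare families and singletons (ORFans).
The uncharacterized part of the cloud — the genomic dark matter — is
disproportionately composed of mobile elements (integrated viruses,
plasmids, transposons), antivirus defense systems, and fast-evolving
membrane/secretory machinery. Because such genes cluster physically,
scanning genomes for *runs* of dark-matter genes is far more informative
than looking at genes one by one: islands concentrate the signal and buffer
against spurious ORF calls. This package turns that idea into a reusable,
fully testable pipeline.

## The flagging rule

Given per-gene family assignments and per-family annotation classes, a gene
is flagged dark iff

* it has no family (ORFan), or
* its family's **genome spread** (number of distinct genomes with at least
  one member) is at most `max_spread` **and** the family's class is
  `uncharacterized` or `virus_related`.

`max_spread` defaults to 5 genomes. Spread is counted over genomes (not
replicons) and over the full input census, not a nonredundant species
subset; the nonredundant subset (`nonredundant_species_set()`, smallest
`genome_id` per species, deterministic) is applied only to group-level
comparisons, where multiply sequenced species would otherwise bias the
contrast. The rarity threshold is applied uniformly to virus-related
families; no length or pseudogene filter is applied at the flagging stage.
Flags form a partition (exactly one reason per gene), and the rule is
monotone in `max_spread`, both of which are enforced by tests.

## Island detection

Windows are **gene-index based**: `window` consecutive genes in annotation
order, ignoring intergenic distance and strand. Defaults:

| parameter | small islands | large islands | defense islands |
|---|---|---|---|
| window (genes) | 5 | 20 | 10 |
| threshold | ≥ 4 dark | ≥ 15 dark (≤ 5 negatives) | ≥ 3 defense |

Every qualifying window is a seed; seeds sharing at least one gene are
merged (connected components of the overlap graph). Seeds that merely abut
without sharing a gene are **not** merged — the strict reading of
"overlapping" — and, consequently, two islands separated by a single
negative gene stay separate. The large-island rule is implemented as
sliding 20-gene windows with at most 5 negative genes, then the same merge;
"at least 20 genes" holds by construction. Whether the original procedure
slid or grew its windows is not determinable from its description, so both
`window` and `max_negative` are exposed as parameters. Replicons shorter
than the window yield no seeds (no shrunken windows), islands never span
replicon boundaries, and plasmid partitions are scanned exactly like
chromosomes. Defense islands reuse the identical machinery on the
`is_defense` flag; their default parameters are package configuration
values, not derived from the dark-matter rule.

Circular replicons are treated as linear by default; `circular = TRUE`
enables wrap-around windows and neighborhoods (a wrapped island reports
`last_index` past `n - 1`, to be read modulo `n`).

## Feature statistics

* **Fractions.** `frac_tm` is the fraction of proteins with ≥ 1 predicted
  transmembrane segment; `frac_signal` by default counts signal peptides
  only on non-membrane proteins (`n_tm == 0`), since an N-terminal TM
  segment and a signal peptide are confounded predictions.
* **Length-matched background.** Protein lengths are binned at
  `bin_width = 20` codons and the background is resampled (with
  replacement) to match the target's bin counts exactly; an unfillable bin
  borrows from the nearest non-empty pool bin. The bin width trades
  matching resolution against per-bin pool depth; 20 codons is fine enough
  that residual length confounding is below the feature-rate differences of
  interest. Sampling is pooled across genomes (a per-genome option would be
  a straightforward extension, but pooled matching is what the fraction
  contrasts require).
* **Tests.** Two-proportion contrasts use the Pearson χ² on the 2×2 table,
  df = 1, *without* Yates continuity correction (the counts compared here
  are large; a `correct` flag exists). The statistic is computed in double
  precision from the closed form — the margin products overflow 32-bit
  integers — and an expected-cell < 1 condition sets a `low_expected` flag
  rather than failing. Length contrasts use the Welch (unequal-variance)
  *t*-test on natural-log lengths via `stats::t.test()`, reporting raw
  medians.
* **Density curves.** `kernel_density()` is a direct Parzen sum with the
  Gaussian kernel, evaluated exactly at 512 grid points padded four
  bandwidths beyond the data range (so the trapezoid integral is 1 within
  1e-3). The default bandwidth is Silverman's rule of thumb. The direct sum
  is deliberate: the contract is exact grid-point equality with the
  definition, which FFT-binned estimators cannot provide.
* **Stand-ins.** `naive_tm_caller()` (non-overlapping 19-residue windows
  with mean Kyte–Doolittle hydropathy > 1.6, greedy left-to-right) and
  `naive_lowcomp_caller()` (any 12-residue window below 2.2 bits of Shannon
  entropy) are crude, clearly flagged stand-ins used only when the input
  carries no `n_tm`/`has_lowcomp` annotations; curated predictions always
  take precedence and are never recomputed.

## Direct repeats and element boundaries

`find_direct_repeats()` reports **maximal perfect direct repeats**: two
identical same-strand copies at `pos1 < pos2` such that extending either
end breaks the equality or hits a sequence end. `N` matches nothing,
including `N`. The algorithm k-mer-anchors (`k = min(min_len, 16)`)
candidate pairs and extends them ungapped along their diagonal; anchors
falling inside an already-extended run on the same diagonal are skipped, and
results are deduplicated, so the output is algorithm-independent — the test
suite proves set equality against a quadratic per-diagonal run-length
oracle. Copies that overlap each other (tandems) have negative separation
and are never reported; `min_sep`/`max_sep` (defaults 1 kb / 100 kb)
bracket plausible integrated-element sizes. `min_len` defaults to 15 nt —
the shortest att repeat the pipeline targets — with a hard floor of 8
(anchor seed length). Degenerate bases other than `N` are rejected at load
rather than silently matched.

`call_elements()` keeps repeat pairs with at least one copy overlapping an
annotated tRNA gene and/or within `adjacency = 2000` nt of an annotated
integrase gene — the arrangement site-specific integration produces — and
reports the flanked span (attL start through attR end, 1-based inclusive)
with the evidence recorded. `split_integrase_scan()` checks for
integrase(-fragment) annotations within 1 kb of each terminus
(`none` / `one_end` / `both_ends`), the signature of SSV-like split
integrases. tRNA and integrase identification is annotation-based
(GenBank feature type `tRNA`; case-insensitive "integrase" in `/product`);
no sequence-level gene detection is in scope.

## The synthetic generator

`generator_config()` defaults define the reference study conditions used
throughout the tests: 50 genomes × 2000 genes, background dark rate 0.05,
three planted 8-gene islands per genome, cloud/shell/core mixture
0.55/0.35/0.10 (shaped to the qualitative core–shell–cloud picture, not
fitted to data), TM rates 0.28 (dark) vs 0.18 (background), non-membrane
signal rates 0.03 vs 0.02, island virus/plasmid label rates 0.07/0.13
(summing to the ~20% of island content attributable to known elements),
log-normal protein lengths with background median 119 codons and a
thermophile shift to a 131-codon median, thermophile fraction 0.5. Element
plantings use 55-nt repeats flanking 9.5 kb (and a 15-nt short-repeat
configuration) as the reference geometries.

Design choices that make the truth exactly recoverable:

* Family spreads are **realized by construction** — each family places one
  member gene in each of its chosen genomes — so spreads recomputed from
  the emitted tables equal the planted ones.
* Families created for negative genes that realize a spread ≤ 5 are classed
  `characterized`; rare dark families are `uncharacterized` (or
  `virus_related` at rate 0.1). This is the generator's consistency
  contract: flagging the emitted tables reproduces the planted dark status
  gene for gene.
* Planted repeat copies have their flanking bases forced to differ between
  the two sites (so the maximal repeat length equals the planted length
  exactly) and the repeat is redrawn until it occurs exactly twice in the
  final sequence.
* Background nucleotides are iid uniform ACGT — sufficient for the
  repeat-uniqueness arguments at the planted lengths.
* All randomness flows from the config seed; identical seeds give
  byte-identical files (hash-checked in the tests).

What the generator does **not** emulate: real intergenic structure, codon
or GC bias, paralogs (one member per genome per family), homology between
planted elements, strand-dependent operon structure, or annotation errors.
Passing the recovery tests therefore demonstrates the correctness of the
algorithms under the stated statistical structure, not robustness to the
full messiness of real annotation pipelines.

## Numerical and statistical checks

The suite cross-checks every operation against an independent route:
exhaustive window enumeration (200 random replicons up to 1000 genes, at
(5,4), (5,5) and (20,15)); union-find components for merging (200 random
seed sets); the quadratic diagonal oracle for repeats (100 random sequences
of 0.5–4 kb at `min_len` 8/12/20); planted-element round trips (100 seeded
replicates of the 9.5 kb/55 nt and 2.5 kb/15 nt geometries, exact span and
length equality); the closed-form Pearson statistic on all 2×2 tables with
margins ≤ 50 plus `chisq.test` equality on the margins ≤ 12 sweep; the
textbook Welch formula to 1e-10; and the direct Parzen sum to 1e-12. The
false-seed rate on the default pangenome is compared with the analytic
`Binomial(5, 0.05)` upper-tail probability; because overlapping windows
make seed events positively correlated, the Monte-Carlo standard deviation
is inflated by the window-overlap factor `2w − 1` before applying a 3-SD
band. These problem sizes keep the default test run to a couple of minutes
while leaving each check statistically meaningful.

## Limitations

* Family assignments, feature predictions and element/defense labels are
  *inputs*; the package deliberately computes none of them (beyond the
  flagged stand-ins) and performs no homology searches or clustering.
* The island definitions are annotation-order based; assembly
  fragmentation, mis-ordered contigs, or very gene-sparse regions distort
  windows in ways nucleotide-based methods would not see.
* The repeat finder reports direct repeats only; inverted repeats (and
  hence IS-element terminal repeats) are out of scope, as is attB/attP
  reconstruction.
* Anchoring is purely positional; a spurious repeat that happens to fall in
  an anchor window will be called. On random sequence at the default
  `min_len = 15` this is rare but not impossible; raising `min_len`
  suppresses it exponentially.
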