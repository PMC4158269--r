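#  Dark-matter flagging from family phyletic patterns.
#
#  A gene is "dark matter" iff it is an ORFan (no family assignment) or its
#  family occurs in at most `max_spread` genomes AND is uncharacterized or
#  virus-related. Everything else is the negative set.

#' Flag dark-matter genes
#'
#' Applies the rarity/annotation rule to every gene: ORFans are dark; a gene
#' with a family is dark iff the family's genome spread is at most
#' `max_spread` and its annotation class is `uncharacterized` or
#' `virus_related`. The flag set is a partition — exactly one flag per gene,
#' with a `reason` in `orfan`, `rare_uncharacterized`, `rare_virus_related`,
#' `negative`.
#'
#' @param genes gene table; genes carry their family in a `family_id` column
#'   (`NA` = ORFan), or supply `assignments`.
#' @param families family records with `family_id`, `genome_spread`,
#'   `annotation_class` (see [build_family_records()]).
#' @param max_spread rarity threshold on genome spread (default 5 genomes).
#' @param assignments optional data.frame `gene_id`, `family_id` used when the
#'   gene table has no `family_id` column.
#' @return data.frame `gene_id`, `is_dark`, `reason`.
#' @export
flag_dark_matter <- function(genes, families, max_spread = 5,
                             assignments = NULL) {
  fam <- if (!is.null(genes$family_id)) genes$family_id
         else if (!is.null(assignments))
           assignments$family_id[match(genes$gene_id, assignments$gene_id)]
         else rep(NA_character_, nrow(genes))
  idx <- match(fam, families$family_id)
  dangling <- !is.na(fam) & is.na(idx)
  if (any(dangling))
    .stopf("family_id(s) not present in family records: %s",
           paste(unique(fam[dangling]), collapse = ", "))
  spread <- families$genome_spread[idx]
  class <- families$annotation_class[idx]
  reason <- rep("negative", nrow(genes))
  reason[is.na(fam)] <- "orfan"
  rare <- !is.na(fam) & spread <= max_spread
  reason[rare & class == "uncharacterized"] <- "rare_uncharacterized"
  reason[rare & class == "virus_related"] <- "rare_virus_related"
  data.frame(gene_id = genes$gene_id,
             is_dark = reason != "negative",
             reason = reason, stringsAsFactors = FALSE)
}

#' Commonality spectrum (gene-frequency plot) of family genome spreads
#'
#' Histogram of ortholog families by genome spread — the core/shell/cloud
#' structure of the pangenome. Counts sum to the number of families.
#'
#' @param families family records.
#' @param n_genomes optional genome census; when given, the spread axis covers
#'   `1..n_genomes` with explicit zero counts.
#' @return data.frame `genome_spread`, `n_families`.
#' @export
commonality_spectrum <- function(families, n_genomes = NULL) {
  if (nrow(families) == 0) .stopf("empty family list")
  tab <- table(families$genome_spread)
  spread <- as.integer(names(tab))
  out <- data.frame(genome_spread = spread, n_families = as.integer(tab))
  if (!is.null(n_genomes)) {
    full <- data.frame(genome_spread = seq_len(n_genomes))
    out <- merge(full, out, all.x = TRUE)
    out$n_families[is.na(out$n_families)] <- 0L
  }
  out[order(out$genome_spread), , drop = FALSE]
}
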