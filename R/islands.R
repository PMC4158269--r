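#  Island detection along replicons: sliding gene-index windows, seed merging,
#  per-genome fractions, element/defense cross-mapping, neighborhoods.
#
#  Windows are gene-index based (annotation order); intergenic distance is
#  ignored. Islands never span replicon boundaries. Replicons shorter than the
#  window yield no seeds. first_index/last_index use the 0-based order_index.

.genes_with_flags <- function(genes, flags = NULL, flag_col = "is_dark") {
  if (!is.null(flags)) {
    genes[[flag_col]] <- flags[[flag_col]][match(genes$gene_id, flags$gene_id)]
  }
  if (is.null(genes[[flag_col]]))
    .stopf("no '%s' column; supply `flags` from flag_dark_matter()", flag_col)
  if (anyNA(genes[[flag_col]]))
    .stopf("missing %s flag for %d gene(s)", flag_col, sum(is.na(genes[[flag_col]])))
  genes
}

.replicon_flag_vector <- function(genes, rep_id, flag_col) {
  sel <- genes[genes$replicon_id == rep_id, , drop = FALSE]
  oi <- sel$order_index
  if (anyDuplicated(oi) || !identical(sort(as.integer(oi)), seq_along(oi) - 1L))
    .stopf("replicon '%s': order_index not consecutive 0..n-1 (unordered input)",
           rep_id)
  as.logical(sel[[flag_col]][order(oi)])
}

#' Find island seeds by sliding a gene window along each replicon
#'
#' Marks every window of `window` consecutive genes containing at least
#' `min_dark` flagged genes as an island seed. With the defaults (5-gene
#' windows, >= 4 dark genes) this is the small-island seeding rule; large
#' islands use 20-gene windows tolerating 5 negatives
#' (see [find_large_islands()]).
#'
#' @param genes gene table with an `is_dark` column, or supply `flags`.
#' @param window window size in genes (default 5).
#' @param min_dark minimum flagged genes per window (default 4).
#' @param flags optional data.frame from [flag_dark_matter()].
#' @param circular treat each replicon as circular: windows wrap past the
#'   origin (default linear).
#' @param flag_col name of the logical flag column scanned (default
#'   `"is_dark"`; [detect_defense_islands()] passes `"is_defense"`).
#' @return data.frame `replicon_id`, `first_index`, `last_index`, `dark_count`
#'   (0-based inclusive order_index bounds; in circular mode `last_index` may
#'   exceed `n-1` and is to be read modulo `n`).
#' @export
find_island_seeds <- function(genes, window = 5, min_dark = 4, flags = NULL,
                              circular = FALSE, flag_col = "is_dark") {
  stopifnot(window >= 1, min_dark >= 1, min_dark <= window)
  genes <- .genes_with_flags(genes, flags, flag_col)
  out <- lapply(unique(genes$replicon_id), function(rep_id) {
    x <- .replicon_flag_vector(genes, rep_id, flag_col)
    n <- length(x)
    if (n < window) return(NULL)
    xx <- if (circular && n > window) c(x, x[seq_len(window - 1L)]) else x
    cs <- cumsum(c(0L, as.integer(xx)))
    n_win <- length(xx) - window + 1L
    counts <- cs[(window + 1L):(n_win + window)] - cs[seq_len(n_win)]
    hit <- which(counts >= min_dark)
    if (length(hit) == 0) return(NULL)
    data.frame(replicon_id = rep_id,
               first_index = hit - 1L,
               last_index = hit + window - 2L,
               dark_count = counts[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(replicon_id = character(), first_index = integer(),
                      last_index = integer(), dark_count = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.island_skeleton <- function() {
  data.frame(island_id = character(), replicon_id = character(),
             first_index = integer(), last_index = integer(),
             n_genes = integer(), n_dark = integer(), variant = character(),
             stringsAsFactors = FALSE)
}

#' Merge overlapping island seeds into islands
#'
#' Islands are the connected components of the seed overlap graph: two seeds
#' belong to the same island iff linked by a chain of seeds sharing at least
#' one gene. Seeds merely abutting (adjacent indices, no shared gene) stay
#' separate. Island span is the union of member seed spans, so islands of one
#' variant are pairwise disjoint on a replicon.
#'
#' @param seeds data.frame from [find_island_seeds()].
#' @param genes optional gene table (with flags merged) used to fill `n_dark`,
#'   nucleotide spans and composition tallies.
#' @param variant `"small"` or `"large"`, recorded on each island.
#' @return island data.frame: `island_id`, `replicon_id`, `first_index`,
#'   `last_index`, `n_genes`, `n_dark`, `variant`, plus `nt_start`, `nt_end`
#'   and composition columns when `genes` is given.
#' @export
merge_seeds <- function(seeds, genes = NULL, variant = "small") {
  if (is.null(seeds) || nrow(seeds) == 0) return(.island_skeleton())
  out <- lapply(unique(seeds$replicon_id), function(rep_id) {
    s <- seeds[seeds$replicon_id == rep_id, , drop = FALSE]
    s <- s[order(s$first_index, s$last_index), , drop = FALSE]
    first <- s$first_index[1L]; last <- s$last_index[1L]
    runs <- list()
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      if (s$first_index[i] <= last) {        # shares >= 1 gene
        last <- max(last, s$last_index[i])
      } else {
        runs[[length(runs) + 1L]] <- c(first, last)
        first <- s$first_index[i]; last <- s$last_index[i]
      }
    }
    runs[[length(runs) + 1L]] <- c(first, last)
    m <- do.call(rbind, runs)
    data.frame(replicon_id = rep_id, first_index = m[, 1], last_index = m[, 2],
               stringsAsFactors = FALSE)
  })
  isl <- do.call(rbind, out)
  isl$n_genes <- isl$last_index - isl$first_index + 1L
  isl$variant <- variant
  isl$island_id <- sprintf("%s_%s_%d", variant, isl$replicon_id, isl$first_index)
  isl$n_dark <- NA_integer_
  if (!is.null(genes)) isl <- .annotate_islands(isl, genes)
  cols <- c("island_id", "replicon_id", "first_index", "last_index",
            "n_genes", "n_dark", "variant")
  isl <- isl[, c(cols, setdiff(names(isl), cols)), drop = FALSE]
  rownames(isl) <- NULL
  isl
}

.annotate_islands <- function(isl, genes) {
  has_dark <- !is.null(genes$is_dark)
  has_coords <- all(c("start", "end") %in% names(genes))
  for (i in seq_len(nrow(isl))) {
    g <- genes[genes$replicon_id == isl$replicon_id[i] &
                 genes$order_index >= isl$first_index[i] &
                 genes$order_index <= isl$last_index[i], , drop = FALSE]
    if (has_dark) isl$n_dark[i] <- sum(g$is_dark)
    if (has_coords) {
      isl$nt_start[i] <- min(g$start)
      isl$nt_end[i] <- max(g$end)
    }
    isl$n_virus[i] <- sum(g$element_label == "virus")
    isl$n_plasmid[i] <- sum(g$element_label %in% c("plasmid", "plasmid_partition"))
    isl$n_defense[i] <- sum(g$is_defense)
    isl$n_tm_genes[i] <- sum(!is.na(g$n_tm) & g$n_tm >= 1)
    isl$n_signal[i] <- sum(g$has_signal %in% TRUE)
    isl$n_lowcomp[i] <- sum(g$has_lowcomp %in% TRUE)
  }
  isl
}

#' Detect small dark-matter islands (seed scan + merge)
#'
#' Convenience wrapper: [find_island_seeds()] then [merge_seeds()].
#'
#' @inheritParams find_island_seeds
#' @return island data.frame (see [merge_seeds()]).
#' @export
find_islands <- function(genes, window = 5, min_dark = 4, flags = NULL,
                         circular = FALSE) {
  genes <- .genes_with_flags(genes, flags)
  seeds <- find_island_seeds(genes, window = window, min_dark = min_dark,
                             circular = circular)
  merge_seeds(seeds, genes = genes, variant = "small")
}

#' Detect large dark-matter islands (20-gene windows, negatives tolerated)
#'
#' Slides `window`-gene windows requiring at least `window - max_negative`
#' dark genes, then merges overlapping windows. With the defaults this flags
#' runs of at least 20 genes with at most 5 negative-set genes per window —
#' the variant expected to capture integrated viruses.
#'
#' @inheritParams find_island_seeds
#' @param max_negative negative-set genes tolerated per window (default 5).
#' @return island data.frame with `variant = "large"`.
#' @export
find_large_islands <- function(genes, window = 20, max_negative = 5,
                               flags = NULL, circular = FALSE) {
  stopifnot(max_negative >= 0, max_negative < window)
  genes <- .genes_with_flags(genes, flags)
  seeds <- find_island_seeds(genes, window = window,
                             min_dark = window - max_negative,
                             circular = circular)
  merge_seeds(seeds, genes = genes, variant = "large")
}

#' Detect defense islands with the same window machinery
#'
#' Applies the identical seed-scan + merge procedure to the `is_defense` flag.
#' The default parameters (10-gene windows, >= 3 defense genes) are package
#' configuration values, not derived from the dark-matter island rule.
#'
#' @inheritParams find_island_seeds
#' @param min_hits minimum defense genes per window (default 3).
#' @return island data.frame with `variant = "defense"`.
#' @export
detect_defense_islands <- function(genes, window = 10, min_hits = 3,
                                   circular = FALSE) {
  if (is.null(genes$is_defense)) .stopf("gene table has no is_defense column")
  seeds <- find_island_seeds(genes, window = window, min_dark = min_hits,
                             circular = circular, flag_col = "is_defense")
  merge_seeds(seeds, genes = genes, variant = "defense")
}

.island_member_ids <- function(islands, genes) {
  if (nrow(islands) == 0) return(character())
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(islands))) {
    hit <- hit | (genes$replicon_id == islands$replicon_id[i] &
                    genes$order_index >= islands$first_index[i] &
                    genes$order_index <= islands$last_index[i])
  }
  genes$gene_id[hit]
}

#' Per-genome fraction of genes inside dark-matter islands
#'
#' @param islands island data.frame (small variant).
#' @param genes gene table for all genomes the islands were computed on.
#' @return data.frame `genome_id`, `n_genes`, `n_island_genes`, `fraction`.
#' @export
genome_island_fraction <- function(islands, genes) {
  if (nrow(genes) == 0) .stopf("empty gene table")
  member <- genes$gene_id %in% .island_member_ids(islands, genes)
  n <- tapply(member, genes$genome_id, length)
  k <- tapply(member, genes$genome_id, sum)
  out <- data.frame(genome_id = names(n), n_genes = as.integer(n),
                    n_island_genes = as.integer(k),
                    fraction = as.numeric(k / n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$genome_id), , drop = FALSE]
}

#' Map known mobile-element labels onto island genes
#'
#' Tallies island gene content by `element_label` per genome and reports the
#' fraction of island genes attributable to known viruses, plasmids, or any
#' element; optionally aggregated by lifestyle group.
#'
#' @param islands island data.frame.
#' @param genes gene table with `element_label` populated (possibly all
#'   `"none"`).
#' @param meta optional genome metadata with `lifestyle` for group-level rows.
#' @return list with `per_genome` (counts + fractions per genome) and
#'   `groups` (one row per group — `all`, and each lifestyle when `meta` is
#'   given — with `frac_virus`, `frac_plasmid`, `frac_element`).
#' @export
map_element_labels <- function(islands, genes, meta = NULL) {
  member_ids <- .island_member_ids(islands, genes)
  g <- genes[genes$gene_id %in% member_ids, , drop = FALSE]
  tally <- function(gg) {
    n <- nrow(gg)
    v <- sum(gg$element_label == "virus")
    p <- sum(gg$element_label %in% c("plasmid", "plasmid_partition"))
    data.frame(n_island_genes = n, n_virus = v, n_plasmid = p,
               n_element = v + p,
               frac_virus = ifelse(n > 0, v / n, 0),
               frac_plasmid = ifelse(n > 0, p / n, 0),
               frac_element = ifelse(n > 0, (v + p) / n, 0))
  }
  per_genome <- do.call(rbind, lapply(split(g, g$genome_id), tally))
  if (is.null(per_genome)) {
    per_genome <- cbind(data.frame(genome_id = character()), tally(g[0, ]))[0, ]
  } else {
    per_genome <- cbind(data.frame(genome_id = rownames(per_genome),
                                   stringsAsFactors = FALSE), per_genome)
  }
  rownames(per_genome) <- NULL
  groups <- cbind(data.frame(group = "all", stringsAsFactors = FALSE), tally(g))
  if (!is.null(meta)) {
    lf <- meta$lifestyle[match(g$genome_id, meta$genome_id)]
    for (grp in intersect(c("thermophile", "mesophile"), unique(lf))) {
      groups <- rbind(groups,
                      cbind(data.frame(group = grp, stringsAsFactors = FALSE),
                            tally(g[!is.na(lf) & lf == grp, , drop = FALSE])))
    }
  }
  list(per_genome = per_genome, groups = groups)
}

#' Cross-map dark-matter islands against defense islands
#'
#' Per-gene set intersection of the two island systems: reports the fraction
#' of dark-island genes lying inside defense islands, how many of the overlap
#' genes carry virus/plasmid labels, and the count of defense-island genes
#' outside any virus/plasmid-labeled region (candidate novel defense genes).
#'
#' @param dark_islands,defense_islands island data.frames on the same gene
#'   tables.
#' @param genes the shared gene table.
#' @return list: `n_dark_island_genes`, `n_overlap`, `overlap_fraction`,
#'   `n_overlap_virus`, `n_overlap_plasmid`, `n_defense_outside_elements`.
#' @export
cross_map_defense <- function(dark_islands, defense_islands, genes) {
  dark_ids <- .island_member_ids(dark_islands, genes)
  def_ids <- .island_member_ids(defense_islands, genes)
  both <- intersect(dark_ids, def_ids)
  g_both <- genes[genes$gene_id %in% both, , drop = FALSE]
  g_def <- genes[genes$gene_id %in% def_ids, , drop = FALSE]
  list(n_dark_island_genes = length(dark_ids),
       n_overlap = length(both),
       overlap_fraction = if (length(dark_ids) > 0)
         length(both) / length(dark_ids) else 0,
       n_overlap_virus = sum(g_both$element_label == "virus"),
       n_overlap_plasmid = sum(g_both$element_label %in%
                                 c("plasmid", "plasmid_partition")),
       n_defense_outside_elements = sum(g_def$element_label == "none"))
}

#' Extract the gene neighborhood around a focus gene
#'
#' Up to `k` genes on each side of the focus on the same replicon, in genomic
#' order; truncated at replicon ends in linear mode, wrapping (without
#' duplicates) in circular mode.
#'
#' @param genes gene table.
#' @param gene_id focus gene.
#' @param k neighbors per side (default 10).
#' @param circular wrap around the replicon origin.
#' @return gene table rows for the neighborhood, focus included, ordered along
#'   the replicon (wrapped order in circular mode).
#' @export
extract_neighborhood <- function(genes, gene_id, k = 10, circular = FALSE) {
  row <- which(genes$gene_id == gene_id)
  if (length(row) == 0) .stopf("unknown gene_id '%s'", gene_id)
  row <- row[1L]
  rep_id <- genes$replicon_id[row]
  sel <- genes[genes$replicon_id == rep_id, , drop = FALSE]
  sel <- sel[order(sel$order_index), , drop = FALSE]
  n <- nrow(sel)
  pos <- which(sel$gene_id == gene_id)
  if (circular) {
    idx <- unique(((pos - 1 + (-k:k)) %% n) + 1L)
    out <- sel[idx, , drop = FALSE]
  } else {
    out <- sel[max(1L, pos - k):min(n, pos + k), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write an island report to TSV
#'
#' @param islands island data.frame.
#' @param genes gene table used to attach `genome_id`.
#' @param path output TSV path.
#' @param bed optional path for a BED export of the nucleotide spans.
#' @return `path`, invisibly.
#' @export
write_island_report <- function(islands, genes, path, bed = NULL) {
  islands$genome_id <-
    genes$genome_id[match(islands$replicon_id, genes$replicon_id)]
  write.table(islands, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed) && nrow(islands) > 0 && !is.null(islands$nt_start)) {
    spans <- data.frame(replicon_id = islands$replicon_id,
                        nt_start = islands$nt_start, nt_end = islands$nt_end,
                        name = islands$island_id, stringsAsFactors = FALSE)
    write_bed(spans, bed)
  }
  invisible(path)
}
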