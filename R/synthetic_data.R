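#  Synthetic pangenome and replicon-sequence generator with emitted ground
#  truth: planted dark-matter islands, core/shell/cloud family spreads,
#  feature enrichments, lifestyle contrasts, and att-site-flanked integrated
#  elements. Every dataset is reproducible from its seed.

#' Build a generator configuration
#'
#' Defaults encode the study conditions the analysis targets: 50 genomes of
#' 2000 genes, a 5% background dark-gene rate with three planted 8-gene
#' islands per genome, cloud/shell/core spread mixture 0.55/0.35/0.10,
#' transmembrane rates 0.28 (dark) vs 0.18 (background), non-membrane
#' signal-peptide rates 0.03 vs 0.02, protein-length log-normal with
#' background median 119 codons shifted to a 131-codon median in thermophiles
#' (half the genomes).
#'
#' @param n_genomes,genes_per_genome pangenome dimensions.
#' @param spread_mixture named weights (`cloud`, `shell`, `core`, summing
#'   to 1) for family genome-spread sampling: cloud spreads 1-5, shell 6 to
#'   `n_genomes - 1`, core `n_genomes`.
#' @param dark_background_rate per-gene probability of a dark gene outside
#'   planted islands.
#' @param islands_per_genome planted contiguous dark runs per genome.
#' @param island_length genes per planted island (scalar, or a vector sampled
#'   uniformly per island).
#' @param orfan_fraction fraction of dark genes that are ORFans (the rest
#'   join rare families of spread 1-5).
#' @param virus_related_fraction fraction of rare dark families annotated
#'   virus-related rather than uncharacterized.
#' @param tm_rate_dark,tm_rate_background probability of >= 1 transmembrane
#'   segment.
#' @param signal_rate_dark,signal_rate_background unconditional probability of
#'   a non-membrane protein with a signal peptide.
#' @param lowcomp_rate_dark,lowcomp_rate_background low-complexity rates.
#' @param island_virus_rate,island_plasmid_rate probability that an
#'   island gene carries a known virus / plasmid element label (defaults sum
#'   to the ~20% of island content attributable to known elements).
#' @param defense_rate iid per-gene probability of a defense annotation.
#' @param thermophile_fraction fraction of genomes labeled thermophile.
#' @param length_logmean,length_logsd log-normal protein-length parameters
#'   (codons); `exp(length_logmean)` is the background median.
#' @param length_logmean_shift added to `length_logmean` in thermophile
#'   genomes.
#' @param mean_intergenic mean intergenic gap in nt (Poisson).
#' @param element_plantings list of `list(element_length=, repeat_length=)`
#'   integrated elements to plant (requires `emit_sequences`).
#' @param emit_sequences also generate replicon nucleotide sequences.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_genomes = 50, genes_per_genome = 2000,
                             spread_mixture = c(cloud = 0.55, shell = 0.35,
                                                core = 0.10),
                             dark_background_rate = 0.05,
                             islands_per_genome = 3, island_length = 8,
                             orfan_fraction = 0.5,
                             virus_related_fraction = 0.1,
                             tm_rate_dark = 0.28, tm_rate_background = 0.18,
                             signal_rate_dark = 0.03,
                             signal_rate_background = 0.02,
                             lowcomp_rate_dark = 0.10,
                             lowcomp_rate_background = 0.07,
                             island_virus_rate = 0.07,
                             island_plasmid_rate = 0.13,
                             defense_rate = 0,
                             thermophile_fraction = 0.5,
                             length_logmean = log(119), length_logsd = 0.45,
                             length_logmean_shift = log(131 / 119),
                             mean_intergenic = 100,
                             element_plantings = list(),
                             emit_sequences = FALSE,
                             seed = 17) {
  cfg <- as.list(environment())
  rates <- c(cfg$dark_background_rate, cfg$orfan_fraction,
             cfg$virus_related_fraction, cfg$tm_rate_dark,
             cfg$tm_rate_background, cfg$signal_rate_dark,
             cfg$signal_rate_background, cfg$lowcomp_rate_dark,
             cfg$lowcomp_rate_background, cfg$island_virus_rate,
             cfg$island_plasmid_rate, cfg$defense_rate,
             cfg$thermophile_fraction)
  if (any(rates < 0 | rates > 1)) .stopf("all rates must lie in [0,1]")
  if (abs(sum(spread_mixture) - 1) > 1e-8)
    .stopf("spread_mixture weights must sum to 1")
  if (max(island_length) * islands_per_genome * 2 > genes_per_genome)
    .stopf("island demands exceed genome size")
  class(cfg) <- "generator_config"
  cfg
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# k non-overlapping runs of lengths len in 1..m with >= buffer genes between
.place_runs <- function(m, k, len, buffer = 5) {
  if (k == 0) return(integer(0))
  for (try in 1:1000) {
    starts <- sort(sample.int(m - max(len) + 1L, k))
    ends <- starts + len - 1L
    if (k == 1 || all(starts[-1] - ends[-k] > buffer)) return(starts)
  }
  .stopf("could not place %d runs of length %d in %d genes", k, max(len), m)
}

#' Generate a synthetic multi-genome pangenome with ground truth
#'
#' Draws per-genome gene tables, ortholog-family assignments with a realized
#' core/shell/cloud spread structure, protein features enriched in dark
#' genes, lifestyle groups with a log-length shift, and contiguous planted
#' dark-gene islands; emits the exact planted truth alongside. Family genome
#' spreads are realized by construction (one member gene per chosen genome),
#' so spreads recomputed from the emitted tables equal the planted ones and
#' dark-matter flagging recovers the truth exactly.
#'
#' @param config a [generator_config()].
#' @return list of class `dm_pangenome`: `genes` (validated gene table with a
#'   `family_id` column), `assignments`, `families`, `meta` (genome metadata),
#'   `truth` (`islands`, `dark`, `elements`, `rates`), `sequences` (named
#'   character, when `emit_sequences`), and `config`.
#' @export
generate_pangenome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, .generate_pangenome_impl(config))
}

.generate_pangenome_impl <- function(cfg) {
  n_g <- cfg$n_genomes; m <- cfg$genes_per_genome
  genome_ids <- sprintf("G%03d", seq_len(n_g))
  lifestyles <- ifelse(seq_len(n_g) %in%
                         sample.int(n_g, round(n_g * cfg$thermophile_fraction)),
                       "thermophile", "mesophile")
  meta <- data.frame(genome_id = genome_ids,
                     species_name = sprintf("Species %03d", seq_len(n_g)),
                     lifestyle = lifestyles, stringsAsFactors = FALSE)

  # --- dark truth and island planting -------------------------------------
  dark <- vector("list", n_g)
  island_rows <- list()
  for (gi in seq_len(n_g)) {
    lens <- if (length(cfg$island_length) == 1)
      rep(cfg$island_length, cfg$islands_per_genome)
    else sample(cfg$island_length, cfg$islands_per_genome, replace = TRUE)
    starts <- .place_runs(m, cfg$islands_per_genome, lens)
    is_dark <- runif(m) < cfg$dark_background_rate
    for (j in seq_along(starts)) {
      is_dark[starts[j]:(starts[j] + lens[j] - 1L)] <- TRUE
      island_rows[[length(island_rows) + 1L]] <-
        data.frame(genome_id = genome_ids[gi],
                   replicon_id = paste0(genome_ids[gi], "_chr"),
                   first_index = starts[j] - 1L,
                   last_index = starts[j] + lens[j] - 2L,
                   n_genes = lens[j], stringsAsFactors = FALSE)
    }
    dark[[gi]] <- is_dark
  }
  truth_islands <- do.call(rbind, island_rows)
  if (is.null(truth_islands))
    truth_islands <- data.frame(genome_id = character(),
                                replicon_id = character(),
                                first_index = integer(), last_index = integer(),
                                n_genes = integer(), stringsAsFactors = FALSE)

  # --- family assignment ---------------------------------------------------
  # dark genes: ORFans or rare (spread <= 5) uncharacterized/virus families;
  # negative genes: mixture families, class "characterized" whenever the
  # realized spread is <= 5 so the emitted tables reproduce the truth exactly.
  fam_of <- lapply(seq_len(n_g), function(gi) rep(NA_character_, m))
  fam_id <- 0L
  fam_records <- list()
  new_family <- function(members, class) {
    fam_id <<- fam_id + 1L
    id <- sprintf("FAM%05d", fam_id)
    fam_records[[fam_id]] <<- data.frame(family_id = id,
                                         genome_spread = length(members),
                                         annotation_class = class,
                                         stringsAsFactors = FALSE)
    id
  }
  dark_slots <- lapply(seq_len(n_g), function(gi) {
    idx <- which(dark[[gi]])
    idx[runif(length(idx)) >= cfg$orfan_fraction]   # non-ORFan dark genes
  })
  rem <- lengths(dark_slots)
  while (sum(rem) > 0) {
    avail <- which(rem > 0)
    s <- min(sample.int(5L, 1L), length(avail))
    gs <- if (length(avail) == 1) avail else sample(avail, s)
    class <- if (runif(1) < cfg$virus_related_fraction) "virus_related"
             else "uncharacterized"
    id <- new_family(gs, class)
    for (gi in gs) {
      slot <- dark_slots[[gi]][rem[gi]]
      fam_of[[gi]][slot] <- id
      rem[gi] <- rem[gi] - 1L
    }
  }
  neg_slots <- lapply(seq_len(n_g), function(gi) {
    idx <- which(!dark[[gi]])
    sample(idx)                                     # random placement order
  })
  rem <- lengths(neg_slots)
  mix <- cfg$spread_mixture
  while (sum(rem) > 0) {
    avail <- which(rem > 0)
    comp <- sample(names(mix), 1L, prob = mix)
    s_target <- switch(comp,
                       cloud = sample.int(min(5L, n_g), 1L),
                       shell = if (n_g >= 7)
                         sample(6:(n_g - 1L), 1L) else n_g,
                       core = n_g)
    s <- min(s_target, length(avail))
    gs <- if (length(avail) == 1) avail else sample(avail, s)
    class <- if (s <= 5) "characterized"
             else sample(c("characterized", "uncharacterized"), 1L)
    id <- new_family(gs, class)
    for (gi in gs) {
      slot <- neg_slots[[gi]][rem[gi]]
      fam_of[[gi]][slot] <- id
      rem[gi] <- rem[gi] - 1L
    }
  }
  families <- do.call(rbind, fam_records)

  # --- per-gene records ----------------------------------------------------
  tables <- vector("list", n_g)
  for (gi in seq_len(n_g)) {
    is_dark <- dark[[gi]]
    shift <- if (lifestyles[gi] == "thermophile") cfg$length_logmean_shift else 0
    plen <- pmax(30L, as.integer(round(rlnorm(m, cfg$length_logmean + shift,
                                              cfg$length_logsd))))
    gaps <- rpois(m, cfg$mean_intergenic)
    nt_len <- plen * 3L + 3L
    start <- cumsum(c(1L, head(nt_len + gaps, -1L)))
    tm_rate <- ifelse(is_dark, cfg$tm_rate_dark, cfg$tm_rate_background)
    has_tm <- runif(m) < tm_rate
    n_tm <- ifelse(has_tm, 1L + rpois(m, 0.7), 0L)
    sig_rate <- ifelse(is_dark, cfg$signal_rate_dark,
                       cfg$signal_rate_background)
    p_sig <- pmin(1, sig_rate / pmax(1e-12, 1 - tm_rate))
    has_signal <- !has_tm & runif(m) < p_sig
    lc_rate <- ifelse(is_dark, cfg$lowcomp_rate_dark,
                      cfg$lowcomp_rate_background)
    has_lowcomp <- runif(m) < lc_rate
    in_island <- rep(FALSE, m)
    tisl <- truth_islands[truth_islands$genome_id == genome_ids[gi], ,
                          drop = FALSE]
    for (j in seq_len(nrow(tisl)))
      in_island[(tisl$first_index[j] + 1L):(tisl$last_index[j] + 1L)] <- TRUE
    u <- runif(m)
    element_label <- rep("none", m)
    element_label[in_island & u < cfg$island_virus_rate] <- "virus"
    element_label[in_island & u >= cfg$island_virus_rate &
                    u < cfg$island_virus_rate + cfg$island_plasmid_rate] <-
      "plasmid"
    tables[[gi]] <- data.frame(
      gene_id = sprintf("%s_g%05d", genome_ids[gi], seq_len(m)),
      genome_id = genome_ids[gi],
      replicon_id = paste0(genome_ids[gi], "_chr"),
      order_index = seq_len(m) - 1L,
      start = start, end = start + nt_len - 1L,
      strand = sample(c("+", "-"), m, replace = TRUE),
      protein_length = plen, family_id = fam_of[[gi]],
      n_tm = n_tm, has_signal = has_signal, has_lowcomp = has_lowcomp,
      element_label = element_label,
      is_defense = runif(m) < cfg$defense_rate,
      is_trna = FALSE, is_integrase = FALSE,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, tables)
  rownames(genes) <- NULL

  truth_dark <- data.frame(gene_id = genes$gene_id,
                           true_dark = unlist(dark), stringsAsFactors = FALSE)
  assignments <- genes[!is.na(genes$family_id), c("gene_id", "family_id")]
  rownames(assignments) <- NULL

  sequences <- NULL
  truth_elements <- data.frame(replicon_id = character(), pos1 = integer(),
                               pos2 = integer(), repeat_length = integer(),
                               span_start = integer(), span_end = integer(),
                               trna_gene = character(),
                               integrase_gene = character(),
                               stringsAsFactors = FALSE)
  if (cfg$emit_sequences) {
    sequences <- character(0)
    for (gi in seq_len(n_g)) {
      rep_id <- paste0(genome_ids[gi], "_chr")
      g <- genes[genes$replicon_id == rep_id, , drop = FALSE]
      sequences[rep_id] <- .random_dna(max(g$end) + 100L)
    }
    for (pi in seq_along(cfg$element_plantings)) {
      pl <- cfg$element_plantings[[pi]]
      gi <- ((pi - 1L) %% n_g) + 1L
      rep_id <- paste0(genome_ids[gi], "_chr")
      g_idx <- which(genes$replicon_id == rep_id)
      # anchor on an existing gene, recycled as a tRNA annotation
      anchor <- g_idx[which.min(abs(genes$start[g_idx] - 1000L))]
      genes$is_trna[anchor] <- TRUE
      planted <- plant_element(sequences[[rep_id]],
                               trna_start = genes$start[anchor],
                               trna_end = genes$end[anchor],
                               element_length = pl$element_length,
                               repeat_length = pl$repeat_length)
      sequences[rep_id] <- planted$sequence
      # nearest gene to the distal copy becomes the integrase annotation
      gap <- .interval_gap(planted$truth$pos2,
                           planted$truth$pos2 + pl$repeat_length - 1L,
                           genes$start[g_idx], genes$end[g_idx])
      intg <- g_idx[which.min(gap)]
      genes$is_integrase[intg] <- TRUE
      truth_elements <- rbind(truth_elements, data.frame(
        replicon_id = rep_id, pos1 = planted$truth$pos1,
        pos2 = planted$truth$pos2, repeat_length = pl$repeat_length,
        span_start = planted$truth$span[1], span_end = planted$truth$span[2],
        trna_gene = genes$gene_id[anchor],
        integrase_gene = genes$gene_id[intg], stringsAsFactors = FALSE))
    }
  }

  genes <- as_gene_table(genes)
  out <- list(genes = genes, assignments = assignments, families = families,
              meta = meta,
              truth = list(islands = truth_islands, dark = truth_dark,
                           elements = truth_elements,
                           rates = cfg[c("dark_background_rate",
                                         "tm_rate_dark", "tm_rate_background",
                                         "signal_rate_dark",
                                         "signal_rate_background",
                                         "island_virus_rate",
                                         "island_plasmid_rate")]),
              sequences = sequences, config = cfg)
  class(out) <- "dm_pangenome"
  out
}

#' @export
print.dm_pangenome <- function(x, ...) {
  cat(sprintf(
    "Synthetic pangenome: %d genomes x %d genes | %d families | %d planted islands | %d planted elements | seed %d\n",
    x$config$n_genomes, x$config$genes_per_genome, nrow(x$families),
    nrow(x$truth$islands), nrow(x$truth$elements), x$config$seed))
  invisible(x)
}

#' Plant an att-site-flanked integrated element into a sequence
#'
#' Overwrites two identical repeat copies (freshly drawn random sequence of
#' `repeat_length` nt) into the draft sequence: the proximal copy overlapping
#' the 3' end of the given tRNA gene, the distal copy placed so the flanked
#' span (attL start through attR end) is exactly `element_length` nt. The
#' bases immediately flanking the copies are forced to differ between the two
#' sites so the planted repeat is maximal at exactly `repeat_length`, and the
#' repeat is redrawn (up to `max_tries`) until it occurs exactly twice in the
#' final sequence.
#'
#' @param sequence draft replicon sequence (1-based coordinates).
#' @param trna_start,trna_end tRNA gene coordinates; the proximal copy
#'   overlaps the 3' end.
#' @param element_length flanked-span length in nt (attL through attR).
#' @param repeat_length att-repeat length in nt (>= 8).
#' @param seed optional integer seed.
#' @param max_tries resampling attempts before giving up.
#' @return list with `sequence` (same length as input) and `truth`
#'   (`pos1`, `pos2`, `repeat_length`, `span`, `separation`).
#' @export
plant_element <- function(sequence, trna_start, trna_end, element_length,
                          repeat_length, seed = NULL, max_tries = 100) {
  run <- function() .plant_element_impl(sequence, trna_start, trna_end,
                                        element_length, repeat_length,
                                        max_tries)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.plant_element_impl <- function(sequence, trna_start, trna_end,
                                element_length, repeat_length, max_tries) {
  n <- nchar(sequence)
  if (repeat_length < 8) .stopf("repeat_length must be >= 8")
  if (element_length < 2 * repeat_length + 1)
    .stopf("element_length too small for two non-overlapping repeat copies")
  overlap <- min(repeat_length, trna_end - trna_start + 1L, 15L)
  pos1 <- trna_end - overlap + 1L
  pos2 <- pos1 + element_length - repeat_length
  if (pos1 < 2L || pos2 + repeat_length > n)
    .stopf("element span %d..%d does not fit in sequence of length %d",
           pos1, pos2 + repeat_length - 1L, n)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    rep_seq <- sample(bases, repeat_length, replace = TRUE)
    cand <- chars
    cand[pos1:(pos1 + repeat_length - 1L)] <- rep_seq
    cand[pos2:(pos2 + repeat_length - 1L)] <- rep_seq
    # force maximality: flanking bases must differ between the two copies
    if (cand[pos1 - 1L] == cand[pos2 - 1L])
      cand[pos2 - 1L] <- sample(setdiff(bases, cand[pos1 - 1L]), 1L)
    e1 <- pos1 + repeat_length; e2 <- pos2 + repeat_length
    if (e2 <= n && cand[e1] == cand[e2])
      cand[e2] <- sample(setdiff(bases, cand[e1]), 1L)
    s <- paste(cand, collapse = "")
    hits <- gregexpr(paste(rep_seq, collapse = ""), s, fixed = TRUE)[[1]]
    if (length(hits) == 2 && all(hits == c(pos1, pos2))) {
      return(list(sequence = s,
                  truth = list(pos1 = pos1, pos2 = pos2,
                               repeat_length = repeat_length,
                               span = c(pos1, pos2 + repeat_length - 1L),
                               separation = pos2 - pos1 - repeat_length)))
    }
  }
  .stopf("could not place a unique repeat after %d attempts", max_tries)
}

#' Simulate a replicon with planted att-site-flanked elements
#'
#' Builds a random replicon plus a minimal gene annotation (one tRNA gene per
#' planting, one integrase gene inside each element adjacent to the distal
#' repeat copy, optionally split-integrase fragments at both termini) and
#' plants each element with [plant_element()]. This is the fixture for the
#' element-caller round trip: [call_elements()] on the output recovers the
#' recorded truth.
#'
#' @param replicon_length total sequence length in nt.
#' @param element_length,repeat_length planted element geometry (recycled
#'   across `n_plantings`).
#' @param n_plantings number of independent elements, placed in disjoint
#'   blocks of the replicon.
#' @param split_integrase also annotate an integrase fragment near the
#'   proximal terminus (the split-gene arrangement).
#' @param genome_id,replicon_id identifiers stamped on the annotation.
#' @param seed integer seed.
#' @return list: `sequence`, `genes` (validated gene table), `truth`
#'   (data.frame, one row per planting: repeat positions, span, anchors).
#' @export
simulate_att_replicon <- function(replicon_length = 20000,
                                  element_length = 9500, repeat_length = 55,
                                  n_plantings = 1, split_integrase = FALSE,
                                  genome_id = "synthG1",
                                  replicon_id = "synthR1", seed = 1) {
  el <- rep_len(element_length, n_plantings)
  rl <- rep_len(repeat_length, n_plantings)
  withr::with_seed(seed, {
    block <- replicon_length %/% n_plantings
    if (any(el + 500 > block))
      .stopf("replicon too short for %d planting(s) of %d nt", n_plantings,
             max(el))
    sequence <- .random_dna(replicon_length)
    gene_rows <- list()
    truth <- list()
    for (i in seq_len(n_plantings)) {
      base <- (i - 1L) * block
      trna_start <- base + 201L
      trna_end <- trna_start + 74L
      planted <- plant_element(sequence, trna_start, trna_end, el[i], rl[i])
      sequence <- planted$sequence
      pos2 <- planted$truth$pos2
      int_start <- pos2 - 800L; int_end <- pos2 - 201L
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("trna_%d", i), genome_id = genome_id,
        replicon_id = replicon_id, start = trna_start, end = trna_end,
        strand = "+", protein_length = 25L, is_trna = TRUE,
        is_integrase = FALSE, stringsAsFactors = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("int_%d", i), genome_id = genome_id,
        replicon_id = replicon_id, start = int_start, end = int_end,
        strand = "+", protein_length = 200L, is_trna = FALSE,
        is_integrase = TRUE, stringsAsFactors = FALSE)
      if (split_integrase) {
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = sprintf("intN_%d", i), genome_id = genome_id,
          replicon_id = replicon_id, start = planted$truth$pos1 + 101L,
          end = planted$truth$pos1 + 400L, strand = "+",
          protein_length = 100L, is_trna = FALSE, is_integrase = TRUE,
          stringsAsFactors = FALSE)
      }
      truth[[i]] <- data.frame(
        replicon_id = replicon_id, pos1 = planted$truth$pos1, pos2 = pos2,
        repeat_length = rl[i], span_start = planted$truth$span[1],
        span_end = planted$truth$span[2], trna_gene = sprintf("trna_%d", i),
        integrase_gene = sprintf("int_%d", i), stringsAsFactors = FALSE)
    }
    list(sequence = sequence, genes = as_gene_table(do.call(rbind, gene_rows)),
         truth = do.call(rbind, truth))
  })
}

#' Write a synthetic pangenome to a directory
#'
#' Emits `genes.tsv`, `assignments.tsv`, `families.tsv`, `meta.tsv`,
#' truth tables (`truth_islands.tsv`, `truth_dark.tsv`,
#' `truth_elements.tsv`) and, when sequences were generated,
#' `replicons.fasta`.
#'
#' @param sim a `dm_pangenome` from [generate_pangenome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir) {
  stopifnot(inherits(sim, "dm_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE, na = "")
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  tsv(sim$assignments, "assignments.tsv")
  tsv(sim$families, "families.tsv")
  tsv(sim$meta, "meta.tsv")
  tsv(sim$truth$islands, "truth_islands.tsv")
  tsv(sim$truth$dark, "truth_dark.tsv")
  tsv(sim$truth$elements, "truth_elements.tsv")
  if (!is.null(sim$sequences)) {
    ss <- Biostrings::DNAStringSet(sim$sequences)
    Biostrings::writeXStringSet(ss, file.path(dir, "replicons.fasta"))
  }
  invisible(dir)
}
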