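#  Gene / family / sequence input-output and the tabular data model.
#
#  Coordinates are 1-based inclusive throughout (GenBank convention); BED
#  export converts to 0-based half-open. order_index is the 0-based rank of a
#  gene along its replicon in genomic order, strand-agnostic.

GENE_REQUIRED_COLS <- c("gene_id", "genome_id", "replicon_id")
GENE_OPTIONAL_COLS <- c("order_index", "start", "end", "strand", "protein_length",
                        "n_tm", "has_signal", "has_lowcomp", "element_label",
                        "is_defense", "is_trna", "is_integrase")
ELEMENT_LABELS <- c("none", "virus", "plasmid", "plasmid_partition")
ANNOTATION_CLASSES <- c("uncharacterized", "virus_related", "characterized")

#' Default keyword list marking a free-text family annotation as virus-related
#'
#' Case-insensitive substrings applied to free-text annotations when no curated
#' `annotation_class` column is supplied.
#' @export
virus_keywords_default <- function() {
  c("integrase", "transposase", "portal", "capsid", "terminase", "recombinase")
}

#' Validate a gene table against the data-model invariants
#'
#' Checks the invariants every downstream operation relies on: required
#' columns present, `start <= end`, unique `gene_id` per replicon, and
#' `order_index` consecutive `0..n-1` on every replicon.
#'
#' @param genes data.frame as returned by [read_gene_table()].
#' @return `genes`, invisibly, if valid; otherwise an error.
#' @export
validate_gene_table <- function(genes) {
  missing <- setdiff(c(GENE_REQUIRED_COLS, "order_index"), names(genes))
  if (length(missing) > 0)
    .stopf("gene table is missing column(s): %s", paste(missing, collapse = ", "))
  key <- paste(genes$replicon_id, genes$gene_id)
  if (anyDuplicated(key)) {
    dup <- genes$gene_id[duplicated(key)][1L]
    .stopf("duplicate gene_id on a replicon: '%s'", dup)
  }
  if (all(c("start", "end") %in% names(genes))) {
    bad <- which(genes$start > genes$end)
    if (length(bad) > 0)
      .stopf("start > end for gene '%s'", genes$gene_id[bad[1L]])
  }
  for (rep_id in unique(genes$replicon_id)) {
    oi <- sort(genes$order_index[genes$replicon_id == rep_id])
    if (!identical(as.integer(oi), seq_len(length(oi)) - 1L))
      .stopf("order_index on replicon '%s' is not consecutive 0..n-1", rep_id)
  }
  invisible(genes)
}

.fill_gene_defaults <- function(genes) {
  n <- nrow(genes)
  if (is.null(genes$strand)) genes$strand <- rep("+", n)
  if (is.null(genes$protein_length)) {
    if (all(c("start", "end") %in% names(genes))) {
      genes$protein_length <- pmax(1L, (genes$end - genes$start + 1L) %/% 3L)
    } else {
      genes$protein_length <- rep(NA_integer_, n)
    }
  }
  if (is.null(genes$n_tm)) genes$n_tm <- rep(NA_integer_, n)
  if (is.null(genes$has_signal)) genes$has_signal <- rep(NA, n)
  if (is.null(genes$has_lowcomp)) genes$has_lowcomp <- rep(NA, n)
  if (is.null(genes$element_label)) genes$element_label <- rep("none", n)
  if (is.null(genes$is_defense)) genes$is_defense <- rep(FALSE, n)
  if (is.null(genes$is_trna)) genes$is_trna <- rep(FALSE, n)
  if (is.null(genes$is_integrase)) genes$is_integrase <- rep(FALSE, n)
  bad <- setdiff(unique(genes$element_label), ELEMENT_LABELS)
  if (length(bad) > 0)
    .stopf("unknown element_label value(s): %s", paste(bad, collapse = ", "))
  genes
}

#' Read a tab-separated gene table
#'
#' The file must name at least `gene_id`, `genome_id`, `replicon_id` and either
#' an `order_index` column or `start`/`end` coordinates. When `order_index` is
#' absent it is assigned per replicon by ascending `start`. Optional columns
#' (`strand`, `protein_length`, `n_tm`, `has_signal`, `has_lowcomp`,
#' `element_label`, `is_defense`, `is_trna`, `is_integrase`) are filled with
#' neutral defaults when missing; the three protein-feature columns default to
#' `NA` so that "not annotated" is distinguishable from "annotated negative".
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame of gene records, ordered by replicon and `order_index`.
#' @export
read_gene_table <- function(path) {
  genes <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_gene_table(genes)
}

#' Coerce a data.frame to a validated gene table
#'
#' @param genes data.frame with at least the required gene-table columns.
#' @return validated, ordered gene table (see [read_gene_table()]).
#' @export
as_gene_table <- function(genes) {
  missing <- setdiff(GENE_REQUIRED_COLS, names(genes))
  if (length(missing) > 0)
    .stopf("gene table is missing column(s): %s", paste(missing, collapse = ", "))
  has_coords <- all(c("start", "end") %in% names(genes))
  if (!has_coords && is.null(genes$order_index))
    .stopf("gene table needs either an order_index column or start/end coordinates")
  if (has_coords) {
    for (col in c("start", "end")) {
      v <- suppressWarnings(as.numeric(genes[[col]]))
      if (anyNA(v)) .stopf("non-numeric %s coordinate at row %d", col,
                           which(is.na(v))[1L])
      genes[[col]] <- as.integer(v)
    }
  }
  if (is.null(genes$order_index)) {
    genes$order_index <- NA_integer_
    for (rep_id in unique(genes$replicon_id)) {
      sel <- which(genes$replicon_id == rep_id)
      genes$order_index[sel][order(genes$start[sel])] <- seq_along(sel) - 1L
    }
  } else {
    genes$order_index <- as.integer(genes$order_index)
  }
  genes <- .fill_gene_defaults(genes)
  genes$n_tm <- as.integer(genes$n_tm)
  for (col in c("has_signal", "has_lowcomp", "is_defense", "is_trna", "is_integrase"))
    genes[[col]] <- as.logical(genes[[col]])
  if ("family_id" %in% names(genes))
    genes$family_id[!is.na(genes$family_id) & genes$family_id == ""] <- NA_character_
  genes <- genes[order(genes$genome_id, genes$replicon_id, genes$order_index), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  validate_gene_table(genes)
  genes
}

#' Write a gene table to TSV
#'
#' Inverse of [read_gene_table()]: `read_gene_table(write_gene_table(x, f))`
#' reproduces `x`.
#'
#' @param genes validated gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  validate_gene_table(genes)
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read ortholog-family assignments and build family records
#'
#' Reads a two-column (minimum) TSV mapping `gene_id` to `family_id`. A gene
#' absent from the map is an ORFan. `genome_spread` of every family is
#' recomputed as the number of distinct genomes among its member genes, so it
#' stays consistent under any gene-table subset.
#'
#' Annotation classes come from, in order of precedence: a curated
#' `annotation_class` column in `family_meta` (or in the assignment file
#' itself), a free-text `annotation` column screened against `virus_keywords`
#' (case-insensitive substring match, yielding `virus_related`), else the
#' default `uncharacterized`.
#'
#' @param path assignment TSV with header `gene_id`, `family_id` and optional
#'   `annotation_class` / `annotation` columns.
#' @param genes gene table providing `genome_id` for each gene.
#' @param family_meta optional data.frame or TSV path with `family_id` plus
#'   `annotation_class` or free-text `annotation`.
#' @param virus_keywords substrings marking a free-text annotation virus-related.
#' @return list with `assignments` (data.frame `gene_id`, `family_id`) and
#'   `families` (data.frame `family_id`, `genome_spread`, `annotation_class`).
#' @export
read_family_assignments <- function(path, genes, family_meta = NULL,
                                    virus_keywords = virus_keywords_default()) {
  asn <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(asn) == 0)
    return(list(assignments = data.frame(gene_id = character(),
                                         family_id = character(),
                                         stringsAsFactors = FALSE),
                families = data.frame(family_id = character(),
                                      genome_spread = integer(),
                                      annotation_class = character(),
                                      stringsAsFactors = FALSE)))
  if (!all(c("gene_id", "family_id") %in% names(asn)))
    .stopf("family assignment file needs gene_id and family_id columns")
  if (is.character(family_meta)) family_meta <- read.delim(family_meta,
                                                           stringsAsFactors = FALSE)
  if (is.null(family_meta) &&
      any(c("annotation_class", "annotation") %in% names(asn)))
    family_meta <- unique(asn[, intersect(names(asn),
                                          c("family_id", "annotation_class",
                                            "annotation")), drop = FALSE])
  build_family_records(asn[, c("gene_id", "family_id")], genes,
                       family_meta = family_meta, virus_keywords = virus_keywords)
}

#' Build family records (genome spread + annotation class) from assignments
#'
#' @inheritParams read_family_assignments
#' @param assignments data.frame with `gene_id`, `family_id` (one family per gene).
#' @return as [read_family_assignments()].
#' @export
build_family_records <- function(assignments, genes, family_meta = NULL,
                                 virus_keywords = virus_keywords_default()) {
  assignments <- unique(assignments[, c("gene_id", "family_id")])
  dup <- assignments$gene_id[duplicated(assignments$gene_id)]
  if (length(dup) > 0)
    .stopf("gene(s) mapped to more than one family: %s",
           paste(unique(dup), collapse = ", "))
  genome_of <- genes$genome_id[match(assignments$gene_id, genes$gene_id)]
  if (anyNA(genome_of))
    .stopf("assignment refers to gene(s) absent from the gene table: %s",
           paste(head(assignments$gene_id[is.na(genome_of)], 5), collapse = ", "))
  spread <- tapply(genome_of, assignments$family_id,
                   function(g) length(unique(g)))
  families <- data.frame(family_id = names(spread),
                         genome_spread = as.integer(spread),
                         stringsAsFactors = FALSE)
  families$annotation_class <- "uncharacterized"
  if (!is.null(family_meta)) {
    idx <- match(families$family_id, family_meta$family_id)
    if ("annotation_class" %in% names(family_meta)) {
      cls <- family_meta$annotation_class[idx]
      bad <- setdiff(unique(cls[!is.na(cls)]), ANNOTATION_CLASSES)
      if (length(bad) > 0)
        .stopf("unknown annotation_class value(s): %s", paste(bad, collapse = ", "))
      families$annotation_class[!is.na(cls)] <- cls[!is.na(cls)]
    } else if ("annotation" %in% names(family_meta)) {
      txt <- tolower(family_meta$annotation[idx])
      hit <- !is.na(txt) &
        Reduce(`|`, lapply(virus_keywords, function(k) grepl(k, txt, fixed = TRUE)))
      families$annotation_class[hit] <- "virus_related"
    }
  }
  rownames(families) <- NULL
  list(assignments = assignments, families = families)
}

#' Read replicon nucleotide sequences (FASTA or GenBank)
#'
#' Sequences are uppercased and restricted to the alphabet `A,C,G,T,N`;
#' any other (degenerate) base is rejected at load. FASTA is read with
#' Biostrings; GenBank flat files with [read_genbank()].
#'
#' @param path FASTA (`.fa`, `.fasta`, `.fna`) or GenBank (`.gb`, `.gbk`) file.
#' @param format `"auto"`, `"fasta"` or `"genbank"`.
#' @param aliases optional named character vector mapping sequence ids in the
#'   file to replicon ids used in the gene tables.
#' @return named character vector of sequences, names = replicon ids.
#' @export
read_replicon_sequences <- function(path, format = c("auto", "fasta", "genbank"),
                                    aliases = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    recs <- read_genbank(path)
    seqs <- vapply(recs, `[[`, character(1), "sequence")
    names(seqs) <- vapply(recs, `[[`, character(1), "replicon_id")
  }
  if (!is.null(aliases)) {
    hit <- names(seqs) %in% names(aliases)
    names(seqs)[hit] <- unname(aliases[names(seqs)[hit]])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    .stopf("sequence '%s' contains bases outside {A,C,G,T,N}", names(seqs)[bad][1L])
  seqs
}

#' Read a GenBank flat file (sequence + tRNA/CDS features)
#'
#' A minimal reader for the subset of the format this pipeline consumes:
#' LOCUS name, FEATURES table (feature key, span, strand, `/product`), and
#' ORIGIN sequence. Joined locations are collapsed to their outer span.
#'
#' @param path GenBank flat file; multiple records separated by `//` are
#'   supported.
#' @return list of records, each a list with `replicon_id`, `sequence`
#'   (uppercase) and `features` (data.frame `type`, `start`, `end`, `strand`,
#'   `product`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) .parse_genbank_record(lines[s:e]),
         starts, ends, SIMPLIFY = FALSE)
}

.parse_genbank_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  replicon_id <- if (length(locus) > 0) strsplit(trimws(locus[1]), "\\s+")[[1]][2]
                 else "unnamed"
  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(origin) > 0) {
    body <- lines[(origin[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  features <- data.frame(type = character(), start = integer(), end = integer(),
                         strand = character(), product = character(),
                         stringsAsFactors = FALSE)
  if (length(feat_start) > 0) {
    end_at <- if (length(origin) > 0) origin[1] - 1L else length(lines)
    flines <- lines[(feat_start[1] + 1L):end_at]
    # a feature header has its key in columns 6-20, a qualifier starts at 22
    is_key <- grepl("^ {5}\\S", flines)
    key_idx <- which(is_key)
    for (i in seq_along(key_idx)) {
      first <- key_idx[i]
      last <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(flines)
      parts <- strsplit(trimws(flines[first]), "\\s+")[[1]]
      type <- parts[1]
      loc <- paste(parts[-1], collapse = "")
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) == 0) next
      qual <- paste(trimws(flines[first:last]), collapse = " ")
      prod <- regmatches(qual, regexpr('/product="[^"]*"', qual))
      prod <- if (length(prod) > 0) sub('/product="([^"]*)"', "\\1", prod) else ""
      features <- rbind(features, data.frame(
        type = type, start = min(nums), end = max(nums), strand = strand,
        product = prod, stringsAsFactors = FALSE))
    }
  }
  list(replicon_id = replicon_id, sequence = seq, features = features)
}

#' Derive a gene table from GenBank records
#'
#' Builds gene rows from `CDS` and `tRNA` features; `is_trna` is set from the
#' feature type and `is_integrase` by case-insensitive substring match of
#' "integrase" against `/product` (no sequence-level detection).
#'
#' @param records output of [read_genbank()].
#' @param genome_id genome identifier to stamp on every gene.
#' @return validated gene table.
#' @export
genbank_gene_table <- function(records, genome_id = "genome1") {
  rows <- lapply(records, function(rec) {
    f <- rec$features
    f <- f[f$type %in% c("CDS", "tRNA"), , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    data.frame(gene_id = sprintf("%s_g%04d", rec$replicon_id, seq_len(nrow(f))),
               genome_id = genome_id, replicon_id = rec$replicon_id,
               start = f$start, end = f$end, strand = f$strand,
               protein_length = pmax(1L, (f$end - f$start + 1L) %/% 3L),
               is_trna = f$type == "tRNA",
               is_integrase = grepl("integrase", f$product, ignore.case = TRUE),
               stringsAsFactors = FALSE)
  })
  as_gene_table(do.call(rbind, rows))
}

#' Check gene coordinates against replicon sequence lengths
#'
#' @param genes gene table with `start`/`end`.
#' @param seqs named sequences from [read_replicon_sequences()].
#' @return `genes`, invisibly; error naming the offending coordinates otherwise.
#' @export
check_gene_coords <- function(genes, seqs) {
  len <- nchar(seqs)[genes$replicon_id]
  bad <- which(is.na(len) | genes$end > len)
  if (length(bad) > 0)
    .stopf("gene '%s' span %d..%d exceeds replicon '%s' (length %s)",
           genes$gene_id[bad[1L]], genes$start[bad[1L]], genes$end[bad[1L]],
           genes$replicon_id[bad[1L]],
           ifelse(is.na(len[bad[1L]]), "unknown", len[bad[1L]]))
  invisible(genes)
}

#' Read genome metadata (species, lifestyle)
#'
#' @param path TSV with columns `genome_id`, `species_name` and optional
#'   `lifestyle` in `thermophile`, `mesophile`, `unknown`.
#' @return data.frame of genome metadata.
#' @export
read_genome_meta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "species_name") %in% names(meta)))
    .stopf("genome metadata needs genome_id and species_name columns")
  if (is.null(meta$lifestyle)) meta$lifestyle <- "unknown"
  bad <- setdiff(unique(meta$lifestyle), c("thermophile", "mesophile", "unknown"))
  if (length(bad) > 0)
    .stopf("unknown lifestyle value(s): %s", paste(bad, collapse = ", "))
  meta
}

#' Export nucleotide spans as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param spans data.frame with `replicon_id`, `nt_start`, `nt_end` and an
#'   optional `name` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(spans, path) {
  name <- spans$name %||% sprintf("region%d", seq_len(nrow(spans)))
  bed <- data.frame(chrom = spans$replicon_id,
                    chromStart = spans$nt_start - 1L,
                    chromEnd = spans$nt_end,
                    name = name, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
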