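#  Maximal perfect direct-repeat detection and integrated-element boundary
#  calling anchored on tRNA and integrase genes.
#
#  A repeat pair is two identical substrings (copies) of the same strand at
#  pos1 < pos2; maximal means extending either end by one base breaks the
#  equality or hits a sequence end. N matches nothing, including N.
#  Coordinates are 1-based inclusive; the flanked span runs from the first
#  base of the proximal copy through the last base of the distal copy
#  (attL through attR).

.repeat_skeleton <- function() {
  data.frame(pos1 = integer(), pos2 = integer(), length = integer(),
             separation = integer(), flank_start = integer(),
             flank_end = integer())
}

#' Find maximal perfect direct repeats in a nucleotide sequence
#'
#' K-mer anchoring (k = `min(min_len, 16)`) with bidirectional ungapped
#' extension: identical k-mers seed candidate copy pairs, each pair is
#' extended to the maximal perfect match on its diagonal, and maximal pairs
#' are reported once. Copies containing `N` never match. Pairs are filtered to
#' `length >= min_len` and a separation (gap between the copies,
#' `pos2 - pos1 - length`) within `[min_sep, max_sep]`; overlapping copies
#' (negative separation) are never reported.
#'
#' @param sequence nucleotide string over `A,C,G,T,N`.
#' @param min_len minimum repeat length in nt (default 15, the smallest
#'   attachment-site repeat this pipeline targets; values below 8 are
#'   rejected — seed-length floor).
#' @param min_sep,max_sep separation bounds in nt (defaults 1000 and 100000,
#'   bracketing integrated-element sizes).
#' @return data.frame `pos1`, `pos2`, `length`, `separation`, `flank_start`,
#'   `flank_end`, sorted by `pos1`, `pos2`.
#' @export
find_direct_repeats <- function(sequence, min_len = 15, min_sep = 1000,
                                max_sep = 100000) {
  if (min_len < 8) .stopf("min_len below the seed-length floor of 8")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    .stopf("sequence contains bases outside {A,C,G,T,N}")
  n <- nchar(sequence)
  k <- min(min_len, 16L)
  if (n < 2L * min_len) return(.repeat_skeleton())
  chars <- strsplit(sequence, "")[[1]]
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  grp <- split(starts[ok], kmers[ok])
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0) return(.repeat_skeleton())
  # candidate anchor pairs as (pos1, diagonal)
  p1 <- integer(0); dg <- integer(0)
  for (g in grp) {
    pr <- utils::combn(g, 2L)
    p1 <- c(p1, pr[1L, ]); dg <- c(dg, pr[2L, ] - pr[1L, ])
  }
  ord <- order(dg, p1)
  p1 <- p1[ord]; dg <- dg[ord]
  res <- list()
  last_d <- -1L; last_end <- -1L
  for (i in seq_along(p1)) {
    d <- dg[i]; a <- p1[i]
    if (d == last_d && a <= last_end) next   # anchor inside the previous run
    # extend left
    s1 <- a; s2 <- a + d
    while (s1 > 1L && chars[s1 - 1L] == chars[s2 - 1L] &&
           chars[s1 - 1L] != "N") { s1 <- s1 - 1L; s2 <- s2 - 1L }
    # extend right
    e1 <- a + k - 1L
    while (e1 + d + 1L <= n && chars[e1 + 1L] == chars[e1 + d + 1L] &&
           chars[e1 + 1L] != "N") e1 <- e1 + 1L
    last_d <- d; last_end <- e1
    len <- e1 - s1 + 1L
    sep <- d - len
    if (len >= min_len && sep >= max(0L, min_sep) && sep <= max_sep)
      res[[length(res) + 1L]] <- c(s1, s1 + d, len, sep)
  }
  if (length(res) == 0) return(.repeat_skeleton())
  m <- unique(do.call(rbind, res))
  out <- data.frame(pos1 = m[, 1], pos2 = m[, 2], length = m[, 3],
                    separation = m[, 4],
                    flank_start = m[, 1], flank_end = m[, 2] + m[, 3] - 1L)
  out <- out[order(out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.interval_gap <- function(a1, a2, b1, b2) pmax(0L, pmax(b1 - a2, a1 - b2))

#' Call integrated-element boundaries from anchored direct repeats
#'
#' Keeps the repeat pairs whose copies are anchored the way site-specific
#' integration leaves them: at least one copy overlapping an annotated tRNA
#' gene (the classical integration target) and/or at least one copy within
#' `adjacency` nt of an annotated integrase gene. The element span is the
#' flanked span, attL through attR inclusive.
#'
#' @param sequence replicon nucleotide sequence.
#' @param genes gene table rows for this replicon, with `is_trna` /
#'   `is_integrase` populated (at least one anchor type present).
#' @inheritParams find_direct_repeats
#' @param adjacency maximum distance in nt between a repeat copy and an
#'   integrase gene (default 2000).
#' @param replicon_id recorded on the calls; defaults to the genes' replicon.
#' @return data.frame of element calls: `replicon_id`, `span_start`,
#'   `span_end`, `pos1`, `pos2`, `length`, `separation`, `anchor_trna`,
#'   `anchor_integrase`, `evidence` (comma-joined subset of
#'   `trna_overlap`, `integrase_adjacent`). Empty when nothing anchors.
#' @export
call_elements <- function(sequence, genes, min_len = 15, min_sep = 1000,
                          max_sep = 100000, adjacency = 2000,
                          replicon_id = NULL) {
  if (is.null(replicon_id))
    replicon_id <- if (nrow(genes) > 0) genes$replicon_id[1L] else "replicon"
  genes <- genes[genes$replicon_id == replicon_id, , drop = FALSE]
  trna <- genes[genes$is_trna %in% TRUE, , drop = FALSE]
  intg <- genes[genes$is_integrase %in% TRUE, , drop = FALSE]
  if (nrow(trna) == 0 && nrow(intg) == 0)
    .stopf("no tRNA or integrase annotations on replicon '%s'", replicon_id)
  reps <- find_direct_repeats(sequence, min_len = min_len,
                              min_sep = min_sep, max_sep = max_sep)
  calls <- lapply(seq_len(nrow(reps)), function(i) {
    r <- reps[i, ]
    copies <- rbind(c(r$pos1, r$pos1 + r$length - 1L),
                    c(r$pos2, r$pos2 + r$length - 1L))
    anchor_trna <- NA_character_
    for (j in 1:2) {
      hit <- which(.interval_gap(copies[j, 1], copies[j, 2],
                                 trna$start, trna$end) == 0L)
      if (length(hit) > 0) { anchor_trna <- trna$gene_id[hit[1L]]; break }
    }
    anchor_int <- NA_character_
    for (j in 1:2) {
      gap <- .interval_gap(copies[j, 1], copies[j, 2], intg$start, intg$end)
      hit <- which(gap <= adjacency)
      if (length(hit) > 0) { anchor_int <- intg$gene_id[hit[1L]]; break }
    }
    evidence <- c(if (!is.na(anchor_trna)) "trna_overlap",
                  if (!is.na(anchor_int)) "integrase_adjacent")
    if (length(evidence) == 0) return(NULL)
    data.frame(replicon_id = replicon_id,
               span_start = r$flank_start, span_end = r$flank_end,
               pos1 = r$pos1, pos2 = r$pos2, length = r$length,
               separation = r$separation,
               anchor_trna = anchor_trna, anchor_integrase = anchor_int,
               evidence = paste(evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(replicon_id = character(), span_start = integer(),
                      span_end = integer(), pos1 = integer(), pos2 = integer(),
                      length = integer(), separation = integer(),
                      anchor_trna = character(), anchor_integrase = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan an element call for split-integrase fragments at its termini
#'
#' SSV-like tyrosine integrases are split by recombination into N- and
#' C-terminal fragments bounding the integrated element. This reports whether
#' annotated integrase(-fragment) genes lie within `terminus_window` nt of
#' each element terminus.
#'
#' @param element one element call row (from [call_elements()]).
#' @param genes gene table rows for the element's replicon.
#' @param terminus_window distance window around each terminus in nt
#'   (default 1000).
#' @return list: `left` and `right` (logical: integrase within the window of
#'   that terminus) and `pattern` in `none`, `one_end`, `both_ends`.
#' @export
split_integrase_scan <- function(element, genes, terminus_window = 1000) {
  genes <- genes[genes$replicon_id == element$replicon_id, , drop = FALSE]
  intg <- genes[genes$is_integrase %in% TRUE, , drop = FALSE]
  near <- function(pos) {
    any(.interval_gap(pos, pos, intg$start, intg$end) <= terminus_window)
  }
  left <- nrow(intg) > 0 && near(element$span_start)
  right <- nrow(intg) > 0 && near(element$span_end)
  pattern <- if (left && right) "both_ends"
             else if (left || right) "one_end" else "none"
  list(left = left, right = right, pattern = pattern)
}

#' Reverse-complement a nucleotide string
#'
#' @param sequence string over `A,C,G,T,N`.
#' @return reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
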