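#  Protein-feature statistics of dark vs background gene sets and group
#  contrasts: feature fractions, length-matched background sampling, Parzen
#  kernel density, two-proportion chi-square, Welch t on log lengths,
#  nonredundant species selection, and a hydropathy-based TM stand-in.

#' Summarize protein features of a gene set
#'
#' Fractions of genes with at least one predicted transmembrane segment, with
#' a predicted signal peptide (restricted to non-membrane proteins when
#' `nonmembrane_signal` is on, i.e. genes with `n_tm == 0`), and with
#' low-complexity segments, plus the protein-length distribution.
#'
#' @param genes non-empty gene table subset with feature columns populated.
#' @param set_label label recorded on the summary (e.g. `"dark"`).
#' @param nonmembrane_signal count signal peptides only on proteins without
#'   transmembrane segments (default TRUE).
#' @return list of class `feature_summary`: `set_label`, `n_genes`, `frac_tm`,
#'   `frac_signal`, `frac_lowcomp`, `length_median`, `length_values`.
#' @export
feature_summary <- function(genes, set_label = "set", nonmembrane_signal = TRUE) {
  if (nrow(genes) == 0) .stopf("empty gene set")
  for (col in c("n_tm", "has_signal", "has_lowcomp"))
    if (anyNA(genes[[col]]))
      .stopf("feature column '%s' not populated for all genes", col)
  signal <- if (nonmembrane_signal) genes$has_signal & genes$n_tm == 0
            else genes$has_signal
  structure(list(
    set_label = set_label,
    n_genes = nrow(genes),
    frac_tm = mean(genes$n_tm >= 1),
    frac_signal = mean(signal),
    frac_lowcomp = mean(genes$has_lowcomp),
    length_median = median(genes$protein_length),
    length_values = genes$protein_length), class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf(
    "Feature summary '%s': %d genes | TM %.1f%% | signal %.1f%% | low-complexity %.1f%% | median length %g codons\n",
    x$set_label, x$n_genes, 100 * x$frac_tm, 100 * x$frac_signal,
    100 * x$frac_lowcomp, x$length_median))
  invisible(x)
}

#' Draw a background sample matching a target length distribution
#'
#' Bins protein lengths into `bin_width`-codon bins and samples, with
#' replacement, the same number of pool genes per bin as the target has, so
#' the sample's length histogram matches the target's exactly. A target bin
#' with no pool genes borrows from the nearest non-empty pool bin.
#'
#' @param pool non-empty background gene table to sample from.
#' @param target gene set whose length distribution is to be matched.
#' @param bin_width length bin width in codons (default 20).
#' @param seed integer seed; sampling is reproducible given the seed.
#' @return gene table of `nrow(target)` rows sampled from `pool`.
#' @export
length_matched_sample <- function(pool, target, bin_width = 20, seed = 1) {
  if (nrow(pool) == 0) .stopf("empty background pool")
  bin <- function(len) as.integer(len %/% bin_width)
  pool_bins <- bin(pool$protein_length)
  target_tab <- table(bin(target$protein_length))
  withr::with_seed(seed, {
    rows <- unlist(lapply(names(target_tab), function(b) {
      b <- as.integer(b)
      need <- target_tab[[as.character(b)]]
      cand <- which(pool_bins == b)
      if (length(cand) == 0) {
        nearest <- unique(pool_bins)[which.min(abs(unique(pool_bins) - b))]
        cand <- which(pool_bins == nearest)
      }
      cand[sample.int(length(cand), need, replace = TRUE)]
    }))
  })
  out <- pool[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson chi-square statistic for a 2x2 table, vectorized
#'
#' Classical closed form `N (ad - bc)^2 / (r1 r2 c1 c2)` on the table
#' `[hits_a, n_a - hits_a; hits_b, n_b - hits_b]`, without continuity
#' correction; returns 0 when a margin is degenerate.
#'
#' @param hits_a,n_a,hits_b,n_b successes and totals per group (vectors
#'   recycle).
#' @return numeric vector of chi-square statistics (df = 1).
#' @export
pearson_chi2 <- function(hits_a, n_a, hits_b, n_b) {
  # double arithmetic throughout: the margin products overflow 32-bit integers
  hits_a <- as.numeric(hits_a); n_a <- as.numeric(n_a)
  hits_b <- as.numeric(hits_b); n_b <- as.numeric(n_b)
  a <- hits_a; b <- n_a - hits_a; c <- hits_b; d <- n_b - hits_b
  N <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(denom > 0, N * (a * d - b * c)^2 / denom, 0)
  as.numeric(stat)
}

#' Compare two proportions by Pearson chi-square
#'
#' 2x2 chi-square without continuity correction (df = 1), the test used for
#' feature-fraction contrasts such as transmembrane content of thermophile vs
#' mesophile island proteins. A Yates-corrected variant is available via
#' `correct = TRUE`.
#'
#' @param a,b length-2 vectors `c(hits, n)` for each group.
#' @param labels group labels.
#' @param correct apply the Yates continuity correction (default FALSE; the
#'   counts this pipeline compares are large).
#' @return one-row data.frame: `test_name`, `group_a`, `group_b`,
#'   `estimate_a`, `estimate_b`, `statistic`, `p_value`, `low_expected`
#'   (TRUE when any expected cell < 1).
#' @export
compare_fractions <- function(a, b, labels = c("a", "b"), correct = FALSE) {
  stopifnot(length(a) == 2, length(b) == 2, a[2] > 0, b[2] > 0,
            a[1] >= 0, b[1] >= 0, a[1] <= a[2], b[1] <= b[2])
  a <- as.numeric(a); b <- as.numeric(b)
  tab <- c(a[1], a[2] - a[1], b[1], b[2] - b[1])
  N <- sum(tab)
  expected <- outer(c(a[2], b[2]), c(a[1] + b[1], N - a[1] - b[1])) / N
  if (correct) {
    ad_bc <- abs(tab[1] * tab[4] - tab[2] * tab[3]) - N / 2
    denom <- prod(a[2], b[2], a[1] + b[1], N - a[1] - b[1])
    stat <- if (denom > 0) N * max(ad_bc, 0)^2 / denom else 0
  } else {
    stat <- pearson_chi2(a[1], a[2], b[1], b[2])
  }
  data.frame(test_name = "pearson_chi2",
             group_a = labels[1], group_b = labels[2],
             estimate_a = a[1] / a[2], estimate_b = b[1] / b[2],
             statistic = stat,
             p_value = pchisq(stat, df = 1, lower.tail = FALSE),
             low_expected = any(expected < 1),
             stringsAsFactors = FALSE)
}

#' Compare two length samples by Welch t-test on log lengths
#'
#' Protein lengths are compared on the natural-log scale (Welch,
#' unequal-variance); the reported estimates are the medians of the raw
#' lengths in codons.
#'
#' @param a,b numeric vectors of protein lengths (>= 2 positive values each).
#' @param labels group labels.
#' @return one-row data.frame: `test_name`, `group_a`, `group_b`,
#'   `estimate_a`, `estimate_b` (raw medians), `statistic` (|t|), `p_value`.
#' @export
compare_log_lengths <- function(a, b, labels = c("a", "b")) {
  if (any(c(a, b) <= 0)) .stopf("non-positive length in input")
  if (length(a) < 2 || length(b) < 2) .stopf("need >= 2 lengths per group")
  tt <- t.test(log(a), log(b))
  data.frame(test_name = "welch_t_log",
             group_a = labels[1], group_b = labels[2],
             estimate_a = median(a), estimate_b = median(b),
             statistic = abs(unname(tt$statistic)),
             p_value = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Gaussian (Parzen) kernel density on a grid
#'
#' Direct Parzen sum: `f(x) = (1/nh) sum_i K((x - x_i)/h)` with the standard
#' normal kernel, evaluated exactly at each grid point (no binning or FFT
#' shortcut). The default bandwidth is Silverman's rule of thumb; the grid
#' pads the data range by four bandwidths so the trapezoid integral is 1 to
#' within 1e-3.
#'
#' @param values numeric data points (>= 1).
#' @param bandwidth kernel bandwidth, or `"auto"` for Silverman's rule.
#' @param n_grid number of grid points (default 512).
#' @return data.frame `x`, `density`.
#' @export
kernel_density <- function(values, bandwidth = "auto", n_grid = 512) {
  if (length(values) < 1) .stopf("need at least one value")
  h <- if (identical(bandwidth, "auto")) {
    h0 <- stats::bw.nrd0(values)
    if (!is.finite(h0) || h0 <= 0) 1 else h0   # degenerate/singleton samples
  } else bandwidth
  if (!is.numeric(h) || h <= 0) .stopf("bandwidth must be positive")
  x <- seq(min(values) - 4 * h, max(values) + 4 * h, length.out = n_grid)
  dens <- vapply(x, function(xx) mean(stats::dnorm((xx - values) / h)) / h,
                 numeric(1))
  data.frame(x = x, density = dens)
}

#' Select one representative genome per species
#'
#' Deterministic nonredundant subset: for each `species_name` the genome with
#' the lexicographically smallest `genome_id` is retained, eliminating biases
#' from multiply sequenced species.
#'
#' @param meta genome metadata with `genome_id`, `species_name`.
#' @return subset of `meta`, one row per species, ordered by `genome_id`.
#' @export
nonredundant_species_set <- function(meta) {
  keep <- tapply(meta$genome_id, meta$species_name, function(g) sort(g)[1L])
  out <- meta[meta$genome_id %in% unlist(keep), , drop = FALSE]
  out <- out[order(out$genome_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kyte-Doolittle hydropathy scale
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Naive transmembrane-segment counter (hydropathy stand-in)
#'
#' Counts non-overlapping 19-residue windows whose mean Kyte-Doolittle
#' hydropathy exceeds 1.6, scanning left to right and skipping past each
#' accepted window. This is an explicitly crude stand-in used only when no
#' `n_tm` annotation is supplied with the input; annotated values always take
#' precedence.
#'
#' @param protein amino-acid sequence (single string, 20-letter alphabet).
#' @param window window length in residues (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return integer count of predicted transmembrane segments.
#' @export
naive_tm_caller <- function(protein, window = 19, threshold = 1.6) {
  aa <- strsplit(toupper(protein), "")[[1]]
  h <- .kd_scale[aa]
  if (anyNA(h))
    .stopf("invalid residue '%s' in protein sequence", aa[is.na(h)][1L])
  n <- length(aa)
  count <- 0L
  i <- 1L
  while (i + window - 1L <= n) {
    if (mean(h[i:(i + window - 1L)]) > threshold) {
      count <- count + 1L
      i <- i + window
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Shannon-entropy low-complexity stand-in
#'
#' Flags a protein as containing a low-complexity segment when any
#' 12-residue window has Shannon entropy below 2.2 bits. A stand-in used only
#' when no `has_lowcomp` annotation is supplied.
#'
#' @param protein amino-acid sequence.
#' @param window window length (default 12).
#' @param threshold entropy threshold in bits (default 2.2).
#' @return logical.
#' @export
naive_lowcomp_caller <- function(protein, window = 12, threshold = 2.2) {
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  if (n < window) return(FALSE)
  for (i in seq_len(n - window + 1L)) {
    p <- table(aa[i:(i + window - 1L)]) / window
    if (-sum(p * log2(p)) < threshold) return(TRUE)
  }
  FALSE
}
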