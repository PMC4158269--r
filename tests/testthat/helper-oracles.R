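# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive route (enumeration, union-find,
# diagonal scan, textbook formula) kept separate from the package internals.

# gene table with an is_dark column from a logical vector / "D"/"N" string
make_flag_genes <- function(x, replicon = "r1", genome = "g1") {
  if (is.character(x) && length(x) == 1)
    x <- strsplit(x, "")[[1]] == "D"
  n <- length(x)
  data.frame(gene_id = sprintf("%s_%04d", replicon, seq_len(n)),
             genome_id = genome, replicon_id = replicon,
             order_index = seq_len(n) - 1L,
             start = seq_len(n) * 1000L - 999L, end = seq_len(n) * 1000L - 100L,
             strand = "+", protein_length = 100L,
             n_tm = 0L, has_signal = FALSE, has_lowcomp = FALSE,
             element_label = "none", is_defense = FALSE,
             is_trna = FALSE, is_integrase = FALSE,
             is_dark = x, stringsAsFactors = FALSE)
}

# exhaustive enumeration of every window position (0-based bounds)
oracle_window_seeds <- function(flags, window, min_dark) {
  n <- length(flags)
  if (n < window) return(data.frame(first_index = integer(),
                                    last_index = integer(),
                                    dark_count = integer()))
  rows <- lapply(0:(n - window), function(i) {
    k <- sum(flags[(i + 1):(i + window)])
    if (k >= min_dark) data.frame(first_index = i,
                                  last_index = i + window - 1L,
                                  dark_count = k) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(first_index = integer(), last_index = integer(),
                               dark_count = integer()) else out
}

# union-find over pairwise interval overlaps (>= 1 shared index)
oracle_merge_components <- function(first, last) {
  n <- length(first)
  if (n == 0) return(data.frame(first_index = integer(), last_index = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && first[j] <= last[i] && first[i] <= last[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(root), function(r) {
    data.frame(first_index = min(first[root == r]),
               last_index = max(last[root == r]))
  }))
  out[order(out$first_index), , drop = FALSE]
}

# all maximal perfect direct repeats by per-diagonal run-length scan
oracle_direct_repeats <- function(s, min_len, min_sep = 0, max_sep = Inf) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  res <- list()
  for (d in seq_len(n - 1L)) {
    len <- n - d
    if (len < min_len) break
    eq <- ch[1:len] == ch[(1 + d):n] & ch[1:len] != "N" & ch[(1 + d):n] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      L <- r$lengths[k]; p1 <- starts[k]; sep <- d - L
      if (sep >= max(0, min_sep) && sep <= max_sep)
        res[[length(res) + 1L]] <- c(p1, p1 + d, L, sep)
    }
  }
  if (length(res) == 0)
    return(data.frame(pos1 = integer(), pos2 = integer(), length = integer(),
                      separation = integer()))
  m <- do.call(rbind, res)
  out <- data.frame(pos1 = m[, 1], pos2 = m[, 2], length = m[, 3],
                    separation = m[, 4])
  out[order(out$pos1, out$pos2), , drop = FALSE]
}

# textbook Welch two-sample t-test on given vectors
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# closed-form Pearson chi-square, coded from the 2x2 cell definition
oracle_chi2 <- function(hits_a, n_a, hits_b, n_b) {
  o <- c(hits_a, n_a - hits_a, hits_b, n_b - hits_b)
  N <- sum(o)
  row <- c(n_a, n_b); col <- c(hits_a + hits_b, N - hits_a - hits_b)
  e <- as.vector(outer(row, col)) / N            # a,c,b,d order
  e <- e[c(1, 3, 2, 4)]
  if (any(e == 0)) return(0)
  sum((o - e)^2 / e)
}

# direct double-loop Parzen sum
oracle_parzen <- function(values, h, grid) {
  vapply(grid, function(x) {
    s <- 0
    for (v in values) s <- s + dnorm((x - v) / h)
    s / (length(values) * h)
  }, numeric(1))
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# small random gene table spanning several genomes/replicons
random_gene_table <- function(n_genomes = 3, genes_per_replicon = 8,
                              replicons_per_genome = 2) {
  rows <- list()
  for (g in seq_len(n_genomes)) for (r in seq_len(replicons_per_genome)) {
    n <- genes_per_replicon
    start <- cumsum(sample(200:800, n, replace = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sprintf("g%d_r%d_%03d", g, r, seq_len(n)),
      genome_id = sprintf("G%02d", g),
      replicon_id = sprintf("G%02d_rep%d", g, r),
      start = start, end = start + sample(90:500, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      protein_length = sample(40:400, n, replace = TRUE),
      n_tm = rpois(n, 0.4), has_signal = runif(n) < 0.1,
      has_lowcomp = runif(n) < 0.1,
      element_label = sample(c("none", "virus", "plasmid"), n, replace = TRUE,
                             prob = c(0.8, 0.1, 0.1)),
      is_defense = runif(n) < 0.1, is_trna = FALSE, is_integrase = FALSE,
      stringsAsFactors = FALSE)
  }
  as_gene_table(do.call(rbind, rows))
}
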