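test_that("single windows and short replicons behave per the seeding rule", {
  # 5 genes, 4 dark -> one seed covering the whole window
  seeds <- find_island_seeds(make_flag_genes("DDDDN"))
  expect_equal(nrow(seeds), 1)
  expect_equal(c(seeds$first_index, seeds$last_index, seeds$dark_count),
               c(0, 4, 4))
  # all-negative replicon and sub-window replicons yield nothing
  expect_equal(nrow(find_island_seeds(make_flag_genes(strrep("N", 30)))), 0)
  expect_equal(nrow(find_island_seeds(make_flag_genes("DDDD"))), 0)
})

test_that("a known 10-gene flag string yields exactly the enumerated seeds", {
  seeds <- find_island_seeds(make_flag_genes("DDNDDNDDDD"))
  expect_equal(seeds$first_index, c(0, 3, 4, 5))
  expect_equal(seeds$last_index, c(4, 7, 8, 9))
})

test_that("seed detection equals exhaustive window enumeration", {
  withr::with_seed(101, {
    for (rep in 1:40) {
      n <- sample(3:300, 1)
      flags <- runif(n) < runif(1, 0.05, 0.6)
      genes <- make_flag_genes(flags)
      for (par in list(c(5, 4), c(5, 5), c(20, 15))) {
        got <- find_island_seeds(genes, window = par[1], min_dark = par[2])
        want <- oracle_window_seeds(flags, par[1], par[2])
        expect_equal(got[, c("first_index", "last_index", "dark_count")],
                     want, ignore_attr = TRUE)
      }
    }
  })
})

test_that("unordered input (gapped order_index) is rejected", {
  genes <- make_flag_genes("DDDDD")
  genes$order_index <- c(0L, 1L, 2L, 4L, 5L)
  expect_error(find_island_seeds(genes), "unordered|consecutive")
})

test_that("overlap merging joins seeds sharing a gene and nothing else", {
  s2 <- data.frame(replicon_id = "r1", first_index = c(0L, 2L),
                   last_index = c(4L, 6L), dark_count = 4L)
  m2 <- merge_seeds(s2)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$first_index, m2$last_index, m2$n_genes), c(0, 6, 7))
  # disjoint and merely abutting seeds stay separate
  s3 <- data.frame(replicon_id = "r1", first_index = c(0L, 6L, 11L),
                   last_index = c(4L, 10L, 15L), dark_count = 4L)
  expect_equal(nrow(merge_seeds(s3)), 3)
})

test_that("merged islands equal union-find connected components", {
  withr::with_seed(202, {
    for (rep in 1:40) {
      k <- sample(1:25, 1)
      first <- sample(0:120, k, replace = TRUE)
      len <- sample(1:12, k, replace = TRUE)
      seeds <- data.frame(replicon_id = "rX", first_index = first,
                          last_index = first + len - 1L, dark_count = 1L)
      got <- merge_seeds(seeds)
      want <- oracle_merge_components(seeds$first_index, seeds$last_index)
      expect_equal(got[, c("first_index", "last_index")], want,
                   ignore_attr = TRUE)
      # pairwise disjoint and every seed contained in exactly one island
      if (nrow(got) > 1) {
        o <- got[order(got$first_index), ]
        expect_true(all(o$first_index[-1] > o$last_index[-nrow(o)]))
      }
      for (i in seq_len(nrow(seeds))) {
        inside <- sum(got$first_index <= seeds$first_index[i] &
                        got$last_index >= seeds$last_index[i])
        expect_equal(inside, 1)
      }
    }
  })
})

test_that("island gene sets equal seed gene sets after merging", {
  withr::with_seed(303, {
    for (rep in 1:10) {
      genes <- make_flag_genes(runif(200) < 0.4)
      seeds <- find_island_seeds(genes)
      isl <- merge_seeds(seeds, genes)
      seed_genes <- unique(unlist(mapply(seq, seeds$first_index,
                                         seeds$last_index,
                                         SIMPLIFY = FALSE)))
      isl_genes <- unique(unlist(mapply(seq, isl$first_index, isl$last_index,
                                        SIMPLIFY = FALSE)))
      expect_setequal(isl_genes, seed_genes)
    }
  })
})

test_that("large islands need 20 genes with at most 5 negatives per window", {
  expect_equal(nrow(find_large_islands(make_flag_genes(strrep("D", 20)))), 1)
  got <- find_large_islands(make_flag_genes(strrep("D", 20)))
  expect_equal(c(got$first_index, got$last_index, got$variant),
               c("0", "19", "large"))
  # 6 negatives in the only window -> no large island
  six_neg <- paste0(strrep("D", 14), strrep("N", 6))
  expect_equal(nrow(find_large_islands(make_flag_genes(six_neg))), 0)
  five_neg <- paste0(strrep("D", 15), strrep("N", 5))
  expect_equal(nrow(find_large_islands(make_flag_genes(five_neg))), 1)
})

test_that("planted 25-gene dark runs: large islands overlap small ones, not conversely", {
  withr::with_seed(404, {
    flags <- runif(400) < 0.03
    for (s in c(50, 200, 330)) flags[s:(s + 24)] <- TRUE   # large-island runs
    for (s in c(120, 270)) flags[s:(s + 5)] <- TRUE        # small-only runs
    genes <- make_flag_genes(flags)
    small <- find_islands(genes)
    large <- find_large_islands(genes)
    expect_equal(nrow(large), 3)
    overlaps <- function(a, b) {
      vapply(seq_len(nrow(a)), function(i)
        any(b$first_index <= a$last_index[i] &
              b$last_index >= a$first_index[i]), logical(1))
    }
    expect_true(all(overlaps(large, small)))     # every large hits a small
    expect_gt(nrow(small), nrow(large))          # extra small-only islands exist
  })
})

test_that("raising min_dark never increases total island gene count", {
  withr::with_seed(505, {
    genes <- make_flag_genes(runif(500) < 0.5)
    counts <- vapply(1:5, function(md)
      sum(find_islands(genes, min_dark = md)$n_genes), numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("genome island fractions equal per-gene membership counting", {
  # 10-gene replicon with one island over genes 0..4 -> fraction 0.5
  genes <- make_flag_genes("DDDDNNNNNN")
  isl <- find_islands(genes)
  fr <- genome_island_fraction(isl, genes)
  expect_equal(fr$fraction, 0.5)
  # a genome with no seeds reports 0
  genes0 <- make_flag_genes(strrep("N", 10), replicon = "r2", genome = "g2")
  both <- rbind(genes, genes0)
  fr2 <- genome_island_fraction(find_islands(both), both)
  expect_equal(fr2$fraction[fr2$genome_id == "g2"], 0)
  expect_error(genome_island_fraction(isl, both[0, ]), "empty")
})

test_that("fractions on a multi-genome set match a brute-force membership oracle", {
  cfg <- generator_config(n_genomes = 10, genes_per_genome = 400, seed = 7)
  sim <- generate_pangenome(cfg)
  genes <- sim$genes
  genes$is_dark <- flag_dark_matter(genes, sim$families)$is_dark
  isl <- find_islands(genes)
  fr <- genome_island_fraction(isl, genes)
  for (g in fr$genome_id) {
    gg <- genes[genes$genome_id == g, ]
    member <- vapply(seq_len(nrow(gg)), function(i) {
      any(isl$replicon_id == gg$replicon_id[i] &
            isl$first_index <= gg$order_index[i] &
            isl$last_index >= gg$order_index[i])
    }, logical(1))
    expect_equal(fr$fraction[fr$genome_id == g], mean(member))
  }
})

test_that("element-label mapping reports exact arithmetic fractions", {
  genes <- make_flag_genes(strrep("D", 10))
  genes$element_label <- c(rep("virus", 2), rep("none", 8))
  isl <- find_islands(genes)
  rep_el <- map_element_labels(isl, genes)
  expect_equal(rep_el$groups$frac_virus[rep_el$groups$group == "all"], 0.2)
  expect_equal(rep_el$groups$frac_plasmid[rep_el$groups$group == "all"], 0)
  # all labels none -> all fractions zero
  genes$element_label <- "none"
  rep0 <- map_element_labels(isl, genes)
  expect_equal(rep0$groups$frac_element, 0)
})

test_that("planted element-label rates are recovered within the binomial 99% CI", {
  cfg <- generator_config(n_genomes = 20, genes_per_genome = 500,
                          islands_per_genome = 4, island_length = 10,
                          seed = 31)
  sim <- generate_pangenome(cfg)
  genes <- sim$genes
  genes$is_dark <- flag_dark_matter(genes, sim$families)$is_dark
  isl <- find_islands(genes)
  rep_el <- map_element_labels(isl, genes, meta = sim$meta)
  all_row <- rep_el$groups[rep_el$groups$group == "all", ]
  for (p in list(c(all_row$frac_virus, cfg$island_virus_rate),
                 c(all_row$frac_plasmid, cfg$island_plasmid_rate))) {
    half <- qnorm(0.995) * sqrt(p[2] * (1 - p[2]) / all_row$n_island_genes)
    expect_lt(abs(p[1] - p[2]), half + 0.01)
  }
  expect_true(all(c("thermophile", "mesophile") %in% rep_el$groups$group))
})

test_that("defense-island detection is the same machinery on relabeled flags", {
  withr::with_seed(606, {
    genes <- make_flag_genes(runif(300) < 0.2)
    genes$is_defense <- genes$is_dark
    def <- detect_defense_islands(genes, window = 5, min_hits = 4)
    ref <- find_islands(genes, window = 5, min_dark = 4)
    expect_equal(def[, c("replicon_id", "first_index", "last_index", "n_genes")],
                 ref[, c("replicon_id", "first_index", "last_index", "n_genes")])
    # trivial cases
    five <- make_flag_genes(strrep("N", 5))
    five$is_defense <- TRUE
    expect_equal(nrow(detect_defense_islands(five, window = 5, min_hits = 4)), 1)
    five$is_defense <- FALSE
    expect_equal(nrow(detect_defense_islands(five, window = 5, min_hits = 4)), 0)
  })
})

test_that("defense cross-mapping equals per-gene set intersection", {
  genes <- make_flag_genes(strrep("D", 30))
  genes$element_label[1:4] <- "virus"
  isl_a <- data.frame(island_id = "a", replicon_id = "r1", first_index = 0L,
                      last_index = 9L, n_genes = 10L, n_dark = 10L,
                      variant = "small")
  # identical sets -> overlap 1; disjoint -> 0
  expect_equal(cross_map_defense(isl_a, isl_a, genes)$overlap_fraction, 1)
  isl_b <- isl_a
  isl_b$first_index <- 15L; isl_b$last_index <- 24L
  expect_equal(cross_map_defense(isl_a, isl_b, genes)$overlap_fraction, 0)
  # partial overlap with labeled genes counted
  isl_c <- isl_a
  isl_c$first_index <- 2L; isl_c$last_index <- 6L
  res <- cross_map_defense(isl_a, isl_c, genes)
  expect_equal(res$n_overlap, 5)
  expect_equal(res$overlap_fraction, 0.5)
  expect_equal(res$n_overlap_virus, 2)          # genes 2,3 carry virus labels
  expect_equal(res$n_defense_outside_elements, 3)
})

test_that("random interval cross-mapping matches an intersection oracle", {
  withr::with_seed(707, {
    for (rep in 1:10) {
      genes <- make_flag_genes(rep(TRUE, 80))
      mk <- function(k) {
        f <- sort(sample(0:70, k))
        data.frame(island_id = sprintf("i%d", seq_len(k)), replicon_id = "r1",
                   first_index = f, last_index = pmin(79L, f + 5L),
                   n_genes = 6L, n_dark = 6L, variant = "small")
      }
      a <- mk(4); b <- mk(3)
      res <- cross_map_defense(a, b, genes)
      in_set <- function(s) {
        unique(unlist(mapply(seq, s$first_index, s$last_index,
                             SIMPLIFY = FALSE)))
      }
      expect_equal(res$n_overlap, length(intersect(in_set(a), in_set(b))))
    }
  })
})

test_that("neighborhood extraction truncates linearly and wraps circularly", {
  genes <- make_flag_genes(strrep("N", 30))
  mid <- extract_neighborhood(genes, genes$gene_id[15], k = 10)
  expect_equal(nrow(mid), 21)
  expect_equal(mid$gene_id[11], genes$gene_id[15])
  first <- extract_neighborhood(genes, genes$gene_id[1], k = 10)
  expect_equal(nrow(first), 11)
  expect_error(extract_neighborhood(genes, "nope"), "unknown")
  # circular mode on a 15-gene replicon returns all genes once
  g15 <- make_flag_genes(strrep("N", 15))
  circ <- extract_neighborhood(g15, g15$gene_id[3], k = 10, circular = TRUE)
  expect_equal(nrow(circ), 15)
  expect_equal(anyDuplicated(circ$gene_id), 0)
  # matches the modular-index oracle for a smaller k
  circ2 <- extract_neighborhood(g15, g15$gene_id[3], k = 4, circular = TRUE)
  want <- ((3 - 1 + (-4:4)) %% 15) + 1
  expect_equal(circ2$gene_id, g15$gene_id[want])
})

test_that("island reports carry composition tallies and nt spans", {
  genes <- make_flag_genes("DDDDNNNNNN")
  genes$n_tm <- c(2L, rep(0L, 9))
  genes$is_defense[2] <- TRUE
  isl <- find_islands(genes)
  expect_equal(isl$n_dark, 4L)
  expect_equal(isl$nt_start, genes$start[1])
  expect_equal(isl$nt_end, genes$end[5])
  expect_equal(isl$n_tm_genes, 1L)
  expect_equal(isl$n_defense, 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  b <- withr::local_tempfile(fileext = ".bed")
  write_island_report(isl, genes, f, bed = b)
  back <- read.delim(f)
  expect_equal(back$n_genes, 5L)
  expect_equal(read.delim(b, header = FALSE)$V2, genes$start[1] - 1L)
})
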