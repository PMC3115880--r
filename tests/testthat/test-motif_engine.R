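test_that("motif parsing: alternation groups, IUPAC, plain words, errors", {
  m <- parse_motif("(A/G)CCGAC")
  expect_equal(m$sets, list(c("A", "G"), "C", "C", "G", "A", "C"))
  expect_equal(m$n_words, 2)
  expect_equal(m$iupac, "RCCGAC")

  abre <- parse_motif("(C/G/T)ACGTG(G/T)(A/C)")
  expect_equal(abre$n_words, 12)
  expect_equal(abre$length, 8)

  plain <- parse_motif("CCGAC")
  expect_true(all(lengths(plain$sets) == 1))
  expect_equal(parse_motif("RYN")$n_words, 2 * 2 * 4)

  expect_error(parse_motif("(A/G"), "parenthes")
  expect_error(parse_motif("A)G"), "parenthes")
  expect_error(parse_motif("(/)"), "empty group")
  expect_error(parse_motif("AXG"), "invalid character")
  expect_error(parse_motif(""), "empty")
})

test_that("scanning coordinates, degenerate mismatch, N, overlaps", {
  ps <- promoter_set(c(A = "TTCCGACGT",      # L=9, CCGAC at offset 3 -> -7
                       B = "CCGACCGAC",      # two matches
                       C = "TTCCGNCGT",      # N blocks the match
                       D = "ACG"))           # shorter than the motif
  h <- scan_promoters(ps, "CCGAC")
  expect_equal(h$A, -7L)
  expect_equal(h$B, c(-9L, -5L))
  expect_equal(h$C, integer(0))
  expect_equal(h$D, integer(0))
  # preceding base T fails the (A/G) requirement
  expect_equal(scan_promoters(ps, "(A/G)CCGAC")$A, integer(0))
  # overlapping matches are all reported
  expect_equal(scan_promoters(promoter_set(c(E = "AAAAA")), "AAA")$E,
               c(-5L, -4L, -3L))
})

test_that("scanner agrees with the naive per-offset oracle (fuzz)", {
  set.seed(13)
  motifs <- c("CCGAC", "(A/G)CCGAC", "CACATG", "(C/T)AAC(G/T)G", "RYCGAC",
              "(C/G/T)ACGTG(G/T)(A/C)")
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(5:80, 1),
                 replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
          collapse = ""), character(1))
  names(seqs) <- paste0("S", seq_along(seqs))
  ps <- promoter_set(seqs)
  for (mo in motifs) {
    expect_equal(unclass(scan_promoters(ps, mo))[names(seqs)],
                 naive_scan(seqs, mo), info = mo)
  }
})

test_that("enrichment matches hand values and handles degenerate margins", {
  # N=10, K=4, n=3, k=3 -> P = C(4,3)/C(10,3) = 1/30
  uni <- gene_set(paste0("G", 1:10))
  hits <- setNames(as.list(rep(list(integer(0)), 10)), uni$genes)
  hits[paste0("G", 1:4)] <- list(-5L)
  fg <- gene_set(paste0("G", 1:3))
  e <- motif_enrichment(fg, uni, hits)
  expect_equal(e$P, 4 / 120)
  expect_equal(c(e$k, e$K, e$n, e$N), c(3, 4, 3, 10))

  # k = 0 -> P = 1;  fg = universe -> k = K, P = 1
  expect_equal(motif_enrichment(gene_set(paste0("G", 5:7)), uni, hits)$P, 1)
  expect_equal(motif_enrichment(uni, uni, hits)$P, 1)
  expect_error(motif_enrichment(gene_set("ZZZ"), uni, hits), "subset")
})

test_that("hypergeometric tail equals brute-force subset enumeration", {
  # enrichment P for (N, K, n, k) against exhaustive enumeration, N <= 12
  for (N in c(5L, 8L, 12L)) {
    uni <- gene_set(paste0("G", 1:N))
    for (K in 0:N) {
      hits <- setNames(rep(list(integer(0)), N), uni$genes)
      if (K > 0) hits[seq_len(K)] <- list(-1L)
      for (n in 1:N) for (k in 0:min(n, K)) {
        if (n - k > N - K) next
        fg <- gene_set(c(head(uni$genes[seq_len(K)], k),
                         head(uni$genes[-seq_len(K)], n - k)))
        expect_equal(motif_enrichment(fg, uni, hits)$P,
                     brute_hyper_tail(N, K, n, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("positional distribution bins, conserves counts, flags uniformity", {
  uni <- gene_set(paste0("G", 1:50))
  # all hits at -75 -> 100% in the [-100, -50) bin
  hits <- setNames(rep(list(-75L), 50), uni$genes)
  pd <- positional_distribution(hits, uni, bin = 50)
  expect_equal(sum(pd$count), 50)
  expect_equal(pd$fraction[pd$lo == -100], 1)
  expect_true(all(pd$fraction[pd$lo != -100] == 0))

  # uniform positions -> flat (chi-square GOF not rejected at 0.01)
  set.seed(17)
  hits_u <- lapply(seq_len(50), function(i)
    sample(seq(-1000L, -1L), 200, replace = TRUE))
  names(hits_u) <- uni$genes
  pd_u <- positional_distribution(hits_u, uni, bin = 50)
  expect_equal(sum(pd_u$count), 50 * 200)
  expect_gt(chisq.test(pd_u$count)$p.value, 0.01)

  expect_error(positional_distribution(hits, gene_set(character(0))), "empty")
  expect_error(positional_distribution(hits, uni, bin = 33), "divide")
})

test_that("k-mer discovery recovers a planted word and reports candidates", {
  sim <- simulate_promoters(promoter_sim_config(
    n_genes = 600, n_foreground = 100, length = 1000,
    plant_spec = list(list(word = "GTCGG", fg_fraction = 0.8,
                           bg_fraction = 0.02, window = "uniform")),
    seed = 21))
  uni <- gene_set(names(sim$promoters))
  res <- discover_kmers(sim$foreground, uni, sim$promoters, 5, 5,
                        threshold = 1e-6)
  expect_equal(attr(res, "n_candidates"), 1024)   # 4^5 candidate words
  expect_true("GTCGG" %in% res$motif)
  expect_true(all(diff(res$P) >= 0))              # sorted by P
  # reported margins are internally consistent
  expect_true(all(res$k <= pmin(res$n, res$K)))

  # full k-range path on a small fixture: candidate space 4^5 + ... + 4^10
  small <- simulate_promoters(promoter_sim_config(n_genes = 30,
                                                  n_foreground = 10,
                                                  length = 200, seed = 2))
  r2 <- discover_kmers(small$foreground, gene_set(names(small$promoters)),
                       small$promoters, 5, 10, threshold = 1e-12)
  expect_equal(attr(r2, "n_candidates"), 1397760)
  expect_error(discover_kmers(small$foreground,
                              gene_set(names(small$promoters)),
                              small$promoters, 7, 5), "k_min")
})

test_that("no 5-mer reaches 1e-10 on unplanted data with a small foreground", {
  for (seed in 1:3) {
    sim <- simulate_promoters(promoter_sim_config(n_genes = 200,
                                                  n_foreground = 20,
                                                  seed = 100 + seed))
    res <- discover_kmers(sim$foreground, gene_set(names(sim$promoters)),
                          sim$promoters, 5, 5)  # induced threshold 1e-10
    expect_equal(nrow(res), 0L, info = paste("seed", seed))
  }
})

test_that("word-set monotonicity: a sub-word never has fewer gene hits", {
  set.seed(23)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("S", 1:100)
  ps <- promoter_set(seqs)
  # every (A/G)CCGAC match contains a CCGAC match (LTRE within DRE/CRT), and
  # every (A/G)CCGAC match is an (A/G)(C/T)CGAC (CBF) match
  g_ltre <- lengths(scan_promoters(ps, "CCGAC")) > 0
  g_dre <- lengths(scan_promoters(ps, "(A/G)CCGAC")) > 0
  g_cbf <- lengths(scan_promoters(ps, "(A/G)(C/T)CGAC")) > 0
  expect_true(sum(g_ltre) >= sum(g_dre))
  expect_true(sum(g_cbf) >= sum(g_dre))
  expect_true(all(g_dre <= g_ltre))
})

test_that("two-background specificity rule distinguishes the three outcomes", {
  # own-set-only planted word: 60 own genes inside a 600-gene merged set,
  # universe 1200, planted in 90% of own only
  n <- 1200
  set.seed(29)
  base <- simulate_promoters(promoter_sim_config(n_genes = n, seed = 31))
  genes <- names(base$promoters)
  own <- gene_set(genes[1:60], "own")
  merged <- gene_set(genes[1:600], "merged")
  uni <- gene_set(genes, "universe")
  seqs <- unclass(base$promoters)
  plant_in <- genes[1:60][runif(60) < 0.9]
  for (g in plant_in) substr(seqs[g], 401, 405) <- "GTCGG"
  ps <- promoter_set(seqs)
  sc <- specificity_call("GTCGG", own, merged, uni, ps)
  expect_equal(sc$call, "specific")

  # planted uniformly across the merged set -> shared
  seqs2 <- unclass(base$promoters)
  plant2 <- genes[1:600][runif(600) < 0.9]
  for (g in plant2) substr(seqs2[g], 401, 405) <- "GTCGG"
  sc2 <- specificity_call("GTCGG", own, merged, uni, promoter_set(seqs2))
  expect_equal(sc2$call, "shared")

  # unplanted word -> not_enriched
  sc3 <- specificity_call("GTCGG", own, merged, uni, base$promoters)
  expect_equal(sc3$call, "not_enriched")
})
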