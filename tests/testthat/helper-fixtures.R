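# Shared fixtures and independent oracles, built in code at test time.

# one-tissue 4x2x{reps} design in canonical condition order
make_design <- function(reps = 3L, tissue = "guard_cell") {
  geno <- rep(c("wt", "gpa1", "agb1", "agb1_gpa1"), each = 2L * reps)
  trt <- rep(rep(c("control", "ABA"), each = reps), times = 4L)
  sample_design(
    sample_id = paste(geno, trt, rep(seq_len(reps), times = 8L), sep = "."),
    tissue = tissue, genotype = geno, treatment = trt,
    replicate = rep(seq_len(reps), times = 8L)
  )
}

# expression matrix from per-condition means (canonical order) + iid noise
make_em <- function(cond_means, reps = 3L, noise_sd = 0, seed = 1L,
                    tissue = "guard_cell") {
  design <- make_design(reps, tissue)
  labs <- paste(design$genotype, design$treatment, sep = ":")
  cond <- paste(rep(c("wt", "gpa1", "agb1", "agb1_gpa1"), each = 2L),
                rep(c("control", "ABA"), times = 4L), sep = ":")
  vals <- cond_means[, match(labs, cond), drop = FALSE]
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), sd = noise_sd), nrow(vals))
  }
  if (is.null(rownames(vals))) rownames(vals) <- paste0("G", seq_len(nrow(vals)))
  colnames(vals) <- design$sample_id
  expression_matrix(vals, design)
}

# naive per-offset scanning oracle, independent of the Biostrings route
naive_scan <- function(seqs, pattern) {
  mp <- parse_motif(pattern)
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < mp$length) return(integer(0))
    ch <- strsplit(s, "")[[1]]
    hits <- integer(0)
    for (st in seq_len(L - mp$length + 1L)) {
      ok <- TRUE
      for (j in seq_len(mp$length)) {
        if (!(ch[st + j - 1L] %in% mp$sets[[j]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, st - L - 1L)
    }
    hits
  })
}

# brute-force upper-tail hypergeometric by enumerating all size-n subsets of
# a universe of N genes of which the first K carry a hit
brute_hyper_tail <- function(N, K, n, k) {
  subs <- utils::combn(N, n)
  hits_per_subset <- colSums(subs <= K)
  mean(hits_per_subset >= k)
}
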