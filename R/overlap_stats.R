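## Gene-set overlap statistics: representation factor with hypergeometric
## P-value, pairwise matrices across experiments, and core-set analysis
## (genes reported in >= k experiments) with cumulative curves.

## shared kernel: overlap, RF and upper-tail hypergeometric P for two sets
## drawn from a universe of N genes
overlap_kernel <- function(a, b, N) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  na <- length(a$genes); nb <- length(b$genes)
  n_union <- length(union(a$genes, b$genes))
  if (N < n_union)
    stop("universe size N = ", N, " smaller than |A union B| = ", n_union)
  k <- length(intersect(a$genes, b$genes))
  expected <- na * nb / N
  rf <- if (k == 0) 0 else k / expected
  p <- stats::phyper(k - 1, na, N - na, nb, lower.tail = FALSE)
  structure(list(size_a = na, size_b = nb, overlap = k, N = N,
                 expected = expected, RF = rf, P = p,
                 pct_of_a = if (na > 0) 100 * k / na else NA_real_,
                 pct_of_b = if (nb > 0) 100 * k / nb else NA_real_,
                 pct_of_min = if (min(na, nb) > 0) 100 * k / min(na, nb)
                              else NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap: |A|=", x$size_a, " |B|=", x$size_b, " k=", x$overlap,
      " N=", x$N, "  RF=", format(x$RF, digits = 4),
      "  P=", format(x$P, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Representation factor of a gene-set overlap
#'
#' The representation factor is the observed overlap divided by the overlap
#' expected for two independent sets of the same sizes drawn from a universe
#' of `N` genes: `RF = k / (|A| |B| / N)`, with `RF = 0` for disjoint sets.
#' `RF > 1` indicates more overlap than expected by chance.
#'
#' @param a,b [gene_set()]s from the same universe.
#' @param N universe size (e.g. genes covered by the array).
#' @return an `overlap_result` (fields `RF`, `P`, `overlap`, `expected`,
#'   percentage overlaps relative to each set).
#' @export
representation_factor <- function(a, b, N) overlap_kernel(a, b, N)

#' Hypergeometric P-value of a gene-set overlap
#'
#' Upper-tail probability of an overlap at least as large as observed:
#' `P = sum_{i >= k} C(|A|, i) C(N - |A|, |B| - i) / C(N, |B|)`, evaluated in
#' log space by `phyper`. `k = 0` gives `P = 1`.
#'
#' @inheritParams representation_factor
#' @return an `overlap_result` (same structure as
#'   [representation_factor()]).
#' @export
overlap_pvalue <- function(a, b, N) overlap_kernel(a, b, N)

#' Pairwise overlap matrix across a collection of gene sets
#'
#' @param sets list of [gene_set()]s with a shared universe.
#' @param N universe size.
#' @return list of matrices `overlap`, `RF`, `P`, `pct_of_min` (symmetric;
#'   diagonal entries describe self-overlap, RF = N/|A|, and are not
#'   comparisons) plus `results` (the full grid of `overlap_result`s).
#' @export
pairwise_matrix <- function(sets, N) {
  m <- length(sets)
  if (m < 2L) stop("need at least two sets")
  nm <- vapply(seq_along(sets), function(i) {
    if (nzchar(sets[[i]]$name)) sets[[i]]$name else paste0("set", i)
  }, character(1))
  mk <- function() matrix(NA_real_, m, m, dimnames = list(nm, nm))
  ov <- mk(); rf <- mk(); pv <- mk(); pc <- mk()
  results <- vector("list", m * m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    r <- overlap_kernel(sets[[i]], sets[[j]], N)
    ov[i, j] <- r$overlap; rf[i, j] <- r$RF; pv[i, j] <- r$P
    pc[i, j] <- r$pct_of_min
    results[[(i - 1L) * m + j]] <- r
  }
  list(overlap = ov, RF = rf, P = pv, pct_of_min = pc, results = results)
}

#' Core gene sets across a collection of experiments
#'
#' Counts, for every gene in the union, how many experiments report it, and
#' returns the genes present in at least `k` experiments together with the
#' full cumulative curve (number of genes in >= k experiments for every k).
#'
#' @param sets list of [gene_set()]s.
#' @param k minimum number of experiments (1 <= k <= number of sets).
#' @return list with `core` (a [gene_set()]), `membership` (named integer
#'   vector), `cumulative` (integer vector indexed by k).
#' @export
core_sets <- function(sets, k) {
  m <- length(sets)
  if (k < 1L || k > m) stop("k must lie in 1..", m)
  counts <- table(unlist(lapply(sets, function(s) s$genes)))
  membership <- stats::setNames(as.integer(counts), names(counts))
  cumulative <- vapply(seq_len(m), function(j) sum(membership >= j),
                       integer(1))
  names(cumulative) <- seq_len(m)
  core <- gene_set(names(membership)[membership >= k],
                   name = sprintf("core_ge_%d", k))
  list(core = core, membership = membership, cumulative = cumulative)
}
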