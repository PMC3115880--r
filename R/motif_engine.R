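## Degenerate-motif parsing, exact-match scanning of upstream regions,
## gene-level hypergeometric enrichment, positional distributions, exhaustive
## k-mer discovery and the two-background tissue-specificity rule.
##
## Scanning is forward-strand, exact match (no inserts or mismatches); an 'N'
## in a promoter never matches. Promoter coordinates are negative offsets
## from the transcription start site: the last base of a length-L sequence is
## position -1, and a match starting at 1-based string offset s is reported
## at coordinate s - L - 1.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

set_to_iupac <- function(s) {
  key <- paste(sort(unique(s)), collapse = "")
  code <- names(which(vapply(IUPAC_SETS, function(x)
    paste(sort(x), collapse = "") == key, logical(1))))
  if (!length(code)) stop("no IUPAC code for base set {", key, "}")
  code[1]
}

#' Parse a degenerate motif pattern
#'
#' Accepts plain bases, IUPAC degenerate letters, and parenthesized
#' alternation groups in the `(A/G)CCGAC` notation used for plant
#' cis-elements (e.g. the ABRE `(C/G/T)ACGTG(G/T)(A/C)`).
#'
#' @param s pattern string.
#' @return a `motif_pattern`: list with `source`, `sets` (list of allowed
#'   bases per position), `length`, `n_words` (product of set sizes) and the
#'   equivalent `iupac` string.
#' @export
parse_motif <- function(s) {
  if (!nzchar(s)) stop("empty motif pattern")
  chars <- strsplit(toupper(s), "")[[1]]
  sets <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- match(")", chars[i:length(chars)])
      if (is.na(j)) stop("unbalanced parentheses in motif '", s, "'")
      grp <- chars[(i + 1L):(i + j - 2L)]
      bases <- grp[grp != "/"]
      if (length(bases) == 0L) stop("empty group in motif '", s, "'")
      if (!all(bases %in% c("A", "C", "G", "T")))
        stop("invalid base in group of motif '", s, "'")
      sets[[length(sets) + 1L]] <- unique(bases)
      i <- i + j
    } else if (ch %in% names(IUPAC_SETS)) {
      sets[[length(sets) + 1L]] <- IUPAC_SETS[[ch]]
      i <- i + 1L
    } else if (ch == ")") {
      stop("unbalanced parentheses in motif '", s, "'")
    } else {
      stop("invalid character '", ch, "' in motif '", s, "'")
    }
  }
  structure(list(source = s, sets = sets, length = length(sets),
                 n_words = prod(lengths(sets)),
                 iupac = paste(vapply(sets, set_to_iupac, character(1)),
                               collapse = "")),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern '", x$source, "' (", x$length, " bp, ", x$n_words,
      " words, IUPAC ", x$iupac, ")\n", sep = "")
  invisible(x)
}

#' Scan promoters for exact matches of a motif
#'
#' Reports every start offset (overlaps included) where all motif positions
#' match; `N` in a sequence never matches. Coordinates are upstream offsets
#' (see module header). A motif longer than a sequence yields an empty hit
#' list for that gene.
#'
#' @param promoters a `promoter_set` (or named character vector).
#' @param motif a [parse_motif()] result or pattern string.
#' @param both_strands also scan the reverse complement (off by default: the
#'   canonical analysis is forward-strand on the supplied upstream sequence).
#' @return a `hit_table`: named list gene -> sorted integer vector of match
#'   start coordinates.
#' @export
scan_promoters <- function(promoters, motif, both_strands = FALSE) {
  if (is.character(motif)) motif <- parse_motif(motif)
  seqs <- unclass(promoters)
  subject <- Biostrings::DNAStringSet(seqs)
  pat <- Biostrings::DNAString(motif$iupac)
  find <- function(p) {
    m <- Biostrings::vmatchPattern(p, subject,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    Biostrings::startIndex(m)
  }
  starts <- find(pat)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    starts2 <- find(rc)
    starts <- Map(function(a, b) sort(unique(c(a, b))), starts, starts2)
  }
  L <- nchar(seqs)
  hits <- Map(function(st, l) {
    if (is.null(st)) integer(0) else sort(as.integer(st) - l - 1L)
  }, starts, L)
  names(hits) <- names(seqs)
  structure(hits, class = "hit_table")
}

## genes (names) having at least one hit
genes_with_hit <- function(hits) names(hits)[lengths(hits) > 0L]

#' Gene-level hypergeometric motif enrichment
#'
#' Counts genes (not occurrences) whose promoter contains >= 1 match, in the
#' foreground and in the universe, and returns the upper-tail hypergeometric
#' probability of drawing at least that many hit-carrying genes in a
#' foreground-sized sample from the universe. Genes without an entry in
#' `hits` (no promoter available) are excluded from both margins.
#'
#' @param fg foreground [gene_set()]; must be a subset of `universe`.
#' @param universe background [gene_set()] over which `hits` was computed.
#' @param hits a [scan_promoters()] hit table.
#' @return an `enrichment_result`: list with `n`, `k`, `N`, `K`, `P` (and the
#'   motif source when available).
#' @export
motif_enrichment <- function(fg, universe, hits) {
  if (!all(fg$genes %in% universe$genes))
    stop("foreground is not a subset of the universe")
  uni <- universe$genes[universe$genes %in% names(hits)]
  drop <- length(universe$genes) - length(uni)
  if (drop > 0L)
    message(drop, " universe gene(s) without promoter excluded from enrichment")
  fgg <- fg$genes[fg$genes %in% uni]
  with_hit <- genes_with_hit(hits)
  K <- sum(uni %in% with_hit)
  k <- sum(fgg %in% with_hit)
  N <- length(uni); n <- length(fgg)
  P <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(n = n, k = k, N = N, K = K, P = P),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment: k/n = ", x$k, "/", x$n, ", K/N = ", x$K, "/", x$N,
      ", P = ", format(x$P, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Positional distribution of motif hits upstream of the TSS
#'
#' Bins hit start coordinates over `[-upstream, 0)` at a fixed bin width
#' (occurrence-level counting: every match counts).
#'
#' @param hits a [scan_promoters()] hit table.
#' @param genes [gene_set()] restricting which genes' hits are counted.
#' @param bin bin width in bases; must divide `upstream`.
#' @param upstream promoter length covered by the bins (default 1000).
#' @return a `positional_distribution`: data.frame with `lo`, `hi` (bin
#'   edges, hits with lo <= pos < hi), `count`, `fraction`.
#' @export
positional_distribution <- function(hits, genes, bin = 50L, upstream = 1000L) {
  if (upstream %% bin != 0) stop("bin width must divide ", upstream)
  if (length(genes$genes) == 0L) stop("empty gene set")
  pos <- unlist(hits[names(hits) %in% genes$genes], use.names = FALSE)
  edges <- seq(-upstream, 0, by = bin)
  counts <- if (length(pos)) {
    as.vector(table(cut(pos, breaks = edges, right = FALSE)))
  } else rep(0L, length(edges) - 1L)
  total <- sum(counts)
  structure(data.frame(lo = edges[-length(edges)], hi = edges[-1],
                       count = counts,
                       fraction = if (total > 0) counts / total else
                         rep(NA_real_, length(counts))),
            class = c("positional_distribution", "data.frame"))
}

## unique k-mers per sequence, N-containing words skipped
gene_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  unique(words)
}

#' Exhaustive k-mer motif discovery with hypergeometric enrichment
#'
#' Streams over every k-mer for `k_min <= k <= k_max` (4^k candidate words
#' per k; words absent from all promoters are never materialized since their
#' enrichment P is 1), computes gene-level enrichment of the foreground
#' against the universe, and returns words below the significance threshold,
#' sorted by P. Default thresholds follow the convention of requiring
#' 1.0e-10 for induced gene sets and 1.0e-4 for repressed gene sets, where
#' candidate motifs are scarcer.
#'
#' @param fg,universe [gene_set()]s (fg within universe).
#' @param promoters a `promoter_set` covering the universe.
#' @param k_min,k_max word length range (defaults 5 and 10).
#' @param direction `"induced"` or `"repressed"`; selects the default
#'   threshold.
#' @param threshold raw hypergeometric P cutoff; overrides `direction`.
#' @param bonferroni divide the threshold by the candidate-space size
#'   (sum of 4^k); off by default, matching the raw-threshold convention.
#' @return data.frame with `motif`, `k` (fg genes with hit), `n`, `K`, `N`,
#'   `P`, sorted by P; attribute `n_candidates` is the candidate-space size.
#' @export
discover_kmers <- function(fg, universe, promoters, k_min = 5L, k_max = 10L,
                           direction = c("induced", "repressed"),
                           threshold = NULL, bonferroni = FALSE) {
  if (k_min < 1L || k_max < k_min) stop("need 1 <= k_min <= k_max")
  direction <- match.arg(direction)
  if (is.null(threshold))
    threshold <- if (direction == "induced") 1.0e-10 else 1.0e-04
  n_candidates <- sum(4^(k_min:k_max))
  if (bonferroni) threshold <- threshold / n_candidates
  fg <- restrict_to_promoters(fg, promoters, "foreground")
  universe <- restrict_to_promoters(universe, promoters, "universe")
  if (!all(fg$genes %in% universe$genes))
    stop("foreground is not a subset of the universe")
  uni_seqs <- unclass(promoters)[universe$genes]
  in_fg <- universe$genes %in% fg$genes
  N <- length(universe$genes); n <- length(fg$genes)
  out <- list()
  for (k in k_min:k_max) {
    per_gene <- lapply(uni_seqs, gene_kmers, k = k)
    dt <- data.table::data.table(
      word = unlist(per_gene, use.names = FALSE),
      fg = rep(in_fg, lengths(per_gene))
    )
    tab <- dt[, list(K = .N, k = sum(fg)), by = "word"]
    tab[, "P" := stats::phyper(tab$k - 1, tab$K, N - tab$K, n,
                               lower.tail = FALSE)]
    hit <- tab[tab$P < threshold]
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.frame(
        motif = hit$word, k = hit$k, n = n, K = hit$K, N = N, P = hit$P,
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), P = numeric(0))
  res <- res[order(res$P), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_candidates") <- n_candidates
  attr(res, "threshold") <- threshold
  res
}

#' Two-background tissue-specificity call for a motif
#'
#' A motif is `specific` to the tissue's own gene set when it is enriched in
#' the own set against the genome-wide universe, NOT enriched in the merged
#' cross-study set against that universe, and still enriched in the own set
#' when the merged set itself is used as the background. It is `shared` when
#' enriched in both own and merged sets against the universe, and
#' `not_enriched` otherwise. The conventional significance anchor is
#' `alpha = 1e-3`.
#'
#' @param motif pattern string or [parse_motif()] result.
#' @param own_set,merged_set,universe [gene_set()]s (own and merged within
#'   the universe; own genes outside the merged set are excluded from the
#'   third test with a warning).
#' @param promoters a `promoter_set`.
#' @param alpha significance threshold for all three tests.
#' @return list with `call` (one of `"specific"`, `"shared"`,
#'   `"not_enriched"`) and the three `enrichment_result`s.
#' @export
specificity_call <- function(motif, own_set, merged_set, universe, promoters,
                             alpha = 1.0e-03) {
  own_set <- restrict_to_promoters(own_set, promoters, "own set")
  merged_set <- restrict_to_promoters(merged_set, promoters, "merged set")
  universe <- restrict_to_promoters(universe, promoters, "universe")
  hits <- scan_promoters(promoters, motif)
  p_own <- motif_enrichment(own_set, universe, hits)
  p_merged <- motif_enrichment(merged_set, universe, hits)
  own_in_merged <- own_set$genes %in% merged_set$genes
  if (!all(own_in_merged))
    warning(sum(!own_in_merged), " own-set gene(s) outside the merged set ",
            "excluded from the merged-background test")
  own3 <- gene_set(own_set$genes[own_in_merged], name = own_set$name)
  p_vs_merged <- motif_enrichment(own3, merged_set, hits)
  call <- if (p_own$P < alpha && p_merged$P >= alpha && p_vs_merged$P < alpha)
    "specific"
  else if (p_own$P < alpha && p_merged$P < alpha)
    "shared"
  else "not_enriched"
  list(call = call, own_vs_universe = p_own, merged_vs_universe = p_merged,
       own_vs_merged = p_vs_merged, alpha = alpha)
}
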