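## Synthetic data with planted truth: expression matrices with planted
## Boolean regulatory modes, promoter sets with planted motif words, and
## collections of "published-study" gene sets with a controlled shared core.
## One global seed expands to per-component seeds by a fixed derivation
## (seed + fixed offsets, kept below 2^31) so partial reruns reproduce.

SIM_MODES <- c("aba_induced_only", "aba_repressed_only",
               "aba_gprotein_dependent", "gprotein_only", "null")

#' Configuration for the expression simulator
#'
#' Defaults state the world the simulator emulates: a one-tissue 4-genotype x
#' 2-treatment x 3-replicate array experiment on the log2 scale, effect size
#' 2.0 log2 units, replicate noise SD 0.25 log2 units, baseline 8.0.
#'
#' @param n_genes number of genes (>= 10).
#' @param fractions named numeric vector over
#'   `aba_induced_only`, `aba_repressed_only`, `aba_gprotein_dependent`,
#'   `gprotein_only` (missing entries default to 0); must sum to <= 1, the
#'   remainder is null genes. Per-mode gene counts are
#'   `floor(fraction * n_genes)`; the remainder is null.
#' @param effect_size,noise_sd,baseline_mean log2-scale parameters.
#' @param replicates replicates per condition.
#' @param tissue tissue label for the design sheet.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L,
                       fractions = c(aba_induced_only = 0.1,
                                     aba_repressed_only = 0.1,
                                     aba_gprotein_dependent = 0.05,
                                     gprotein_only = 0.05),
                       effect_size = 2.0, noise_sd = 0.25,
                       baseline_mean = 8.0, replicates = 3L,
                       tissue = "guard_cell", seed = 1L) {
  fr <- stats::setNames(numeric(4), setdiff(SIM_MODES, "null"))
  fr[names(fractions)] <- fractions
  if (any(is.na(fr))) stop("unknown mode in fractions: ",
                           paste(setdiff(names(fractions), names(fr)), collapse = ", "))
  if (any(fr < 0)) stop("fractions must be non-negative")
  if (sum(fr) > 1) stop("fractions sum to ", sum(fr), " > 1")
  if (n_genes < 10L) stop("n_genes must be >= 10")
  if (noise_sd <= 0 && noise_sd != 0) stop("noise_sd must be >= 0")
  structure(list(n_genes = as.integer(n_genes), fractions = fr,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 replicates = as.integer(replicates), tissue = tissue,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## planted truth vectors for each mode, in canonical condition order
planted_rule_truth <- function(mode) {
  cond <- conditions_frame()
  aba <- as.integer(cond$treatment == "ABA")
  gp <- GENOTYPE_STATES[cond$genotype, ]
  switch(mode,
    aba_induced_only       = aba,                                  # B4
    aba_repressed_only     = 1L - aba,                             # B13
    aba_gprotein_dependent = aba * gp[, "GPA1"] * gp[, "AGB1"],    # ABA AND intact heterotrimer
    gprotein_only          = gp[, "GPA1"],
    null                   = NULL
  )
}

#' Simulate a factorial expression experiment with planted regulatory modes
#'
#' Genes are assigned modes by the exact allocation rule
#' `floor(fraction * n_genes)` (remainder null) in the order induced-only,
#' repressed-only, co-regulated, G-protein-only. Per gene, condition means
#' are `baseline + effect_size * truth(condition)` of the planted rule (flat
#' for null genes) and replicate values add independent Gaussian noise on the
#' log2 scale. Bit-identical output for equal config and seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame gene, mode, direction).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  counts <- floor(cfg$fractions * cfg$n_genes)
  n_null <- cfg$n_genes - sum(counts)
  modes <- rep(c(names(counts), "null"), c(counts, n_null))
  genes <- sprintf("SIMG%05d", seq_len(cfg$n_genes))

  cond <- conditions_frame()
  design <- sample_design(
    sample_id = paste(rep(paste(cond$genotype, cond$treatment, sep = "."),
                          each = cfg$replicates),
                      rep(seq_len(cfg$replicates), times = 8L), sep = ".r"),
    tissue    = cfg$tissue,
    genotype  = rep(cond$genotype, each = cfg$replicates),
    treatment = rep(cond$treatment, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), times = 8L)
  )
  cond_of_sample <- match(condition_labels(design),
                          paste(cond$genotype, cond$treatment, sep = ":"))
  means <- matrix(cfg$baseline_mean, cfg$n_genes, 8L)
  for (m in setdiff(unique(modes), "null")) {
    tv <- planted_rule_truth(m)
    means[modes == m, ] <- rep(cfg$baseline_mean + cfg$effect_size * tv,
                               each = sum(modes == m))
  }
  vals <- means[, cond_of_sample, drop = FALSE]
  if (cfg$noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), sd = cfg$noise_sd),
                          nrow = nrow(vals))
  dimnames(vals) <- list(genes, design$sample_id)
  direction <- c(aba_induced_only = "induced", aba_repressed_only = "repressed",
                 aba_gprotein_dependent = "induced", gprotein_only = "unsigned",
                 null = "unsigned")[modes]
  list(matrix = expression_matrix(vals, design),
       truth = data.frame(gene = genes, mode = modes, direction = direction,
                          stringsAsFactors = FALSE, row.names = NULL))
}

#' Configuration for the promoter simulator
#'
#' @param n_genes total genes; the first `n_foreground` are the foreground.
#' @param n_foreground foreground size.
#' @param length promoter length in bases (default 1000).
#' @param base_comp probabilities of A, C, G, T (default uniform).
#' @param plant_spec list of `list(word=, fg_fraction=, bg_fraction=,
#'   window=)`; `window = c(lo, hi)` gives allowed start coordinates in
#'   promoter coordinates (-length .. -nchar(word)), or `"uniform"`.
#' @param seed integer seed.
#' @export
promoter_sim_config <- function(n_genes = 100L, n_foreground = 0L,
                                length = 1000L,
                                base_comp = c(A = .25, C = .25, G = .25, T = .25),
                                plant_spec = list(), seed = 1L) {
  stopifnot(n_foreground <= n_genes, length > 0)
  base_comp <- base_comp / sum(base_comp)
  for (ps in plant_spec) {
    stopifnot(all(c("word", "fg_fraction", "bg_fraction") %in% names(ps)))
    if (ps$fg_fraction < 0 || ps$fg_fraction > 1 ||
        ps$bg_fraction < 0 || ps$bg_fraction > 1)
      stop("plant fractions must lie in [0, 1]")
    w <- nchar(ps$word)
    win <- if (is.null(ps$window) || identical(ps$window, "uniform"))
      c(-length, -w) else ps$window
    if (win[1] < -length || win[2] > -w || win[1] > win[2])
      stop("window [", win[1], ", ", win[2], "] cannot hold a ", w,
           "-base word in a ", length, "-base promoter")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_foreground = as.integer(n_foreground),
                 length = as.integer(length), base_comp = base_comp,
                 plant_spec = plant_spec, seed = as.integer(seed)),
            class = "promoter_sim_config")
}

#' Simulate promoter sequences with planted motif words
#'
#' Background bases are i.i.d. from the base composition; each planted word
#' overwrites the sequence (so lengths stay fixed) at a start coordinate
#' drawn uniformly from its window, in the chosen fraction of foreground and
#' background genes. Truth records the exact planted coordinates.
#'
#' @param cfg a [promoter_sim_config()].
#' @return list with `promoters` (a `promoter_set`), `foreground` /
#'   `background` ([gene_set()]s), and `truth` (named list gene -> data.frame
#'   word/position).
#' @export
simulate_promoters <- function(cfg) {
  stopifnot(inherits(cfg, "promoter_sim_config"))
  set.seed(cfg$seed + 104729L)  # fixed derivation from the global seed
  genes <- sprintf("PROM%05d", seq_len(cfg$n_genes))
  L <- cfg$length
  seqs <- vapply(seq_len(cfg$n_genes), function(i)
    paste(sample(names(cfg$base_comp), L, replace = TRUE,
                 prob = cfg$base_comp), collapse = ""), character(1))
  names(seqs) <- genes
  is_fg <- seq_len(cfg$n_genes) <= cfg$n_foreground
  truth <- stats::setNames(vector("list", cfg$n_genes), genes)
  for (ps in cfg$plant_spec) {
    w <- nchar(ps$word)
    win <- if (is.null(ps$window) || identical(ps$window, "uniform"))
      c(-L, -w) else ps$window
    frac <- ifelse(is_fg, ps$fg_fraction, ps$bg_fraction)
    planted <- stats::runif(cfg$n_genes) < frac
    for (i in which(planted)) {
      pos <- sample(seq(win[1], win[2]), 1L)      # promoter coordinate
      start1 <- pos + L + 1L                      # 1-based string offset
      substr(seqs[i], start1, start1 + w - 1L) <- ps$word
      truth[[i]] <- rbind(truth[[i]],
                          data.frame(word = ps$word, position = pos,
                                     stringsAsFactors = FALSE))
    }
  }
  list(promoters = promoter_set(seqs),
       foreground = gene_set(genes[is_fg], name = "foreground"),
       background = gene_set(genes[!is_fg], name = "background"),
       truth = truth)
}

#' Simulate a collection of study gene sets with a planted shared core
#'
#' Every set contains the same `shared_core` genes (sampled once from the
#' universe) plus random fill drawn independently per set from the remaining
#' universe. Deterministic given the seed.
#'
#' @param n_experiments number of sets.
#' @param universe a [gene_set()] to draw from.
#' @param shared_core size of the common core (<= per_set_size).
#' @param per_set_size size of every set (<= universe size).
#' @param seed integer seed.
#' @return list with `sets` (list of [gene_set()]) and `core` (the planted
#'   core [gene_set()]).
#' @export
simulate_study_collection <- function(n_experiments, universe, shared_core,
                                      per_set_size, seed = 1L) {
  n_u <- length(universe$genes)
  if (shared_core > per_set_size || per_set_size > n_u)
    stop("need shared_core <= per_set_size <= universe size, got ",
         shared_core, " / ", per_set_size, " / ", n_u)
  set.seed(as.integer(seed) + 15485863L)
  core <- sample(universe$genes, shared_core)
  rest <- setdiff(universe$genes, core)
  sets <- lapply(seq_len(n_experiments), function(i)
    gene_set(c(core, sample(rest, per_set_size - shared_core)),
             name = sprintf("study_%02d", i)))
  list(sets = sets, core = gene_set(core, name = "planted_core"))
}
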