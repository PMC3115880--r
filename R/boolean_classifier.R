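## Boolean regulatory-mode classification.
##
## Expression of each gene across the 8 genotype x treatment conditions is
## compared against idealized 0/1 templates of the composed form
## F(ABA, GPA1, AGB1) = B(ABA, A(GPA1, AGB1)) + C, where A and B range over
## all 16 two-input Boolean functions, ABA is the hormone indicator and
## GPA1/AGB1 are the subunit knockout indicators. The constant offset C is a
## per-gene baseline and is absorbed by the correlation score. The scoring
## measure used here (Pearson correlation between per-condition means and the
## template, times the absolute log2 amplitude between template-on and
## template-off conditions) is a reconstruction: the original measure was
## defined in earlier work and is not restated in full anywhere we can cite,
## so the definition below is this package's own, chosen so that the
## conventional threshold of 1.5 is attainable and carries log2-fold-change
## units. See the methods vignette.

## canonical condition order: genotype-major, control before ABA
conditions_frame <- function() {
  data.frame(
    genotype  = rep(GENOTYPES, each = 2L),
    treatment = rep(TREATMENTS, times = 4L),
    stringsAsFactors = FALSE
  )
}

## evaluate two-input Boolean function with truth-table index 0..15 on (x, y):
## bit 1 + x + 2y of the index (bit order f(0,0), f(1,0), f(0,1), f(1,1))
bool2 <- function(idx, x, y) {
  bits <- as.integer(intToBits(idx))[1:4]
  bits[1L + x + 2L * y]
}

#' Enumerate composed Boolean regulatory rules
#'
#' Evaluates every composition `B(ABA, A(GPA1, AGB1))` of two-input Boolean
#' functions (16 x 16 = 256) on the 8 genotype x treatment states,
#' deduplicates by truth vector and drops the two constant vectors, which
#' cannot serve as expression templates. Rule B4 (`B(ABA, a) = ABA`) and its
#' complement B13 (`not ABA`) are the two hormone-only rules and are flagged
#' `aba_only`; rules whose truth vector ignores the hormone are flagged
#' `gprotein_only`.
#'
#' @return a `boolean_rules` object: list with `truth` (rules x 8 0/1
#'   matrix, columns in canonical condition order), `conditions`, and logical
#'   flags `aba_only`, `gprotein_only`, plus `b_index`/`a_index` of the first
#'   composition realizing each truth vector.
#' @export
enumerate_rules <- function() {
  cond <- conditions_frame()
  st <- cbind(ABA = as.integer(cond$treatment == "ABA"),
              GENOTYPE_STATES[cond$genotype, ])
  seen <- new.env(parent = emptyenv())
  truth <- matrix(0L, 0, 8); b_ix <- a_ix <- integer(0)
  for (B in 0:15) for (A in 0:15) {
    a <- mapply(bool2, MoreArgs = list(idx = A), x = st[, "GPA1"], y = st[, "AGB1"])
    tv <- mapply(function(aba, av) bool2(B, aba, av), st[, "ABA"], a)
    key <- paste(tv, collapse = "")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    truth <- rbind(truth, tv); b_ix <- c(b_ix, B); a_ix <- c(a_ix, A)
  }
  keep <- rowSums(truth) > 0L & rowSums(truth) < 8L
  truth <- truth[keep, , drop = FALSE]
  b_ix <- b_ix[keep]; a_ix <- a_ix[keep]
  aba_vec <- st[, "ABA"]
  aba_only <- apply(truth, 1, function(r) all(r == aba_vec) || all(r == 1L - aba_vec))
  ## ignores ABA: same value for control and ABA within every genotype
  ctrl <- seq(1, 8, by = 2); aba <- ctrl + 1L
  gprotein_only <- apply(truth, 1, function(r) all(r[ctrl] == r[aba]))
  rownames(truth) <- sprintf("R%03d", seq_len(nrow(truth)))
  colnames(truth) <- paste(cond$genotype, cond$treatment, sep = ":")
  structure(list(truth = truth, conditions = cond, b_index = b_ix,
                 a_index = a_ix, aba_only = aba_only,
                 gprotein_only = gprotein_only),
            class = "boolean_rules")
}

#' Per-sample 0/1 template of a rule under a design
#'
#' @param rule_truth 0/1 vector of length 8 in canonical condition order (a
#'   row of `enumerate_rules()$truth`).
#' @param design a [sample_design()] covering all 8 genotype x treatment
#'   conditions of one tissue; replicates share the condition value.
#' @return integer 0/1 vector, one entry per design row.
#' @export
rule_template <- function(rule_truth, design) {
  cond <- conditions_frame()
  labs <- paste(cond$genotype, cond$treatment, sep = ":")
  got <- condition_labels(design)
  missing_cond <- setdiff(labs, got)
  if (length(missing_cond))
    stop("design is missing condition(s): ", paste(missing_cond, collapse = ", "))
  as.integer(rule_truth[match(got, labs)])
}

## per-condition means for every gene: genes x 8 matrix in canonical order
condition_means <- function(em) {
  labs <- condition_labels(em$design)
  cond <- conditions_frame()
  want <- paste(cond$genotype, cond$treatment, sep = ":")
  miss <- setdiff(want, labs)
  if (length(miss))
    stop("design is missing condition(s): ", paste(miss, collapse = ", "))
  f <- factor(labs, levels = want)
  counts <- as.vector(table(f))
  ind <- stats::model.matrix(~ 0 + f)  # samples x 8
  sweep(em$values %*% ind, 2, counts, "/")
}

#' Correlation score of a gene against a Boolean template
#'
#' The score is `r * |delta|` where `r` is the Pearson correlation between
#' the per-condition means and the 0/1 template over the 8 conditions and
#' `delta` is the difference between mean expression in template-on and
#' template-off conditions (log2 units). The score is signed by `r`, so a
#' gene matching the complementary rule scores negatively; assignment takes
#' the maximum over rules, which sends such genes to the complement. Adding a
#' constant to the gene (the baseline offset C) leaves the score unchanged; a
#' flat gene scores 0.
#'
#' @param values per-sample log2 vector (if `design` given) or per-condition
#'   8-vector (if `design = NULL`, canonical order assumed).
#' @param template per-sample 0/1 vector from [rule_template()], or the
#'   8-condition truth vector when `design = NULL`.
#' @param design the [sample_design()], or NULL for pre-averaged input.
#' @return numeric score in log2 units.
#' @export
correlation_score <- function(values, template, design = NULL) {
  if (!is.null(design)) {
    stopifnot(length(values) == nrow(design), length(template) == nrow(design))
    f <- factor(condition_labels(design))
    m <- tapply(values, f, mean)
    t8 <- tapply(template, f, function(x) x[1])
  } else {
    m <- values; t8 <- template
  }
  if (length(unique(t8)) < 2L) stop("template is constant")
  if (stats::sd(m) == 0) return(0)
  r <- stats::cor(as.numeric(m), as.numeric(t8))
  delta <- mean(m[t8 == 1]) - mean(m[t8 == 0])
  r * abs(delta)
}

## vectorized score matrix: genes x rules
score_matrix <- function(em, rules) {
  M <- condition_means(em)                     # genes x 8
  Tm <- rules$truth                            # R x 8
  Mc <- M - rowMeans(M)
  Tc <- Tm - rowMeans(Tm)
  num <- Mc %*% t(Tc)
  den <- outer(sqrt(rowSums(Mc^2)), sqrt(rowSums(Tc^2)))
  r <- num / den
  r[!is.finite(r)] <- 0                        # flat genes
  W <- t(apply(Tm, 1, function(tv) tv / sum(tv) - (1 - tv) / sum(1 - tv)))
  delta <- M %*% t(W)
  S <- r * abs(delta)
  dimnames(S) <- list(rownames(em$values), rownames(Tm))
  S
}

## best rule per gene with deterministic tie-break: hormone-only rules first,
## then lowest rule index
best_rule <- function(S, rules) {
  ord <- order(!rules$aba_only, seq_along(rules$aba_only))
  S2 <- S[, ord, drop = FALSE]
  ix <- max.col(S2, ties.method = "first")
  orig <- ord[ix]
  list(rule = orig, score = S[cbind(seq_len(nrow(S)), orig)])
}

#' Classify genes into Boolean regulatory modes
#'
#' Scores every gene against every non-constant composed rule, assigns the
#' best-scoring rule and calls genes whose best score reaches `threshold`
#' (default 1.5, which in the original study controlled the false discovery
#' rate within 0.001). Categories:
#' \itemize{
#'   \item `gprotein_independent_aba` - best rule is one of the two
#'     hormone-only rules (ABA / not ABA);
#'   \item `gprotein_dependent_aba` - best rule depends on both the hormone
#'     and at least one subunit, and the gene additionally shows a >2-fold
#'     ABA response in wild type at FDR < 0.05 (moderated t on the wild-type
#'     subset); co-regulated genes failing that confirmation get `none`;
#'   \item `gprotein_only` - best rule ignores the hormone;
#'   \item `none` - below threshold or unconfirmed.
#' }
#' Direction of ABA response is read from the observed wild-type ABA-minus-
#' control difference.
#'
#' @param em an [expression_matrix()] for a single tissue with all 8
#'   conditions.
#' @param threshold correlation-score threshold (log2 units).
#' @param n_perm number of label permutations for the FDR estimate (>= 1).
#' @param seed integer seed for the permutations.
#' @param wt_fc_min,wt_fdr_max wild-type confirmation thresholds for
#'   co-regulated genes (fold change on the natural scale, BH FDR).
#' @return a `boolean_callset`: data.frame `calls` (gene, rule, score,
#'   category, direction) plus `threshold`, `fdr_estimate`, `rules`.
#' @export
classify <- function(em, threshold = 1.5, n_perm = 50L, seed = 1L,
                     wt_fc_min = 2, wt_fdr_max = 0.05) {
  if (length(unique(em$design$tissue)) > 1L)
    stop("classify() expects one tissue at a time")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  rules <- enumerate_rules()
  S <- score_matrix(em, rules)
  bb <- best_rule(S, rules)
  called <- bb$score >= threshold

  ## wild-type ABA response (moderated t on the wt subset) for direction and
  ## for confirmation of co-regulated genes
  wt <- em$design$genotype == "wt"
  wt_em <- expression_matrix(em$values[, wt, drop = FALSE],
                             sample_design(em$design$sample_id[wt],
                                           em$design$tissue[wt],
                                           em$design$genotype[wt],
                                           em$design$treatment[wt],
                                           em$design$replicate[wt]))
  wt_fit <- fit_factorial(wt_em)
  wt_prior <- robust_prior(wt_fit)
  ctr <- as.numeric(wt_fit$cells$treatment == "ABA") -
         as.numeric(wt_fit$cells$treatment == "control")
  wt_test <- moderated_t(wt_fit, wt_prior, ctr)
  wt_fdr <- bh_adjust(wt_test$p)

  rule_is_aba_only <- rules$aba_only[bb$rule]
  rule_is_gp_only <- rules$gprotein_only[bb$rule]
  category <- rep("none", nrow(S))
  category[called & rule_is_aba_only] <- "gprotein_independent_aba"
  category[called & rule_is_gp_only] <- "gprotein_only"
  co <- called & !rule_is_aba_only & !rule_is_gp_only
  confirmed <- abs(wt_test$log2FC) > log2(wt_fc_min) & wt_fdr < wt_fdr_max
  category[co & confirmed] <- "gprotein_dependent_aba"

  direction <- ifelse(wt_test$log2FC > 0, "induced",
                      ifelse(wt_test$log2FC < 0, "repressed", "unsigned"))
  direction[category %in% c("gprotein_only", "none")] <- "unsigned"

  fdr <- permutation_fdr(em, threshold = threshold, n_perm = n_perm,
                         seed = seed)
  calls <- data.frame(
    gene = rownames(em$values),
    rule = rownames(rules$truth)[bb$rule],
    score = bb$score,
    category = category,
    direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(calls = calls, threshold = threshold, fdr_estimate = fdr,
                 rules = rules),
            class = "boolean_callset")
}

#' @export
print.boolean_callset <- function(x, ...) {
  cat("boolean_callset:", sum(x$calls$category != "none"), "of",
      nrow(x$calls), "genes called at threshold", x$threshold,
      "(permutation FDR", signif(x$fdr_estimate, 3), ")\n")
  print(table(x$calls$category))
  invisible(x)
}

#' Permutation estimate of the false discovery rate of the Boolean calls
#'
#' Sample labels of the whole matrix are permuted (full column relabelling,
#' preserving gene-wise covariance), best scores recomputed, and the FDR
#' estimated as the mean permuted call count over the observed call count.
#' A 0/0 case (nothing called on the real data) is reported as 0 with a
#' warning.
#'
#' @inheritParams classify
#' @return estimated FDR (numeric scalar).
#' @export
permutation_fdr <- function(em, threshold = 1.5, n_perm = 50L, seed = 1L) {
  rules <- enumerate_rules()
  S <- score_matrix(em, rules)
  real_called <- sum(best_rule(S, rules)$score >= threshold)
  ns <- ncol(em$values)
  counts <- numeric(n_perm)
  set.seed(as.integer(seed))
  for (i in seq_len(n_perm)) {
    perm <- sample.int(ns)
    em_p <- em
    em_p$values <- em$values[, perm, drop = FALSE]
    colnames(em_p$values) <- em$design$sample_id
    Sp <- score_matrix(em_p, rules)
    counts[i] <- sum(best_rule(Sp, rules)$score >= threshold)
  }
  if (real_called == 0L) {
    if (mean(counts) == 0) {
      warning("no genes called on real or permuted data; FDR reported as 0")
      return(0)
    }
  }
  mean(counts) / max(1L, real_called)
}
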