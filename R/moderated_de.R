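## Factorial linear model with empirical-Bayes variance moderation.
##
## Cell-means OLS per gene over the treatment x genotype cells, a scaled-F
## hierarchical model for the residual variances estimated by matching
## moments of log s^2 (digamma/trigamma relations), moderated t-statistics
## for the three contrast families of interest, and Benjamini-Hochberg
## adjustment. This is the standard moderated-t machinery written out in
## full so its behaviour is testable against an independent implementation.

#' Fit the cell-means factorial model per gene
#'
#' Each genotype x treatment cell present in the design is a model cell; the
#' OLS coefficient for a cell is its replicate mean and the residual variance
#' is the pooled within-cell variance on `n - n_cells` degrees of freedom.
#'
#' @param em an [expression_matrix()] for one tissue; every cell needs at
#'   least one replicate and moderation needs `n > n_cells`.
#' @return a `factorial_fit`: list with `coef` (genes x cells), `s2`, `df`
#'   (scalar residual df), `cells` (data.frame genotype/treatment), `cell_n`.
#' @export
fit_factorial <- function(em) {
  if (length(unique(em$design$tissue)) > 1L)
    stop("fit_factorial() expects one tissue at a time")
  labs <- condition_labels(em$design)
  ## full grid over the genotype and treatment levels present: a genotype x
  ## treatment combination that is entirely absent is an error, not a
  ## silently smaller model
  cells <- expand.grid(
    treatment = intersect(TREATMENTS, unique(em$design$treatment)),
    genotype = intersect(GENOTYPES, unique(em$design$genotype)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c("genotype", "treatment")]
  rownames(cells) <- NULL
  cell_labs <- paste(cells$genotype, cells$treatment, sep = ":")
  f <- factor(labs, levels = cell_labs)
  n_cell <- as.vector(table(f))
  if (any(n_cell == 0L))
    stop("empty design cell: ", paste(cell_labs[n_cell == 0L], collapse = ", "))
  ind <- stats::model.matrix(~ 0 + f)
  coef <- sweep(em$values %*% ind, 2, n_cell, "/")
  colnames(coef) <- cell_labs
  fitted <- coef %*% t(ind)
  resid <- em$values - fitted
  df <- ncol(em$values) - length(cell_labs)
  s2 <- if (df > 0) rowSums(resid^2) / df else rep(NA_real_, nrow(em$values))
  structure(list(coef = coef, s2 = s2, df = df, cells = cells,
                 cell_n = n_cell),
            class = "factorial_fit")
}

## Newton inversion of the trigamma function (solve trigamma(y) = x), as used
## when fitting the scaled-F prior.
trigamma_inverse <- function(x) {
  sapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  })
}

#' Estimate the variance-moderation prior from gene-wise variances
#'
#' Models gene variances as `s0^2 * F(d, d0)` and estimates `(d0, s0^2)` by
#' matching the mean and variance of `log(s2)` via digamma/trigamma
#' identities. When the observed spread of `log(s2)` does not exceed what the
#' residual degrees of freedom alone explain, `d0` is `+Inf` (complete
#' shrinkage to a common variance).
#'
#' @param s2 gene-wise residual variances (zeros are excluded with a warning).
#' @param df residual degrees of freedom (scalar or per-gene vector, >= 1).
#' @return a `moderation_prior`: list with `d0` and `s02`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (!any(ok)) stop("all gene variances are zero or undefined; cannot fit prior")
  if (sum(ok) < 30L)
    stop("need at least 30 genes with positive variance and df >= 1, got ",
         sum(ok))
  if (sum(!ok) > 0L)
    warning(sum(!ok), " gene(s) with zero/undefined variance excluded from prior fit")
  z <- log(s2[ok]); d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess dispersion: with d0 = Inf every s2 estimates s02 directly
    ## and the unbiased arithmetic mean replaces the log-scale back-transform
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  structure(list(d0 = d0, s02 = s02), class = "moderation_prior")
}

#' Moderated t-test for one contrast of the factorial fit
#'
#' Shrinks each gene variance toward the prior,
#' `s2_tilde = (d0 s0^2 + d s2) / (d0 + d)`, and tests
#' `t = c' beta / (se_mult * s_tilde)` on `d + d0` degrees of freedom
#' (two-sided; `d0 = Inf` gives a z-like test on the prior variance, `d0 = 0`
#' recovers the ordinary t-test).
#'
#' @param fit a [fit_factorial()] result.
#' @param prior a [estimate_prior()] result (or list with `d0`, `s02`).
#' @param contrast numeric vector, one weight per model cell.
#' @return data.frame with `log2FC`, `t`, `p` per gene.
#' @export
moderated_t <- function(fit, prior, contrast) {
  stopifnot(length(contrast) == ncol(fit$coef))
  d0 <- prior$d0; s02 <- prior$s02; d <- fit$df
  lfc <- as.vector(fit$coef %*% contrast)
  se_mult <- sqrt(sum(contrast^2 / fit$cell_n))
  if (is.infinite(d0)) {
    s2t <- rep(s02, length(fit$s2)); df_t <- Inf
  } else if (d0 == 0) {
    s2t <- fit$s2; df_t <- d
  } else {
    s2t <- (d0 * s02 + d * fit$s2) / (d0 + d); df_t <- d + d0
  }
  tt <- lfc / (se_mult * sqrt(s2t))
  ## zero moderated variance (exactly replicated data): effect is either
  ## exactly zero or infinitely significant
  zero <- s2t == 0
  if (any(zero)) tt[zero] <- ifelse(lfc[zero] == 0, 0, sign(lfc[zero]) * Inf)
  p <- 2 * stats::pt(abs(tt), df = df_t, lower.tail = FALSE)
  data.frame(gene = rownames(fit$coef), log2FC = lfc, t = tt, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return monotone adjusted values, clipped at 1; ties share a value.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

## prior estimation with graceful degradation for degenerate inputs: exactly
## replicated data (all s2 = 0) collapses to the zero-variance limit, and too
## few genes for moment matching falls back to unmoderated variances.
robust_prior <- function(fit) {
  s2 <- fit$s2
  if (fit$df < 1 || all(s2 == 0, na.rm = TRUE))
    return(structure(list(d0 = Inf, s02 = 0), class = "moderation_prior"))
  tryCatch(estimate_prior(s2, fit$df), error = function(e) {
    warning("variance moderation disabled: ", conditionMessage(e))
    structure(list(d0 = 0, s02 = 1), class = "moderation_prior")
  })
}

## the three contrast families of the study, as weight vectors over cells
standard_contrasts <- function(cells) {
  lab <- paste(cells$genotype, cells$treatment, sep = ":")
  unit <- function(on, off) {
    v <- numeric(length(lab)); v[lab == on] <- 1; v[lab == off] <- -1; v
  }
  muts <- setdiff(unique(cells$genotype), "wt")
  geno <- list()
  for (m in muts) {
    geno[[paste0(m, "_control_vs_wt")]] <- unit(paste0(m, ":control"), "wt:control")
    geno[[paste0(m, "_ABA_vs_wt")]]     <- unit(paste0(m, ":ABA"), "wt:ABA")
  }
  list(aba = unit("wt:ABA", "wt:control"), genotype = geno)
}

#' Call differentially expressed genes from the moderated factorial model
#'
#' Tests the hormone contrast (ABA-treated wild type vs control wild type)
#' and the genotype contrasts (each mutant vs wild type, within control and
#' within ABA). A gene is ABA-regulated when the hormone contrast is
#' significant at raw `p < p_aba` and BH FDR (over the hormone contrast
#' p-values of all genes) `< fdr`; it is `gprotein_independent_aba` when no
#' genotype contrast reaches raw `p < p_geno`, and `gprotein_dependent_aba`
#' when at least one does. Direction is the sign of the hormone log2
#' fold-change.
#'
#' @param em an [expression_matrix()] (one tissue, full 2 x 4 layout), or a
#'   precomputed [fit_factorial()] via `fit`.
#' @param p_aba raw p threshold for the hormone contrast (default 1e-4).
#' @param p_geno raw p threshold for genotype contrasts (default 0.01).
#' @param fdr BH FDR cutoff over hormone-contrast p-values (default 0.001).
#' @param prior optional [estimate_prior()] override (e.g. `list(d0 = 0)`
#'   with `s02` ignored for an ordinary-t pipeline).
#' @return a `limma_callset`: data.frame `calls` with gene, category,
#'   direction, p_aba, fdr_aba, log2FC_aba, p_geno_min.
#' @export
call_de <- function(em, p_aba = 1e-4, p_geno = 0.01, fdr = 0.001,
                    prior = NULL) {
  fit <- if (inherits(em, "factorial_fit")) em else fit_factorial(em)
  if (is.null(prior)) prior <- robust_prior(fit)
  ctr <- standard_contrasts(fit$cells)
  aba <- moderated_t(fit, prior, ctr$aba)
  fdr_aba <- bh_adjust(aba$p)
  geno_p <- sapply(ctr$genotype, function(cc) moderated_t(fit, prior, cc)$p)
  if (is.null(dim(geno_p))) geno_p <- matrix(geno_p, nrow = 1)
  p_geno_min <- apply(geno_p, 1, min)
  aba_sig <- aba$p < p_aba & fdr_aba < fdr
  any_geno <- apply(geno_p < p_geno, 1, any)
  category <- rep("none", nrow(aba))
  category[aba_sig & !any_geno] <- "gprotein_independent_aba"
  category[aba_sig & any_geno]  <- "gprotein_dependent_aba"
  direction <- ifelse(aba$log2FC > 0, "induced",
                      ifelse(aba$log2FC < 0, "repressed", "unsigned"))
  direction[category == "none"] <- "unsigned"
  calls <- data.frame(gene = aba$gene, category = category,
                      direction = direction, p_aba = aba$p,
                      fdr_aba = fdr_aba, log2FC_aba = aba$log2FC,
                      p_geno_min = p_geno_min,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(calls = calls,
                 thresholds = list(p_aba = p_aba, p_geno = p_geno, fdr = fdr),
                 prior = prior),
            class = "limma_callset")
}

#' @export
print.limma_callset <- function(x, ...) {
  cat("limma_callset:", sum(x$calls$category != "none"), "of",
      nrow(x$calls), "genes called\n")
  print(table(x$calls$category))
  invisible(x)
}
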