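## Combining the two call sets (Boolean classifier and moderated linear
## model) into the final gene lists, splitting by direction, comparing
## tissues, and the call-concordance arithmetic used for validation.

#' Intersect the Boolean and linear-model call sets into final calls
#'
#' Only genes called ABA-regulated by BOTH methods survive. Agreement on
#' G-protein independence keeps the category; genes whose two calls disagree
#' about G-protein involvement are demoted to G-protein-independent (the
#' existence of ABA regulation is confirmed, its G-protein dependence is
#' not); only genes called G-protein-dependent by both methods are reported
#' as dependent. Genes whose two methods disagree on direction are dropped
#' with a warning. Provenance records the subsector each final gene came
#' from, so two-method cross-tabulations can be rebuilt from the output.
#'
#' @param boolean a `boolean_callset` from [classify()].
#' @param limma a `limma_callset` from [call_de()].
#' @return a `final_callset`: data.frame `calls` (gene, category, direction,
#'   provenance) plus `n_direction_conflicts`.
#' @export
finalize_calls <- function(boolean, limma) {
  b <- boolean$calls; l <- limma$calls
  aba_cats <- c("gprotein_independent_aba", "gprotein_dependent_aba")
  b <- b[b$category %in% aba_cats, c("gene", "category", "direction")]
  l <- l[l$category %in% aba_cats, c("gene", "category", "direction")]
  m <- merge(b, l, by = "gene", suffixes = c("_bool", "_lm"))
  conflict <- m$direction_bool != m$direction_lm
  n_conflict <- sum(conflict)
  if (n_conflict > 0L)
    warning(n_conflict, " gene(s) with conflicting direction between the ",
            "two methods dropped")
  m <- m[!conflict, , drop = FALSE]
  both_dep <- m$category_bool == "gprotein_dependent_aba" &
              m$category_lm == "gprotein_dependent_aba"
  both_ind <- m$category_bool == "gprotein_independent_aba" &
              m$category_lm == "gprotein_independent_aba"
  category <- ifelse(both_dep, "gprotein_dependent_aba",
                     "gprotein_independent_aba")
  provenance <- ifelse(both_dep, "dependent_both",
                ifelse(both_ind, "independent_both",
                ifelse(m$category_bool == "gprotein_dependent_aba",
                       "boolean_dependent_lm_independent",
                       "boolean_independent_lm_dependent")))
  calls <- data.frame(gene = m$gene, category = category,
                      direction = m$direction_bool, provenance = provenance,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(calls = calls, n_direction_conflicts = n_conflict),
            class = "final_callset")
}

#' @export
print.final_callset <- function(x, ...) {
  cat("final_callset:", nrow(x$calls), "genes\n")
  print(table(x$calls$category, x$calls$direction))
  invisible(x)
}

#' Split a final call set into induced and repressed gene sets
#'
#' @param final a [finalize_calls()] result.
#' @return list with [gene_set()]s `induced` and `repressed` (disjoint;
#'   union covers the final set). Genes with an unresolvable direction are
#'   dropped with a warning.
#' @export
split_direction <- function(final) {
  calls <- final$calls
  bad <- !(calls$direction %in% c("induced", "repressed"))
  if (any(bad))
    warning(sum(bad), " gene(s) without resolved direction dropped")
  calls <- calls[!bad, , drop = FALSE]
  list(
    induced = gene_set(calls$gene[calls$direction == "induced"],
                       name = "induced", direction = "induced"),
    repressed = gene_set(calls$gene[calls$direction == "repressed"],
                         name = "repressed", direction = "repressed")
  )
}

#' Compare final call sets across the two tissues
#'
#' Partitions the union of two tissues' calls into five sets: regulated in
#' both tissues with the same direction (induced or repressed), regulated in
#' both with opposite directions, and exclusive to either tissue.
#'
#' @param gc,lf `final_callset`s for guard cells and leaves.
#' @return list of [gene_set()]s: `common_induced`, `common_repressed`,
#'   `opposite`, `gc_only`, `lf_only`.
#' @export
cross_tissue_compare <- function(gc, lf) {
  g <- gc$calls; l <- lf$calls
  both <- intersect(g$gene, l$gene)
  dg <- g$direction[match(both, g$gene)]
  dl <- l$direction[match(both, l$gene)]
  list(
    common_induced = gene_set(both[dg == "induced" & dl == "induced"],
                              "common_induced", "induced"),
    common_repressed = gene_set(both[dg == "repressed" & dl == "repressed"],
                                "common_repressed", "repressed"),
    opposite = gene_set(both[dg != dl], "opposite"),
    gc_only = gene_set(setdiff(g$gene, l$gene), "gc_only"),
    lf_only = gene_set(setdiff(l$gene, g$gene), "lf_only")
  )
}

#' Percent agreement between two sets of per-(gene, tissue) call labels
#'
#' Used for validation bookkeeping, e.g. comparing microarray direction
#' calls against Q-PCR results over the same gene/tissue pairs. Reports
#' `100 * matches / comparisons` to one decimal.
#'
#' @param calls_a,calls_b data.frames with columns `gene`, `tissue`,
#'   `label`; must cover the same (gene, tissue) keys.
#' @return percent agreement, rounded to one decimal.
#' @export
concordance_rate <- function(calls_a, calls_b) {
  need <- c("gene", "tissue", "label")
  stopifnot(all(need %in% names(calls_a)), all(need %in% names(calls_b)))
  if (nrow(calls_a) == 0L) stop("empty input")
  key_a <- paste(toupper(calls_a$gene), calls_a$tissue)
  key_b <- paste(toupper(calls_b$gene), calls_b$tissue)
  if (!setequal(key_a, key_b) || nrow(calls_a) != nrow(calls_b))
    stop("the two call tables must cover the same (gene, tissue) keys")
  m <- match(key_a, key_b)
  agree <- calls_a$label == calls_b$label[m]
  round(100 * sum(agree) / length(agree), 1)
}
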