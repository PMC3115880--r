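## Small published reference tables bundled with the package: the Q-PCR
## validation call table for the guard-cell/leaf ABA study (17 genes x 2
## tissues, with the two known microarray/Q-PCR discrepancies in leaves) and
## the known cis-element enrichment counts (gene-level promoter hits of each
## element among all array genes and within the four ABA-regulated gene
## sets, whose sizes ship alongside).

#' Bundled Q-PCR validation call table
#'
#' Direction labels (`induced`, `repressed`, `none`) per gene and tissue as
#' called by the microarray analysis and by Q-PCR for the 17 validation
#' genes of the guard-cell/leaf ABA study. Feed the two label columns to
#' [concordance_rate()].
#'
#' @return data.frame with columns gene, symbol, tissue, microarray, qpcr.
#' @export
load_qpcr_validation <- function() {
  utils::read.delim(system.file("extdata", "qpcr_validation.tsv",
                                package = "abatrans"),
                    stringsAsFactors = FALSE)
}

#' Bundled known cis-element counts and gene-set sizes
#'
#' Published gene-level promoter hit counts of eight known ABA/stress
#' cis-regulatory elements (ABRE, CE3, DRE/CRT, CBF, LTRE, MYB, MYC,
#' SORLIP1AT) among all array genes and within the four ABA-regulated gene
#' sets of the guard-cell/leaf study, plus the sizes of those sets.
#'
#' @return list with data.frames `motifs` and `set_sizes`.
#' @export
load_known_motifs <- function() {
  list(
    motifs = utils::read.delim(system.file("extdata", "known_motifs.tsv",
                                           package = "abatrans"),
                               stringsAsFactors = FALSE),
    set_sizes = utils::read.delim(system.file("extdata", "gene_set_sizes.tsv",
                                              package = "abatrans"),
                                  stringsAsFactors = FALSE)
  )
}

#' Prevalence of a known motif in an ABA-regulated gene set
#'
#' Percentage of genes in one of the bundled gene sets whose promoter
#' carries at least one occurrence of the element.
#'
#' @param motif_name row of the bundled table, e.g. `"ABRE"`.
#' @param set_label one of `"gc_induced"`, `"gc_repressed"`, `"lf_induced"`,
#'   `"lf_repressed"`.
#' @return percentage (0-100).
#' @export
motif_prevalence <- function(motif_name, set_label = "gc_induced") {
  ref <- load_known_motifs()
  row <- ref$motifs[ref$motifs$name == motif_name, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown motif name: ", motif_name)
  col <- paste0(set_label, "_hits")
  if (!col %in% names(row)) stop("unknown set label: ", set_label)
  size <- ref$set_sizes$size[ref$set_sizes$set_label == set_label]
  100 * row[[col]] / size
}
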