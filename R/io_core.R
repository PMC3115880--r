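## Data model and readers/writers for the formats the pipeline touches:
## tab-delimited expression matrices, sample design sheets, gene lists and
## upstream-region FASTA in the TAIR dialect.

GENOTYPES  <- c("wt", "gpa1", "agb1", "agb1_gpa1")
TREATMENTS <- c("control", "ABA")
TISSUES    <- c("guard_cell", "leaf")

## genotype -> Boolean states of the two G-protein subunits
GENOTYPE_STATES <- matrix(
  c(1L, 1L,   # wt
    0L, 1L,   # gpa1
    1L, 0L,   # agb1
    0L, 0L),  # agb1_gpa1
  ncol = 2, byrow = TRUE,
  dimnames = list(GENOTYPES, c("GPA1", "AGB1"))
)

#' Construct a sample design sheet
#'
#' Describes the factorial layout of the experiment: tissue (guard cell or
#' leaf), heterotrimeric G-protein genotype (`wt`, `gpa1`, `agb1`,
#' `agb1_gpa1`), hormone treatment (`ABA` or solvent `control`) and biological
#' replicate. The genotype maps deterministically to Boolean subunit states
#' (GPA1, AGB1): wt (1,1), gpa1 (0,1), agb1 (1,0), agb1_gpa1 (0,0); treatment
#' maps to the Boolean hormone variable ABA (ABA = 1, control = 0).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param tissue one of `"guard_cell"`, `"leaf"` per sample.
#' @param genotype one of `"wt"`, `"gpa1"`, `"agb1"`, `"agb1_gpa1"`.
#' @param treatment one of `"ABA"`, `"control"`.
#' @param replicate positive integer replicate index.
#' @return a `sample_design` data.frame with one row per sample.
#' @export
sample_design <- function(sample_id, tissue, genotype, treatment, replicate) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    tissue    = as.character(tissue),
    genotype  = as.character(genotype),
    treatment = as.character(treatment),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id))
    stop("sample_ids must be unique; duplicated: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(d$tissue), TISSUES)
  if (length(bad)) stop("unknown tissue: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(d$genotype), GENOTYPES)
  if (length(bad)) stop("unknown genotype: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(d$treatment), TREATMENTS)
  if (length(bad)) stop("unknown treatment: ", paste(bad, collapse = ", "))
  if (any(d$replicate < 1L)) stop("replicate indices must be positive")
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Boolean states (ABA, GPA1, AGB1) for each sample of a design
#'
#' @param design a [sample_design()].
#' @return integer matrix with columns `ABA`, `GPA1`, `AGB1`.
#' @export
design_states <- function(design) {
  cbind(
    ABA = as.integer(design$treatment == "ABA"),
    GENOTYPE_STATES[design$genotype, , drop = FALSE]
  )
}

## condition label helper: genotype:treatment
condition_labels <- function(design) paste(design$genotype, design$treatment, sep = ":")

#' Construct an expression matrix container
#'
#' @param values numeric matrix of log2 intensities, genes x samples; rownames
#'   are gene identifiers, colnames must equal `design$sample_id`.
#' @param design a [sample_design()].
#' @return an `expression_matrix` object (list with `values`, `design`).
#' @export
expression_matrix <- function(values, design) {
  stopifnot(is.matrix(values), inherits(design, "sample_design"))
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (ncol(values) != nrow(design))
    stop("column count (", ncol(values), ") does not match design (",
         nrow(design), " samples)")
  if (!is.null(colnames(values)) && !identical(colnames(values), design$sample_id))
    stop("matrix columns must be ordered as in the design")
  colnames(values) <- design$sample_id
  if (anyNA(values)) stop("expression matrix contains missing values")
  rownames(values) <- toupper(rownames(values))
  structure(list(values = values, design = design), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", paste(unique(x$design$tissue), collapse = "+"), ")\n")
  invisible(x)
}

#' Read a sample design sheet (TSV)
#'
#' @param path TSV file with columns sample_id, tissue, genotype, treatment,
#'   replicate.
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "genotype", "treatment", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design file missing columns: ", paste(miss, collapse = ", "))
  sample_design(d$sample_id, d$tissue, d$genotype, d$treatment, d$replicate)
}

#' Read a tab-delimited expression matrix plus its design sheet
#'
#' The matrix file has a header row of sample ids and a first column of gene
#' identifiers. Columns are reordered to follow the design file; genes are
#' never reordered. Gene ids are uppercased.
#'
#' @param path matrix TSV.
#' @param design_path design TSV (see [read_sample_design()]).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, design_path) {
  design <- read_sample_design(design_path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  gene_ids <- toupper(raw[[1]])
  hdr <- names(raw)[-1]
  missing_samples <- setdiff(design$sample_id, hdr)
  if (length(missing_samples))
    stop("sample(s) in design but not in matrix header: ",
         paste(missing_samples, collapse = ", "))
  vals <- as.matrix(raw[, design$sample_id, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", vals[bad[1], bad[2]], "' at gene ",
         gene_ids[bad[1]], ", sample ", design$sample_id[bad[2]])
  }
  dimnames(num) <- list(gene_ids, design$sample_id)
  expression_matrix(num, design)
}

#' Write an expression matrix and its design to TSV files
#'
#' @param em an [expression_matrix()].
#' @param path,design_path output TSV paths.
#' @export
write_expression_matrix <- function(em, path, design_path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(em$design), design_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param genes character vector of gene ids; uppercased and deduplicated.
#' @param name set label.
#' @param direction `"induced"`, `"repressed"` or `"unsigned"`.
#' @return a `gene_set` object.
#' @export
gene_set <- function(genes, name = "", direction = c("unsigned", "induced", "repressed")) {
  direction <- match.arg(direction)
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  structure(list(name = name, genes = genes, direction = direction),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", x$direction, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene list (one id per line, '#' comments allowed)
#'
#' @inheritParams gene_set
#' @param path input file.
#' @return a [gene_set()]; an empty file yields an empty set with a warning.
#' @export
read_gene_set <- function(path, name = basename(path),
                          direction = c("unsigned", "induced", "repressed")) {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gs <- gene_set(lines, name = name, direction = direction)
  if (length(gs$genes) == 0L) warning("gene set '", name, "' is empty")
  gs
}

#' Write a gene set, one id per line
#' @param gs a [gene_set()]; @param path output path.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(gs$genes, path)
  invisible(path)
}

#' Read promoter sequences from FASTA (TAIR upstream dialect)
#'
#' The first whitespace-delimited token of each header is the gene identifier,
#' optionally carrying a `.n` splice-variant suffix which is stripped. Ids are
#' uppercased; duplicate ids after stripping keep the first record (with a
#' warning). Sequences are uppercased; `N` is allowed. Each record is
#' nominally the 1000 bases upstream of the transcription start site, the last
#' base being position -1.
#'
#' @param path FASTA file.
#' @return a `promoter_set`: named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (",
                             conditionMessage(e), ")")
  )
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- toupper(sub("\\.[0-9]+$", "", sub("\\s.*$", "", names(seqs))))
  s <- toupper(as.character(seqs))
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicate promoter id(s) after splice-suffix ",
            "stripping; keeping first record: ",
            paste(unique(ids[dup]), collapse = ", "))
    s <- s[!dup]; ids <- ids[!dup]
  }
  names(s) <- ids
  structure(s, class = "promoter_set")
}

#' Construct a promoter set from a named character vector
#' @param seqs named character vector of upstream sequences (A/C/G/T/N).
#' @export
promoter_set <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  s <- toupper(as.character(seqs))
  if (any(grepl("[^ACGTN]", s))) stop("promoter sequences restricted to A/C/G/T/N")
  names(s) <- toupper(names(seqs))
  structure(s, class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("promoter_set:", length(x), "sequences, lengths",
      min(nchar(x)), "-", max(nchar(x)), "\n")
  invisible(x)
}

#' Write a promoter set to FASTA
#' @param promoters a `promoter_set`; @param path output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  x <- Biostrings::BStringSet(unclass(promoters))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## shared check used across analysis modules: restrict gene sets to genes that
## actually have a promoter sequence, keeping hypergeometric margins
## consistent; counts of dropped genes are reported via message().
restrict_to_promoters <- function(gs, promoters, what = "gene set") {
  keep <- gs$genes %in% names(promoters)
  if (!all(keep))
    message(sum(!keep), " gene(s) in ", what,
            " lack a promoter sequence and are excluded")
  gene_set(gs$genes[keep], name = gs$name, direction = gs$direction)
}
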