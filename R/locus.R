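#' Describe the target disease locus
#'
#' A `target_locus` records where the disease gene lies on chromosome X, the
#' pathogenic variant being tracked, the flanking window in which SNP markers
#' are selected, and the disease status of the phase-reference sample (an
#' affected proband, or an unaffected relative such as chorionic villus from a
#' conceptus known not to carry the variant). The reference status sets the
#' phase polarity: the maternal haplotype carried by an affected reference is
#' the mutant-linked one, the haplotype carried by an unaffected reference is
#' the normal one.
#'
#' @param chrom chromosome name, normally `"chrX"`.
#' @param gene_start,gene_end 1-based inclusive gene interval (bp).
#' @param mutation_pos 1-based position of the pathogenic variant (bp); must
#'   lie inside the analysis window.
#' @param mutation_ref,mutation_alt reference and alternate alleles of the
#'   pathogenic variant.
#' @param window_flank bp added on each side of the gene to form the closed
#'   marker-selection window `[gene_start - window_flank, gene_end +
#'   window_flank]`. Default 1 Mb.
#' @param reference_status `"affected"` or `"unaffected"`: disease status of
#'   the phase-reference sample.
#' @param gene_name optional gene symbol used in reports.
#' @return an object of class `target_locus`.
#' @examples
#' target_locus(
#'   gene_start = 123480000, gene_end = 123507000,
#'   mutation_pos = 123499000, mutation_ref = "G", mutation_alt = "A",
#'   reference_status = "affected", gene_name = "SH2D1A"
#' )
#' @export
target_locus <- function(chrom = "chrX", gene_start, gene_end, mutation_pos,
                         mutation_ref = "N", mutation_alt = "N",
                         window_flank = 1e6,
                         reference_status = c("affected", "unaffected"),
                         gene_name = NA_character_) {
  reference_status <- match.arg(reference_status)
  if (!is.numeric(gene_start) || !is.numeric(gene_end) || gene_start > gene_end)
    stop("gene_start must be <= gene_end", call. = FALSE)
  if (!is.numeric(window_flank) || window_flank < 0)
    stop("window_flank must be a non-negative number of base pairs", call. = FALSE)
  win <- c(gene_start - window_flank, gene_end + window_flank)
  if (!is.numeric(mutation_pos) || mutation_pos < win[1] || mutation_pos > win[2])
    stop("mutation_pos must lie within the analysis window [",
         win[1], ", ", win[2], "]", call. = FALSE)
  structure(
    list(chrom = chrom,
         gene_start = as.numeric(gene_start), gene_end = as.numeric(gene_end),
         mutation_pos = as.numeric(mutation_pos),
         mutation_ref = mutation_ref, mutation_alt = mutation_alt,
         window_flank = as.numeric(window_flank),
         reference_status = reference_status,
         gene_name = gene_name),
    class = "target_locus"
  )
}

#' Analysis window of a target locus
#'
#' @param locus a [target_locus()].
#' @return numeric `c(start, end)`, closed interval in bp.
#' @export
locus_window <- function(locus) {
  stopifnot(inherits(locus, "target_locus"))
  c(locus$gene_start - locus$window_flank, locus$gene_end + locus$window_flank)
}

#' Maternal haplotype linked to the pathogenic variant
#'
#' X1 is by construction the maternal haplotype carried by the phase-reference
#' sample; an affected reference therefore anchors the mutation to X1, an
#' unaffected reference to X2.
#'
#' @param reference_status `"affected"` or `"unaffected"`.
#' @return `"X1"` or `"X2"`.
#' @export
mutant_linked_label <- function(reference_status) {
  switch(match.arg(reference_status, c("affected", "unaffected")),
         affected = "X1", unaffected = "X2")
}

#' @export
print.target_locus <- function(x, ...) {
  win <- locus_window(x)
  cat("Target locus", if (!is.na(x$gene_name)) paste0("(", x$gene_name, ")"), "\n")
  cat("  gene:     ", x$chrom, ":", format(x$gene_start, big.mark = ","), "-",
      format(x$gene_end, big.mark = ","), "\n", sep = "")
  cat("  mutation: ", x$chrom, ":", format(x$mutation_pos, big.mark = ","), " ",
      x$mutation_ref, ">", x$mutation_alt, "\n", sep = "")
  cat("  window:   ", x$chrom, ":", format(win[1], big.mark = ","), "-",
      format(win[2], big.mark = ","), " (flank ", format(x$window_flank,
      big.mark = ","), " bp)\n", sep = "")
  cat("  reference sample:", x$reference_status,
      "=> mutant-linked haplotype", mutant_linked_label(x$reference_status), "\n")
  invisible(x)
}
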