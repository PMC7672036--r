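# Informative-SNP classification and maternal phasing against the
# reference sample.

#' Classify marker informativeness and phase the maternal haplotypes
#'
#' A site is maternally informative when the mother is heterozygous and the
#' phase-reference sample has a usable single-allele call there. Maternal
#' haplotype X1 is defined as the haplotype carried by the reference; X2 is
#' the other maternal allele. With biallelic SNPs the father's single allele
#' always equals exactly one of the two maternal alleles, which yields two
#' sub-classes for female embryos:
#'
#' * `x1_detecting` — father's allele differs from the X1 allele (it equals
#'   X2), so observing the X1 allele in a female embryo is unambiguous;
#' * `x2_detecting` — father's allele differs from the X2 allele.
#'
#' Sites where the father's call is missing are classed `male_only`: any
#' maternal-het site is fully informative in a male embryo (no paternal X),
#' but female-embryo disambiguation needs the paternal allele.
#'
#' The mutant-linked haplotype follows the reference sample's disease
#' status: an affected reference carries the mutant haplotype, so
#' `mutant_linked = "X1"`; an unaffected reference implies
#' `mutant_linked = "X2"`.
#'
#' @param table a filtered [snp_table()].
#' @param locus a [target_locus()]; only `reference_status` is consulted
#'   here (filtering is [apply_region_depth_filter()]'s job).
#' @return a list with elements `phase` (class `maternal_phase`: data frame
#'   of informative sites with columns `chrom`, `pos`, `ref`, `alt`, `x1`,
#'   `x2`, `father`, `class`, allele-base columns `x1_base`/`x2_base`/
#'   `father_base`, and attribute `mutant_linked`) and `markers`
#'   (a [summarize_markers()] record).
#' @export
classify_sites <- function(table, locus) {
  stopifnot(inherits(table, "snp_table"), inherits(locus, "target_locus"))
  mo <- table$geno[, role_sample(table, "mother")]
  fa <- table$geno[, role_sample(table, "father")]
  re <- table$geno[, role_sample(table, "reference")]

  informative <- is_het(mo) & is_single(re)
  if (!any(informative))
    warning("no maternally informative sites: mother never heterozygous ",
            "with a usable reference call")
  idx <- which(informative)
  x1 <- re[idx]
  x2 <- other_allele(x1)
  father <- ifelse(is_single(fa[idx]), fa[idx], NA_character_)
  cls <- ifelse(is.na(father), "male_only",
                ifelse(father == x2, "x1_detecting", "x2_detecting"))

  sites <- table$sites[idx, , drop = FALSE]
  base_of <- function(allele, ref, alt)
    ifelse(is.na(allele), NA_character_, ifelse(allele == "0", ref, alt))
  phase <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    x1 = x1, x2 = x2, father = father, class = cls,
    x1_base = base_of(x1, sites$ref, sites$alt),
    x2_base = base_of(x2, sites$ref, sites$alt),
    father_base = base_of(father, sites$ref, sites$alt),
    stringsAsFactors = FALSE)
  rownames(phase) <- NULL
  attr(phase, "mutant_linked") <- mutant_linked_label(locus$reference_status)
  class(phase) <- c("maternal_phase", "data.frame")
  list(phase = phase, markers = summarize_markers(phase))
}

#' Summarise marker counts by informativeness class
#'
#' @param phase a `maternal_phase` from [classify_sites()].
#' @return an object of class `marker_summary` with fields
#'   `n_paternal_informative` (informative sites with a usable father call,
#'   i.e. usable for paternal-X tracking), `n_x1_informative` /
#'   `n_x2_informative` (X1-/X2-detecting site counts for female embryos),
#'   and `n_male_usable` (all maternal-informative sites, usable in male
#'   embryos).
#' @export
summarize_markers <- function(phase) {
  stopifnot(inherits(phase, "maternal_phase"))
  structure(list(
    n_paternal_informative = sum(phase$class != "male_only"),
    n_x1_informative = sum(phase$class == "x1_detecting"),
    n_x2_informative = sum(phase$class == "x2_detecting"),
    n_male_usable = nrow(phase)),
    class = "marker_summary")
}

#' @export
print.marker_summary <- function(x, ...) {
  cat("Informative SNP markers\n")
  cat("  paternal-X trackable:", x$n_paternal_informative, "\n")
  cat("  X1-detecting:        ", x$n_x1_informative, "\n")
  cat("  X2-detecting:        ", x$n_x2_informative, "\n")
  cat("  usable in males:     ", x$n_male_usable, "\n")
  invisible(x)
}

#' @export
print.maternal_phase <- function(x, ...) {
  cat("Phased maternal haplotypes:", nrow(x), "informative sites; ",
      "mutant-linked =", attr(x, "mutant_linked"), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more sites\n")
  invisible(x)
}

#' Export the per-site marker classification as TSV
#'
#' @param phase a `maternal_phase`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(phase, path) {
  stopifnot(inherits(phase, "maternal_phase"))
  out <- data.frame(site = seq_len(nrow(phase)), pos = phase$pos,
                    X1 = phase$x1_base, X2 = phase$x2_base,
                    father = phase$father_base, class = phase$class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
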