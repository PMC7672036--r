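#' Construct the canonical multi-sample SNP genotype table
#'
#' The `snp_table` is the package's working container: an ordered set of
#' biallelic chrX SNPs with one genotype call and one read depth per sample.
#' Genotype calls use allele indices relative to REF/ALT in a collapsed
#' encoding: `"0"` or `"1"` when a single allele is observed (hemizygous
#' males, homozygous diploid calls, or WGA samples where only one allele
#' amplified), `"0/1"` when both alleles are observed, and `NA` for a
#' no-call. Zygosity of homozygous diploid calls is deliberately not kept:
#' no step of the haplotyping analysis can use it, and it is unknowable in a
#' whole-genome-amplified single cell.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing), `ref`, `alt` (single bases).
#' @param geno character matrix, `nrow(sites)` x samples, in the encoding
#'   above. Column names are sample names.
#' @param depth numeric matrix of per-site read depths, same shape as `geno`.
#' @param roles named character vector mapping each sample name to a role:
#'   exactly one `"father"`, one `"mother"`, one `"reference"`, and any
#'   number of `"embryo"` samples.
#' @return an object of class `snp_table`.
#' @export
snp_table <- function(sites, geno, depth, roles) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  if (nrow(sites) > 1 && any(diff(sites$pos) <= 0))
    stop("site positions must be strictly increasing", call. = FALSE)
  if (!identical(dim(geno), dim(depth)) || nrow(geno) != nrow(sites))
    stop("geno and depth must be sites x samples matrices", call. = FALSE)
  if (is.null(colnames(geno))) stop("geno must have sample column names", call. = FALSE)
  colnames(depth) <- colnames(geno)
  roles <- check_roles(roles, colnames(geno))
  ok <- is.na(geno) | geno %in% c("0", "1", "0/1")
  if (!all(ok))
    stop("invalid genotype encoding: ", paste(unique(geno[!ok]), collapse = ", "),
         call. = FALSE)
  structure(list(sites = sites, geno = geno, depth = depth, roles = roles),
            class = "snp_table")
}

check_roles <- function(roles, samples) {
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("roles must be a named vector (sample name -> role)", call. = FALSE)
  bad <- setdiff(roles, c("father", "mother", "reference", "embryo"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  # samples not named in the role map default to embryos
  missing <- setdiff(samples, names(roles))
  if (length(missing)) roles[missing] <- "embryo"
  extra <- setdiff(names(roles), samples)
  if (length(extra))
    stop("role map names samples absent from the table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (r in c("father", "mother", "reference"))
    if (sum(roles == r) != 1L)
      stop("exactly one sample must have role '", r, "' (got ",
           sum(roles == r), ")", call. = FALSE)
  roles[samples]  # table column order
}

#' Sample name holding a given role
#' @param table a [snp_table()].
#' @param role one of `"father"`, `"mother"`, `"reference"`, `"embryo"`.
#' @return character vector of sample names (length 1 except for embryos).
#' @export
role_sample <- function(table, role) {
  names(table$roles)[table$roles == role]
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x$sites), "biallelic SNP sites x",
      ncol(x$geno), "samples\n")
  cat("  samples:", paste(sprintf("%s[%s]", names(x$roles), x$roles),
                          collapse = ", "), "\n")
  if (nrow(x$sites))
    cat("  span: ", x$sites$chrom[1], ":", format(min(x$sites$pos), big.mark = ","),
        "-", format(max(x$sites$pos), big.mark = ","), "\n", sep = "")
  fl <- attr(x, "filter_log")
  if (!is.null(fl))
    cat("  filter:", fl$n_in, "sites in,", fl$n_out, "retained\n")
  invisible(x)
}

#' Subset a snp_table to a set of site rows
#' @keywords internal
#' @noRd
subset_sites <- function(table, keep) {
  out <- table
  out$sites <- table$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$geno <- table$geno[keep, , drop = FALSE]
  out$depth <- table$depth[keep, , drop = FALSE]
  out
}
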