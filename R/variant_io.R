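# VCF input/output and the region + depth filter.
#
# Reading goes through vcfR; writing is a plain-text VCF 4.2 formatter so
# that simulated families round-trip losslessly through load_vcf().

#' Load a multi-sample VCF into a snp_table
#'
#' Reads a VCF 4.2 file holding the father, mother, phase-reference and
#' embryo samples, keeps biallelic SNP records only (multiallelic and
#' indel/other records are excluded and counted), and normalises genotypes
#' into the collapsed encoding of [snp_table()]. Both hemizygous-male VCF
#' dialects are accepted: a haploid `GT` (`"0"`) and a homozygous-diploid
#' `GT` (`"0/0"`) both become the single-allele call `"0"`. A heterozygous
#' call in the father or reference sample (impossible on a male X, so an
#' artifact) is set to no-call and counted.
#'
#' @param path path to a VCF file (plain text or bgzip).
#' @param roles named character vector mapping sample names to roles
#'   (`"father"`, `"mother"`, `"reference"`, `"embryo"`); samples present in
#'   the VCF but absent from the map are treated as embryos.
#' @return a [snp_table()]; attribute `"excluded"` records exclusion counts.
#' @export
load_vcf <- function(path, roles) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no records", call. = FALSE)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  is_snp <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  n_excluded <- sum(!is_snp)
  if (n_excluded > 0)
    message("load_vcf: excluded ", n_excluded,
            " non-SNP or multiallelic record(s)")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(dp)) {
    warning("no DP field in VCF; depths set to NA (sites will fail depth gating)")
    dp <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  }
  keep <- which(is_snp)
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.numeric(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  gt <- gt[keep, , drop = FALSE]
  dp <- dp[keep, , drop = FALSE]

  ord <- order(sites$pos)
  dup <- duplicated(sites$pos[ord])
  if (any(dup)) {
    message("load_vcf: dropped ", sum(dup), " duplicate-position record(s)")
    ord <- ord[!dup]
  }
  sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
  gt <- gt[ord, , drop = FALSE]; dp <- dp[ord, , drop = FALSE]

  geno <- apply(gt, 2, normalize_gt)
  if (nrow(gt) == 1L) geno <- matrix(geno, nrow = 1L, dimnames = dimnames(gt))
  roles <- check_roles(roles, colnames(geno))

  # hemizygous-male samples cannot be heterozygous on chrX
  n_male_het <- 0L
  for (s in names(roles)[roles %in% c("father", "reference")]) {
    bad <- which(is_het(geno[, s]))
    if (length(bad)) {
      n_male_het <- n_male_het + length(bad)
      geno[bad, s] <- NA_character_
    }
  }
  if (n_male_het > 0)
    message("load_vcf: set ", n_male_het,
            " heterozygous call(s) in male samples to no-call")

  out <- snp_table(sites, geno, dp, roles)
  attr(out, "excluded") <- list(non_snp = n_excluded, male_het = n_male_het)
  out
}

# "0/0", "0|0", "0" -> "0"; "0/1", "1|0" -> "0/1"; "./.", ".", NA -> NA
normalize_gt <- function(g) {
  out <- rep(NA_character_, length(g))
  g <- gsub("|", "/", g, fixed = TRUE)
  nz <- !is.na(g) & g != "." & g != "./."
  al <- strsplit(g[nz], "/", fixed = TRUE)
  out[nz] <- vapply(al, function(a) {
    a <- sort(unique(a[a != "."]))
    if (length(a) == 0 || any(!a %in% c("0", "1"))) NA_character_
    else if (length(a) == 1) a else "0/1"
  }, character(1))
  out
}

#' Write a snp_table as a VCF 4.2 file
#'
#' Emits one record per site with `GT:DP` per sample. Diploid samples
#' (mother, embryos of unknown sex) are written in diploid notation
#' (`0/0`, `0/1`, ...); the known-male father and reference samples are
#' written in the chosen hemizygous dialect. Round-trips losslessly through
#' [load_vcf()].
#'
#' @param table a [snp_table()].
#' @param path output file path.
#' @param male_gt_dialect `"haploid"` (`GT` = `"0"`) or `"diploid"`
#'   (`GT` = `"0/0"`) encoding for the father and reference samples.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(table, path,
                             male_gt_dialect = c("haploid", "diploid")) {
  stopifnot(inherits(table, "snp_table"))
  male_gt_dialect <- match.arg(male_gt_dialect)
  if (nrow(table$sites) == 0) stop("cannot write an empty snp_table", call. = FALSE)
  samples <- names(table$roles)
  male <- table$roles %in% c("father", "reference")

  fmt_gt <- function(g, is_male) {
    if (is.na(g)) return(if (is_male && male_gt_dialect == "haploid") "." else "./.")
    if (g == "0/1") return("0/1")
    if (is_male) {
      if (male_gt_dialect == "haploid") g else paste0(g, "/", g)
    } else paste0(g, "/", g)
  }
  fmt_dp <- function(d) ifelse(is.na(d), ".", format(as.integer(round(d))))

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", table$sites$chrom[1], ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  n <- nrow(table$sites)
  sample_cols <- vapply(seq_along(samples), function(j) {
    gts <- vapply(seq_len(n), function(i) fmt_gt(table$geno[i, j], male[j]),
                  character(1))
    paste0(gts, ":", fmt_dp(table$depth[, j]))
  }, character(n))
  if (n == 1L) sample_cols <- matrix(sample_cols, nrow = 1L)
  body <- paste(table$sites$chrom, format(table$sites$pos, scientific = FALSE,
                                          trim = TRUE),
                ".", table$sites$ref, table$sites$alt, ".", "PASS", ".",
                "GT:DP", apply(sample_cols, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Apply the analysis-window and sequencing-depth filter
#'
#' Retains sites lying in the closed window
#' `[gene_start - window_flank, gene_end + window_flank]` whose depth is
#' strictly greater than `min_depth` in the father, the mother and the
#' reference sample. The strict inequality (`> 10x`, not `>= 10x`) is the
#' usability convention for the parental/reference genomic DNA. Embryo
#' depths are deliberately not gated here: a WGA dropout in one embryo must
#' not discard the marker for all embryos, so embryo depth is applied
#' per-embryo during support counting.
#'
#' Genotype values are never altered; the output site set is a subset of the
#' input, and the filter is idempotent.
#'
#' @param table a [snp_table()].
#' @param locus a [target_locus()].
#' @param min_depth usability threshold; a site is kept only where depth
#'   `> min_depth` in all three gDNA samples. Default 10.
#' @return the filtered [snp_table()]; attribute `"filter_log"` records
#'   input/output counts. An empty result is allowed with a warning.
#' @export
apply_region_depth_filter <- function(table, locus, min_depth = 10) {
  stopifnot(inherits(table, "snp_table"), inherits(locus, "target_locus"))
  if (!is.numeric(min_depth) || min_depth < 0)
    stop("min_depth must be >= 0", call. = FALSE)
  win <- locus_window(locus)
  in_window <- table$sites$chrom == locus$chrom &
    table$sites$pos >= win[1] & table$sites$pos <= win[2]
  gdna <- c(role_sample(table, "father"), role_sample(table, "mother"),
            role_sample(table, "reference"))
  d <- table$depth[, gdna, drop = FALSE]
  d[is.na(d)] <- 0
  deep_enough <- rowSums(d > min_depth) == length(gdna)
  keep <- in_window & deep_enough
  out <- subset_sites(table, keep)
  attr(out, "excluded") <- attr(table, "excluded")
  attr(out, "filter_log") <- list(
    n_in = nrow(table$sites), n_out = sum(keep),
    n_outside_window = sum(!in_window),
    n_low_depth = sum(in_window & !deep_enough),
    min_depth = min_depth, window = win)
  if (sum(keep) == 0)
    warning("no sites survive the region/depth filter; ",
            "downstream calls will be Undetermined")
  out
}
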