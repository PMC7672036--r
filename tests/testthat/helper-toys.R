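# Shared toy builders and independent brute-force oracles.
# The oracles re-derive expected results with straight-line per-site logic,
# independent of the package's implementation paths.

# Build a snp_table from genotype vectors ("0", "1", "0/1", NA).
# `embryos` is a named list of genotype vectors; depths default uniform.
toy_table <- function(mother, father, reference, embryos = list(),
                      pos = NULL, depth = 30, chrom = "chrX") {
  n <- length(mother)
  pos <- pos %||% (123400000 + seq_len(n) * 1000)
  geno <- cbind(father = father, mother = mother, reference = reference)
  for (nm in names(embryos)) geno <- cbind(geno, embryos[[nm]])
  colnames(geno) <- c("father", "mother", "reference", names(embryos))
  if (length(depth) == 1) depth <- matrix(depth, n, ncol(geno))
  colnames(depth) <- colnames(geno)
  roles <- setNames(c("father", "mother", "reference",
                      rep("embryo", length(embryos))), colnames(geno))
  snp_table(data.frame(chrom = chrom, pos = pos,
                       ref = "A", alt = "G", stringsAsFactors = FALSE),
            geno, depth, roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_locus <- function(reference_status = "affected", flank = 1e6) {
  target_locus(gene_start = 123480000, gene_end = 123507000,
               mutation_pos = 123499000, mutation_ref = "G",
               mutation_alt = "A", window_flank = flank,
               reference_status = reference_status, gene_name = "SH2D1A")
}

# Independent per-site informativeness oracle.
oracle_classify <- function(mother, father, reference) {
  n <- length(mother)
  out <- data.frame(informative = logical(n), x1 = NA_character_,
                    x2 = NA_character_, father = NA_character_,
                    class = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    mo <- mother[i]; re <- reference[i]; fa <- father[i]
    if (is.na(mo) || mo != "0/1") next
    if (is.na(re) || !re %in% c("0", "1")) next
    out$informative[i] <- TRUE
    out$x1[i] <- re
    out$x2[i] <- if (re == "0") "1" else "0"
    if (!is.na(fa) && fa %in% c("0", "1")) {
      out$father[i] <- fa
      out$class[i] <- if (fa == out$x1[i]) "x2_detecting" else "x1_detecting"
    } else out$class[i] <- "male_only"
  }
  out
}

# Independent per-site support-counting oracle.
oracle_count <- function(geno, depth, oc, sex, min_depth = 10) {
  f_x <- 0L; m1 <- 0L; m2 <- 0L
  for (i in seq_along(geno)) {
    if (!oc$informative[i]) next
    g <- geno[i]
    if (is.na(g) || is.na(depth[i]) || depth[i] <= min_depth) next
    vote <- NULL
    if (sex == "F") {
      if (oc$class[i] == "male_only") next
      f <- oc$father[i]
      if (g == "0/1") {
        m <- setdiff(c("0", "1"), f)
        vote <- m
        f_x <- f_x + 1L
      } else if (g != f) vote <- g
    } else {
      if (g %in% c("0", "1")) vote <- g
    }
    if (!is.null(vote)) {
      if (vote == oc$x1[i]) m1 <- m1 + 1L else m2 <- m2 + 1L
    }
  }
  list(f_x = f_x, m_x1 = m1, m_x2 = m2)
}
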