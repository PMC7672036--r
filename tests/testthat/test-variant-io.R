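test_that("a simulated family round-trips losslessly through VCF in both male dialects", {
  fam <- simulate_family(sim_config(n_snps = 70, n_embryos = 3, seed = 9))
  roles <- c(father = "father", mother = "mother", reference = "reference")
  for (dialect in c("haploid", "diploid")) {
    path <- tempfile(fileext = ".vcf")
    write_family_vcf(fam$table, path, male_gt_dialect = dialect)
    back <- suppressMessages(load_vcf(path, roles))
    expect_identical(back$sites, fam$table$sites)
    expect_identical(back$geno, fam$table$geno)
    expect_equal(unname(back$depth), unname(fam$table$depth * 1.0))
    expect_identical(back$roles, fam$table$roles)
  }
})

test_that("the VCF writer emits one record per site and one column per sample", {
  tab <- toy_table(mother = c("0/1", "0/1", "0"),
                   father = c("0", "1", "0"),
                   reference = c("1", "0", "0"),
                   embryos = list(embryo_1 = c("1", NA, "0")))
  path <- tempfile(fileext = ".vcf")
  write_family_vcf(tab, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 3)
  header <- lines[startsWith(lines, "#CHROM")]
  expect_length(strsplit(header, "\t")[[1]], 9 + 4)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
})

test_that("non-SNP and multiallelic records are excluded and both male dialects normalise", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrX>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "dad", "mum", "kid"), collapse = "\t"),
    "chrX\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/0:30\t0/1:25\t0:20",
    "chrX\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1:30\t0/0:25\t1/1:20",
    "chrX\t300\t.\tG\tGA\t.\tPASS\t.\tGT:DP\t0:30\t0/1:25\t0:20",   # indel
    "chrX\t400\t.\tT\tA,C\t.\tPASS\t.\tGT:DP\t1:30\t1/2:25\t1:20",  # multiallelic
    "chrX\t500\t.\tG\tC\t.\tPASS\t.\tGT:DP\t0|1:30\t1|0:25\t./.:.",
    "chrX\t600\t.\tA\tT\t.\tPASS\t.\tGT:DP\t.\t0/1:25\t0/0:18",
    "chrX\t700\t.\tC\tG\t.\tPASS\t.\tGT:DP\t0/0:9\t0/1:25\t1:20")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  roles <- c(dad = "father", mum = "mother", kid = "reference")
  msgs <- capture_messages(tab <- load_vcf(path, roles))
  expect_true(any(grepl("excluded 2", msgs)))
  expect_equal(tab$sites$pos, c(100, 200, 500, 600, 700))
  # homozygous-diploid and haploid male calls both collapse to one allele
  expect_identical(unname(tab$geno[, "dad"]),
                   c("0", "1", NA, NA, "0"))
  # a heterozygous call in a male sample is an artifact -> no-call
  expect_identical(unname(tab$geno[1, "kid"]), "0")
  expect_identical(unname(tab$geno[, "mum"]),
                   c("0/1", "0", "0/1", "0/1", "0/1"))
  expect_true(is.na(tab$geno[3, "kid"]))  # ./. stays a no-call
  expect_true(is.na(tab$depth[3, "kid"]))
  expect_identical(attr(tab, "excluded")$non_snp, 2L)
})

test_that("a heterozygous father call is nulled with a log message", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrX>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "dad", "mum", "ref"), collapse = "\t"),
    "chrX\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:30\t0/1:25\t0:20")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  msgs <- capture_messages(
    tab <- load_vcf(path, c(dad = "father", mum = "mother", ref = "reference")))
  expect_true(any(grepl("heterozygous", msgs)))
  expect_true(is.na(tab$geno[1, "dad"]))
})

test_that("missing roles are a configuration error; spare samples become embryos", {
  fam <- simulate_family(sim_config(n_snps = 10, n_embryos = 2, seed = 4))
  path <- tempfile(fileext = ".vcf")
  write_family_vcf(fam$table, path)
  expect_error(load_vcf(path, c(father = "father", mother = "mother")),
               "reference")
  tab <- load_vcf(path, c(father = "father", mother = "mother",
                          reference = "reference"))
  expect_identical(unname(tab$roles[c("embryo_1", "embryo_2")]),
                   c("embryo", "embryo"))
  expect_error(load_vcf(tempfile(), c(father = "father")), "not found")
})

test_that("window bounds are closed and the depth gate is strictly greater-than", {
  locus <- toy_locus(flank = 1000)
  win <- locus_window(locus)
  pos <- c(win[1] - 1, win[1], win[2], win[2] + 1)
  tab <- toy_table(mother = rep("0/1", 4), father = rep("0", 4),
                   reference = rep("1", 4), pos = pos)
  out <- apply_region_depth_filter(tab, locus, min_depth = 10)
  expect_equal(out$sites$pos, c(win[1], win[2]))

  # mother depth exactly at the threshold fails the strict > gate
  depth <- matrix(30, 1, 3, dimnames = list(NULL, c("father", "mother", "reference")))
  tab2 <- toy_table(mother = "0/1", father = "0", reference = "1",
                    pos = win[1] + 5, depth = depth)
  tab2$depth[1, "mother"] <- 10
  expect_warning(out2 <- apply_region_depth_filter(tab2, locus, min_depth = 10),
                 "no sites")
  expect_equal(nrow(out2$sites), 0)
  tab2$depth[1, "mother"] <- 11
  out3 <- apply_region_depth_filter(tab2, locus, min_depth = 10)
  expect_equal(nrow(out3$sites), 1)
})

test_that("the filter matches a site-by-site oracle, is idempotent, and never edits genotypes", {
  set.seed(42)
  locus <- toy_locus(flank = 50000)
  win <- locus_window(locus)
  n <- 200
  pos <- sort(sample(seq(win[1] - 20000, win[2] + 20000), n))
  tab <- toy_table(mother = sample(c("0/1", "0", "1"), n, TRUE),
                   father = sample(c("0", "1", NA), n, TRUE),
                   reference = sample(c("0", "1"), n, TRUE),
                   embryos = list(embryo_1 = sample(c("0", "1", "0/1", NA), n, TRUE)),
                   pos = pos,
                   depth = matrix(rpois(n * 4, 14), n, 4))
  out <- apply_region_depth_filter(tab, locus, min_depth = 10)
  keep_oracle <- vapply(seq_len(n), function(i) {
    pos[i] >= win[1] && pos[i] <= win[2] &&
      tab$depth[i, "father"] > 10 && tab$depth[i, "mother"] > 10 &&
      tab$depth[i, "reference"] > 10
  }, logical(1))
  expect_equal(out$sites$pos, pos[keep_oracle])
  expect_identical(out$geno, tab$geno[keep_oracle, , drop = FALSE])

  twice <- apply_region_depth_filter(out, locus, min_depth = 10)
  expect_identical(twice$sites, out$sites)
  expect_identical(twice$geno, out$geno)
  fl <- attr(out, "filter_log")
  expect_equal(fl$n_in, n)
  expect_equal(fl$n_out, sum(keep_oracle))
})
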