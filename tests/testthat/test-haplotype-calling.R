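make_phase <- function(tab, status = "affected") {
  suppressWarnings(classify_sites(tab, toy_locus(reference_status = status)))$phase
}

test_that("an embryo with no usable data accrues zero support", {
  tab <- toy_table(mother = rep("0/1", 5), father = rep("0", 5),
                   reference = rep("1", 5),
                   embryos = list(embryo_1 = rep(NA_character_, 5)))
  phase <- make_phase(tab)
  cnt <- count_support(tab, "embryo_1", phase, sex = "M")
  expect_equal(c(cnt$f_x, cnt$m_x1, cnt$m_x2), c(0, 0, 0))
  expect_true(all(cnt$sites$support == "no-call"))
  # and an empty phase gives zero counts too
  empty <- make_phase(toy_table(mother = "0", father = "0", reference = "0",
                                embryos = list(embryo_1 = "0")))
  cnt2 <- count_support(tab, "embryo_1", empty, sex = "M")
  expect_equal(c(cnt2$f_x, cnt2$m_x1, cnt2$m_x2), c(0, 0, 0))
})

test_that("a clean male embryo votes for its transmitted haplotype at every usable site", {
  fam <- simulate_family(sim_config(n_snps = 400, n_embryos = 12,
                                    ado_rate = 0, adi_rate = 0,
                                    sample_fail_rate = 0,
                                    recomb_rate_per_mb = 0, seed = 14))
  filtered <- apply_region_depth_filter(fam$table, fam$locus)
  phase <- classify_sites(filtered, fam$locus)$phase
  males <- fam$truth$embryos$id[fam$truth$embryos$sex == "M"]
  expect_gt(length(males), 0)
  e <- males[1]
  lab <- unique(fam$truth$transmitted[, e])
  cnt <- count_support(filtered, e, phase, sex = "M")
  usable <- sum(filtered$depth[match(phase$pos, filtered$sites$pos), e] > 10)
  if (lab == "X1") {
    expect_equal(cnt$m_x1, usable)
    expect_equal(cnt$m_x2, 0)
  } else {
    expect_equal(cnt$m_x2, usable)
    expect_equal(cnt$m_x1, 0)
  }
})

test_that("in noisy females every contradicting vote traces to a recorded WGA artifact", {
  fam <- simulate_family(sim_config(n_snps = 250, n_embryos = 10,
                                    ado_rate = 0.08, adi_rate = 0.01,
                                    sample_fail_rate = 0,
                                    recomb_rate_per_mb = 0, seed = 26))
  filtered <- apply_region_depth_filter(fam$table, fam$locus)
  phase <- classify_sites(filtered, fam$locus)$phase
  emb <- fam$truth$embryos
  for (j in which(emb$sex == "F")) {
    e <- emb$id[j]
    cnt <- count_support(filtered, e, phase, sex = "F")
    votes <- cnt$sites[cnt$sites$support %in% c("X1", "X2"), ]
    truth_lab <- fam$truth$transmitted[match(votes$pos, fam$truth$maternal$pos), e]
    wrong <- votes$pos[votes$support != truth_lab]
    corrupted <- c(fam$truth$ado_sites[[e]], fam$truth$adi_sites[[e]])
    expect_true(all(wrong %in% corrupted))
  }
})

test_that("support counting agrees with the brute-force oracle under both sex hypotheses", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 40
    tab <- toy_table(mother = sample(c("0/1", "0", "1"), n, TRUE),
                     father = sample(c("0", "1", NA), n, TRUE),
                     reference = sample(c("0", "1", NA), n, TRUE),
                     embryos = list(e = sample(c("0", "1", "0/1", NA), n, TRUE)),
                     depth = matrix(rpois(n * 4, 14), n, 4))
    phase <- make_phase(tab)
    oc <- oracle_classify(tab$geno[, "mother"], tab$geno[, "father"],
                          tab$geno[, "reference"])
    for (sex in c("M", "F")) {
      cnt <- count_support(tab, "e", phase, sex = sex)
      exp <- oracle_count(tab$geno[, "e"], tab$depth[, "e"], oc, sex)
      expect_equal(cnt$f_x, exp$f_x)
      expect_equal(cnt$m_x1, exp$m_x1)
      expect_equal(cnt$m_x2, exp$m_x2)
    }
  }
})

test_that("sex inference: SRY flag is authoritative, SNP evidence sexes clean embryos, no data is unknown", {
  tab <- toy_table(mother = rep("0/1", 5), father = rep("0", 5),
                   reference = rep("1", 5),
                   embryos = list(e = rep(NA_character_, 5)))
  phase <- make_phase(tab)
  expect_identical(infer_sex(tab, "e", phase, sry = TRUE), "M")
  expect_identical(infer_sex(tab, "e", phase, sry = FALSE), "F")
  expect_identical(infer_sex(tab, "e", phase), "unknown")

  fam <- simulate_family(sim_config(n_snps = 200, n_embryos = 20,
                                    sample_fail_rate = 0, seed = 18))
  filtered <- apply_region_depth_filter(fam$table, fam$locus)
  phase2 <- classify_sites(filtered, fam$locus)$phase
  inferred <- vapply(fam$truth$embryos$id, function(e)
    infer_sex(filtered, e, phase2), character(1))
  expect_identical(unname(inferred), fam$truth$embryos$sex)
})

test_that("embryo calls reproduce the published worked examples", {
  # male, overwhelming X1 support, mutation on X2 => Normal
  c1 <- call_embryo(support_counts(0, 137, 1), sex = "M", mutant_linked = "X2")
  expect_identical(c1$haplotype, "X1")
  expect_identical(c1$disposition, "Normal")
  # no data
  c2 <- call_embryo(support_counts(0, 0, 0), sex = "F", mutant_linked = "X2")
  expect_identical(c2$disposition, "Undetermined")
  expect_identical(c2$reason, "no_data")
  # exact tie cannot be called
  c3 <- call_embryo(support_counts(0, 50, 50), sex = "F", mutant_linked = "X2")
  expect_identical(c3$disposition, "Undetermined")
  expect_identical(c3$reason, "tie")
  # modest but clean support is callable
  c4 <- call_embryo(support_counts(2, 26, 0), sex = "F", mutant_linked = "X2")
  expect_identical(c4$haplotype, "X1")
  expect_identical(c4$disposition, "Normal")
  # inheriting the mutant-linked haplotype: Affected male, Carrier female
  expect_identical(call_embryo(support_counts(0, 137, 1), sex = "M",
                               mutant_linked = "X1")$disposition, "Affected")
  expect_identical(call_embryo(support_counts(1, 90, 0), sex = "F",
                               mutant_linked = "X1")$disposition, "Carrier")
  # mutant haplotype with unknown sex cannot be placed
  expect_identical(call_embryo(support_counts(0, 90, 0), sex = "unknown",
                               mutant_linked = "X1")$disposition, "Undetermined")
  # below the support threshold
  expect_identical(call_embryo(support_counts(0, 9, 0), sex = "M",
                               mutant_linked = "X2")$reason,
                   "insufficient_support")
  # too much contradiction
  expect_identical(call_embryo(support_counts(0, 80, 20), sex = "M",
                               mutant_linked = "X2")$reason, "excess_minority")
})

test_that("relabelling X1<->X2 with flipped polarity leaves the disposition invariant", {
  set.seed(11)
  for (rep in 1:50) {
    m1 <- rpois(1, 40); m2 <- rpois(1, 3)
    sex <- sample(c("M", "F"), 1)
    mut <- sample(c("X1", "X2"), 1)
    a <- call_embryo(support_counts(0, m1, m2), sex = sex, mutant_linked = mut)
    b <- call_embryo(support_counts(0, m2, m1), sex = sex,
                     mutant_linked = if (mut == "X1") "X2" else "X1")
    expect_identical(a$disposition, b$disposition)
    if (a$haplotype != "none")
      expect_identical(b$haplotype, if (a$haplotype == "X1") "X2" else "X1")
  }
})

test_that("growing the winning count never un-calls an embryo", {
  set.seed(13)
  for (rep in 1:30) {
    minority <- sample(0:3, 1)
    w0 <- sample(10:40, 1)
    base <- call_embryo(support_counts(0, w0, minority), sex = "M",
                        mutant_linked = "X2")
    if (base$haplotype == "none") next
    for (w in w0 + c(1, 10, 100)) {
      grown <- call_embryo(support_counts(0, w, minority), sex = "M",
                           mutant_linked = "X2")
      expect_identical(grown$haplotype, base$haplotype)
    }
  }
})

test_that("recombination detection finds constructed and simulated switches", {
  pos <- 123400000 + (1:40) * 1000
  one_run <- data.frame(pos = pos[1:20], support = rep("X1", 20))
  r0 <- detect_recombination(one_run)
  expect_equal(nrow(r0$breakpoints), 0)

  switch <- data.frame(pos = pos, support = rep(c("X1", "X2"), each = 20))
  r1 <- detect_recombination(switch)
  expect_equal(nrow(r1$breakpoints), 1)
  expect_equal(r1$breakpoints$left_pos, pos[20])
  expect_equal(r1$breakpoints$right_pos, pos[21])

  # an isolated contradicting site is noise, not a breakpoint
  noisy <- switch; noisy$support[10] <- "X2"
  r2 <- detect_recombination(noisy)
  expect_equal(nrow(r2$breakpoints), 1)

  # a switch right at the mutation position poisons the call
  r3 <- detect_recombination(switch, mutation_pos = (pos[20] + pos[21]) / 2)
  expect_true(r3$mutation_flag)
  # a mutation deep inside a long segment is safe
  r4 <- detect_recombination(switch, mutation_pos = pos[5])
  expect_false(r4$mutation_flag)

  # simulated single-crossover embryo: the reported interval contains the truth
  fam <- simulate_family(sim_config(n_snps = 300, n_embryos = 30,
                                    recomb_rate_per_mb = 0.4,
                                    ado_rate = 0, adi_rate = 0,
                                    sample_fail_rate = 0, seed = 62))
  filtered <- apply_region_depth_filter(fam$table, fam$locus)
  phase <- classify_sites(filtered, fam$locus)$phase
  checked <- 0
  for (e in fam$truth$embryos$id) {
    xov <- fam$truth$crossovers[[e]]
    if (length(xov) != 1) next
    sex <- fam$truth$embryos$sex[fam$truth$embryos$id == e]
    cnt <- count_support(filtered, e, phase, sex = sex)
    # detectability precondition: enough voting sites flank the crossover
    votes <- cnt$sites$pos[cnt$sites$support %in% c("X1", "X2")]
    if (sum(votes < xov) < 5 || sum(votes > xov) < 5) next
    det <- detect_recombination(cnt$sites)
    expect_gte(nrow(det$breakpoints), 1)
    expect_true(any(det$breakpoints$left_pos <= xov &
                    det$breakpoints$right_pos >= xov))
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("direct mutation + SRY interpretation covers the clinical decision table", {
  calls <- interpret_direct_test(
    mutation_genotype = c("alt", "ref", "het", "ref", "failed", "alt"),
    sry_present = c(TRUE, TRUE, FALSE, FALSE, NA, TRUE),
    id = paste0("E", 1:6))
  expect_identical(calls$disposition,
                   c("Affected", "Normal", "Carrier", "Normal",
                     "Undetermined", "Affected"))
  expect_identical(calls$sex, c("M", "M", "F", "F", "unknown", "M"))
  expect_identical(calls$reason[5], "failed_amplification")

  # SRY-positive heterozygote is contamination evidence, not a call
  expect_error(interpret_direct_test("het", TRUE), "contamination")
  # SRY-negative mutant-only is flagged, not silently resolved
  expect_warning(amb <- interpret_direct_test("alt", FALSE), "drop-out")
  expect_identical(amb$disposition, "Undetermined")
})
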