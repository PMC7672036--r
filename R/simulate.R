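# Synthetic X-linked family generator.
#
# Produces the same inputs the real pipeline consumes (a multi-sample
# snp_table / VCF) together with a full ground-truth record, so that every
# downstream step can be tested against known answers: maternal phase,
# transmitted haplotypes, crossover positions, and the exact sites hit by
# WGA artifacts.

#' Configuration for the synthetic family simulator
#'
#' Defaults describe a realistic clinical PGH workup for an X-linked
#' recessive locus: a ~2 Mb marker window centred on the gene, roughly half
#' of the SNPs heterozygous in the mother, single-blastomere WGA samples
#' with per-allele drop-out below 10%, rare drop-in, an occasional
#' whole-sample amplification failure, target-capture depths well above the
#' 10x usability threshold, and the genome-average X-chromosome
#' recombination rate.
#'
#' @param n_snps number of biallelic X SNPs simulated in the window.
#' @param window_span width (bp) of the marker window centred on the gene.
#' @param maternal_het_fraction probability a site is heterozygous in the
#'   mother.
#' @param ado_rate per-allele drop-out probability in embryo WGA samples.
#' @param adi_rate per-site allele drop-in probability in embryo WGA samples.
#' @param sample_fail_rate probability an embryo sample yields no data at all.
#' @param recomb_rate_per_mb expected crossovers per Mb per meiosis
#'   (Haldane: Poisson count, uniform positions, no interference).
#' @param depth_mean mean per-site read depth (Poisson).
#' @param depth_min_usable depth usability threshold (sites at or below it
#'   are emitted but fail the `> depth_min_usable` gate downstream).
#' @param n_embryos number of embryo biopsy samples.
#' @param embryo_sex_prob_female probability an embryo is female.
#' @param male_gt_dialect VCF encoding used for hemizygous-male genotypes
#'   when the family is written out: `"haploid"` or `"diploid"`.
#' @param reference_status disease status of the phase-reference sample
#'   (`"affected"` proband anchor or `"unaffected"` villus-type anchor).
#' @param seed integer RNG seed; a fixed seed makes the output bit-identical
#'   across runs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 600, window_span = 2e6,
                       maternal_het_fraction = 0.5,
                       ado_rate = 0.08, adi_rate = 0.005,
                       sample_fail_rate = 0.1,
                       recomb_rate_per_mb = 0.013,
                       depth_mean = 50, depth_min_usable = 10,
                       n_embryos = 10, embryo_sex_prob_female = 0.5,
                       male_gt_dialect = c("haploid", "diploid"),
                       reference_status = c("affected", "unaffected"),
                       seed = 1L) {
  cfg <- list(n_snps = n_snps, window_span = window_span,
              maternal_het_fraction = maternal_het_fraction,
              ado_rate = ado_rate, adi_rate = adi_rate,
              sample_fail_rate = sample_fail_rate,
              recomb_rate_per_mb = recomb_rate_per_mb,
              depth_mean = depth_mean, depth_min_usable = depth_min_usable,
              n_embryos = n_embryos,
              embryo_sex_prob_female = embryo_sex_prob_female,
              male_gt_dialect = match.arg(male_gt_dialect),
              reference_status = match.arg(reference_status),
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("sim_config field '", field, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  for (f in c("maternal_het_fraction", "ado_rate", "adi_rate",
              "sample_fail_rate", "embryo_sex_prob_female")) chk_prob(f)
  chk_pos <- function(field, min) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min)
      stop("sim_config field '", field, "' must be a number >= ", min,
           call. = FALSE)
  }
  chk_pos("n_snps", 1); chk_pos("window_span", 1)
  chk_pos("recomb_rate_per_mb", 0); chk_pos("depth_mean", 0)
  chk_pos("depth_min_usable", 0); chk_pos("n_embryos", 0)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop("sim_config field 'seed' must be a single integer", call. = FALSE)
  invisible(cfg)
}

#' Simulate an X-linked family with known ground truth
#'
#' Generates a family of father, mother, phase-reference sample and embryo
#' biopsies at `n_snps` biallelic SNPs in a window centred on an
#' SH2D1A-like Xq25 locus. The mother is heterozygous at roughly
#' `maternal_het_fraction` of sites, with her two haplotype phases (X1/X2)
#' drawn at random; the father and reference are hemizygous. The reference
#' carries maternal haplotype X1 by construction. Each embryo receives a
#' maternal gamete recombined under a Haldane (Poisson, no interference)
#' crossover process; female embryos additionally carry the paternal X.
#' Observed embryo genotypes are the truth corrupted by per-allele drop-out,
#' per-site drop-in, and whole-sample amplification failure; per-site read
#' depths are Poisson around `depth_mean` for every sample.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_family` with elements `table`
#'   (a [snp_table()]), `locus` (a [target_locus()]) and `truth`
#'   (class `family_truth`; see Details).
#' @details The `truth` record holds, per embryo: true sex, transmitted
#'   maternal haplotype at the mutation position, crossover positions, true
#'   disposition, whole-sample failure flag, and per-site lists of
#'   drop-out/drop-in events; plus the maternal phase itself, the per-site
#'   transmitted-haplotype labels, and allele-level drop-out tallies used by
#'   estimator-recovery tests.
#' @export
simulate_family <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, simulate_family_impl(config))
}

simulate_family_impl <- function(cfg) {
  gene_start <- 123480000; gene_end <- 123507000
  centre <- (gene_start + gene_end) / 2
  flank <- ceiling((cfg$window_span - (gene_end - gene_start + 1)) / 2)
  if (flank < 0) flank <- 0
  locus <- target_locus(chrom = "chrX", gene_start = gene_start,
                        gene_end = gene_end, mutation_pos = 123499000,
                        mutation_ref = "G", mutation_alt = "A",
                        window_flank = flank,
                        reference_status = cfg$reference_status,
                        gene_name = "SH2D1A")
  win <- locus_window(locus)

  pos <- sort(sample.int(win[2] - win[1] + 1, cfg$n_snps)) + win[1] - 1
  pos <- pos[pos != locus$mutation_pos]
  n <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  # maternal phase: two haplotypes of allele indices
  het <- stats::rbinom(n, 1, cfg$maternal_het_fraction) == 1
  hap1 <- character(n); hap2 <- character(n)
  hom_allele <- as.character(stats::rbinom(n, 1, 0.5))
  hap1[!het] <- hom_allele[!het]; hap2[!het] <- hom_allele[!het]
  flip <- stats::rbinom(n, 1, 0.5) == 1   # which haplotype gets the ref allele
  hap1[het] <- ifelse(flip[het], "0", "1")
  hap2[het] <- other_allele(hap1[het])

  father <- as.character(stats::rbinom(n, 1, 0.5))
  mother <- ifelse(het, "0/1", hom_allele)
  reference <- hap1   # defines X1

  window_mb <- (win[2] - win[1] + 1) / 1e6
  mutant <- mutant_linked_label(cfg$reference_status)

  n_emb <- cfg$n_embryos
  emb_names <- if (n_emb > 0) paste0("embryo_", seq_len(n_emb)) else character(0)
  geno <- matrix(NA_character_, n, 3 + n_emb,
                 dimnames = list(NULL, c("father", "mother", "reference",
                                         emb_names)))
  geno[, "father"] <- father
  geno[, "mother"] <- mother
  geno[, "reference"] <- reference

  transmitted <- matrix(character(0), n, 0)
  if (n_emb > 0)
    transmitted <- matrix(NA_character_, n, n_emb,
                          dimnames = list(NULL, emb_names))
  emb <- data.frame(id = emb_names,
                    sex = character(n_emb), hap_at_mutation = character(n_emb),
                    disposition = character(n_emb),
                    failed = logical(n_emb), n_crossovers = integer(n_emb),
                    n_alleles_total = integer(n_emb),
                    n_alleles_dropped = integer(n_emb),
                    stringsAsFactors = FALSE)
  crossovers <- stats::setNames(vector("list", n_emb), emb_names)
  ado_sites <- stats::setNames(vector("list", n_emb), emb_names)
  adi_sites <- stats::setNames(vector("list", n_emb), emb_names)

  for (j in seq_len(n_emb)) {
    sex <- if (stats::runif(1) < cfg$embryo_sex_prob_female) "F" else "M"
    k <- stats::rpois(1, cfg$recomb_rate_per_mb * window_mb)
    xov <- sort(stats::runif(k, win[1], win[2]))
    start_hap <- sample(1:2, 1)
    seg <- (start_hap - 1 + findInterval(pos, xov)) %% 2 + 1  # 1 => X1, 2 => X2
    hap_lab <- c("X1", "X2")[seg]
    maternal_allele <- ifelse(seg == 1, hap1, hap2)

    hap_at_mut <- c("X1", "X2")[(start_hap - 1 + findInterval(locus$mutation_pos, xov)) %% 2 + 1]
    failed <- stats::runif(1) < cfg$sample_fail_rate

    obs <- rep(NA_character_, n)
    n_total <- 0L; n_dropped <- 0L
    ado_j <- integer(0); adi_j <- integer(0)
    if (!failed) {
      for (i in seq_len(n)) {
        true_alleles <- if (sex == "F") c(father[i], maternal_allele[i])
                        else maternal_allele[i]
        n_total <- n_total + length(true_alleles)
        kept <- true_alleles[stats::runif(length(true_alleles)) >= cfg$ado_rate]
        n_drop_i <- length(true_alleles) - length(kept)
        if (n_drop_i > 0) { n_dropped <- n_dropped + n_drop_i; ado_j <- c(ado_j, i) }
        seen <- unique(kept)
        if (stats::runif(1) < cfg$adi_rate) {
          spurious <- as.character(stats::rbinom(1, 1, 0.5))
          if (!spurious %in% seen) { seen <- c(seen, spurious); adi_j <- c(adi_j, i) }
        }
        obs[i] <- if (length(seen) == 0) NA_character_
                  else if (length(seen) == 1) seen
                  else "0/1"
      }
    }
    geno[, emb_names[j]] <- obs
    transmitted[, j] <- hap_lab
    emb$sex[j] <- sex
    emb$hap_at_mutation[j] <- hap_at_mut
    emb$disposition[j] <- true_disposition(sex, hap_at_mut, mutant)
    emb$failed[j] <- failed
    emb$n_crossovers[j] <- k
    emb$n_alleles_total[j] <- n_total
    emb$n_alleles_dropped[j] <- n_dropped
    crossovers[[j]] <- xov
    ado_sites[[j]] <- pos[ado_j]
    adi_sites[[j]] <- pos[adi_j]
  }

  depth <- matrix(stats::rpois(n * ncol(geno), cfg$depth_mean), n, ncol(geno),
                  dimnames = dimnames(geno))
  if (n_emb > 0) {
    fail_cols <- emb_names[emb$failed]
    depth[, fail_cols] <- 0L
  }

  roles <- stats::setNames(c("father", "mother", "reference",
                             rep("embryo", n_emb)), colnames(geno))
  table <- snp_table(data.frame(chrom = "chrX", pos = pos, ref = ref,
                                alt = alt, stringsAsFactors = FALSE),
                     geno, depth, roles)

  truth <- structure(
    list(mutant_linked = mutant,
         maternal = data.frame(pos = pos, x1 = hap1, x2 = hap2,
                               stringsAsFactors = FALSE),
         father = father,
         transmitted = transmitted,
         embryos = emb,
         crossovers = crossovers,
         ado_sites = ado_sites,
         adi_sites = adi_sites,
         window = win),
    class = "family_truth")

  structure(list(table = table, locus = locus, truth = truth,
                 config = cfg), class = "sim_family")
}

# X-linked recessive convention: hemizygous mutant male is Affected,
# heterozygous female is an asymptomatic Carrier.
true_disposition <- function(sex, hap, mutant_linked) {
  if (hap != mutant_linked) "Normal"
  else if (sex == "M") "Affected"
  else "Carrier"
}

#' @export
print.sim_family <- function(x, ...) {
  cat("Simulated X-linked family (seed ", x$config$seed, ")\n", sep = "")
  print(x$table)
  cat("  mutant-linked haplotype:", x$truth$mutant_linked, "\n")
  if (nrow(x$truth$embryos)) {
    cat("  embryo truth:\n")
    print(x$truth$embryos[, c("id", "sex", "hap_at_mutation", "disposition",
                              "failed", "n_crossovers")], row.names = FALSE)
  }
  invisible(x)
}

#' Write the ground-truth sidecar as JSON
#'
#' @param truth a `family_truth` object from [simulate_family()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "family_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar written by [write_ground_truth()]
#'
#' @param path JSON path.
#' @return a `family_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$maternal <- as.data.frame(x$maternal)
  x$embryos <- as.data.frame(x$embryos)
  x$transmitted <- as.matrix(x$transmitted)
  fix_list <- function(l) lapply(l, function(v) as.numeric(unlist(v)))
  x$crossovers <- fix_list(x$crossovers)
  x$ado_sites <- fix_list(x$ado_sites)
  x$adi_sites <- fix_list(x$adi_sites)
  structure(x, class = "family_truth")
}
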