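# Per-embryo support counting, sex inference, recombination detection and
# disposition calling — the computational core of the haplotyping analysis.

#' Calling thresholds for embryo haplotype calls
#'
#' The published clinical workups print per-embryo support counts but no
#' explicit decision rule; these thresholds are this package's rule and are
#' deliberately conservative. A haplotype is called only when the winning
#' maternal haplotype is supported by at least `min_informative` sites and
#' the contradicting minority fraction is at most `max_minority_fraction`.
#'
#' @param min_informative minimum winning-haplotype support count. Default 10.
#' @param max_minority_fraction maximum tolerated
#'   `min(m_x1, m_x2) / (m_x1 + m_x2)`. Default 0.05.
#' @param recomb_min_segment minimum consecutive-site run length for a
#'   haplotype segment to count in recombination detection. Default 5.
#' @param sex_min_het minimum usable informative sites for SNP-based sex
#'   inference. Default 3.
#' @return an object of class `call_params`.
#' @export
call_params <- function(min_informative = 10, max_minority_fraction = 0.05,
                        recomb_min_segment = 5, sex_min_het = 3) {
  if (!is.numeric(min_informative) || min_informative < 1)
    stop("min_informative must be >= 1", call. = FALSE)
  if (!is.numeric(max_minority_fraction) ||
      max_minority_fraction < 0 || max_minority_fraction >= 0.5)
    stop("max_minority_fraction must be in [0, 0.5)", call. = FALSE)
  if (!is.numeric(recomb_min_segment) || recomb_min_segment < 1)
    stop("recomb_min_segment must be >= 1", call. = FALSE)
  structure(list(min_informative = min_informative,
                 max_minority_fraction = max_minority_fraction,
                 recomb_min_segment = recomb_min_segment,
                 sex_min_het = sex_min_het),
            class = "call_params")
}

#' Construct a support-count record directly
#'
#' Mostly used to replay printed count triplets through [call_embryo()];
#' [count_support()] builds these from genotypes.
#'
#' @param f_x paternal-X support count.
#' @param m_x1,m_x2 maternal haplotype support counts.
#' @param sites optional per-site support data frame
#'   (`pos`, `support` in `X1`/`X2`/`ambiguous`/`no-call`).
#' @return an object of class `support_counts`.
#' @export
support_counts <- function(f_x = 0, m_x1 = 0, m_x2 = 0, sites = NULL) {
  stopifnot(f_x >= 0, m_x1 >= 0, m_x2 >= 0)
  structure(list(f_x = f_x, m_x1 = m_x1, m_x2 = m_x2, sites = sites),
            class = "support_counts")
}

#' @export
print.support_counts <- function(x, ...) {
  cat(sprintf("support: F(X)=%d M(X1)=%d M(X2)=%d\n",
              x$f_x, x$m_x1, x$m_x2))
  invisible(x)
}

#' Count informative-SNP support for each haplotype in one embryo
#'
#' Under the male hypothesis the embryo has no paternal X, so every
#' maternal-informative site with a usable single-allele call votes for the
#' haplotype whose allele it shows; a heterozygous observation (a drop-in
#' artifact in a true male) is ambiguous. Under the female hypothesis the
#' paternal allele is subtracted first: at X1-/X2-detecting sites a
#' heterozygous call resolves the maternal allele exactly (and counts
#' paternal-X support `f_x`), a single allele differing from the father's is
#' a paternally-dropped maternal allele, and a single allele equal to the
#' father's cannot be assigned. Sites whose embryo depth is not strictly
#' above `min_depth`, or with no call, contribute nothing.
#'
#' @param table a filtered [snp_table()].
#' @param embryo embryo sample name.
#' @param phase a `maternal_phase` from [classify_sites()].
#' @param sex `"M"`, `"F"`, or `"unknown"` (counted with the male logic;
#'   with almost no usable data the counts stay below any calling threshold).
#' @param min_depth embryo per-site depth gate (strict `>`). Default 10.
#' @return a [support_counts()] with the per-site support vector attached.
#' @export
count_support <- function(table, embryo, phase, sex = c("M", "F", "unknown"),
                          min_depth = 10) {
  stopifnot(inherits(table, "snp_table"), inherits(phase, "maternal_phase"))
  sex <- match.arg(sex)
  if (!embryo %in% names(table$roles))
    stop("no sample named '", embryo, "' in table", call. = FALSE)
  if (nrow(phase) == 0)
    return(support_counts(0L, 0L, 0L,
                          sites = data.frame(pos = numeric(0),
                                             support = character(0))))
  idx <- match(phase$pos, table$sites$pos)
  if (anyNA(idx))
    stop("phase refers to sites absent from the table", call. = FALSE)
  g <- table$geno[idx, embryo]
  d <- table$depth[idx, embryo]
  d[is.na(d)] <- 0

  n <- nrow(phase)
  support <- rep("no-call", n)
  f_x <- 0L
  usable <- !is.na(g) & d > min_depth
  for (i in which(usable)) {
    gi <- g[i]
    if (sex == "F") {
      if (phase$class[i] == "male_only") { support[i] <- "ambiguous"; next }
      f <- phase$father[i]
      if (gi == "0/1") {
        m <- other_allele(f)     # subtract the paternal allele
        support[i] <- if (m == phase$x1[i]) "X1" else "X2"
        f_x <- f_x + 1L          # paternal allele seen, distinct from maternal
      } else if (gi != f) {
        support[i] <- if (gi == phase$x1[i]) "X1" else "X2"
      } else {
        support[i] <- "ambiguous"
      }
    } else {
      if (gi == "0/1") { support[i] <- "ambiguous"; next }
      support[i] <- if (gi == phase$x1[i]) "X1" else "X2"
    }
  }
  support_counts(f_x = f_x,
                 m_x1 = sum(support == "X1"), m_x2 = sum(support == "X2"),
                 sites = data.frame(pos = phase$pos, support = support,
                                    stringsAsFactors = FALSE))
}

#' Infer embryo sex from SNP evidence (or an SRY assay flag)
#'
#' An SRY assay result, when supplied, is authoritative. Otherwise sex is
#' read from heterozygosity at maternal-informative sites, which is exactly
#' the paternal-X evidence: a female embryo carries the paternal allele next
#' to the maternal one and so is heterozygous wherever they differ (about
#' half the informative sites, thinned by drop-out), while a hemizygous male
#' shows heterozygosity only through drop-in artifacts. An embryo is called
#' female when it is heterozygous at `max(sex_min_het, 10%)` of its usable
#' informative sites, male when below that with at least `sex_min_het`
#' usable sites, and `"unknown"` with fewer. A single heterozygous site is
#' deliberately not enough to sex an embryo: one drop-in artifact would
#' otherwise feminise a true male.
#'
#' @param table a filtered [snp_table()].
#' @param embryo embryo sample name.
#' @param phase a `maternal_phase`.
#' @param min_depth embryo depth gate (strict `>`).
#' @param sex_min_het minimum usable informative sites. Default 3.
#' @param sry optional logical: `TRUE` SRY detected (male), `FALSE` absent
#'   (female), `NA`/`NULL` not assayed.
#' @return `"M"`, `"F"`, or `"unknown"`.
#' @export
infer_sex <- function(table, embryo, phase, min_depth = 10, sex_min_het = 3,
                      sry = NULL) {
  if (!is.null(sry) && !is.na(sry)) return(if (isTRUE(sry)) "M" else "F")
  if (nrow(phase) == 0) return("unknown")
  idx <- match(phase$pos, table$sites$pos)
  g <- table$geno[idx, embryo]
  d <- table$depth[idx, embryo]
  d[is.na(d)] <- 0
  usable <- !is.na(g) & d > min_depth
  n_usable <- sum(usable)
  n_het <- sum(usable & g == "0/1")
  if (n_usable < sex_min_het) return("unknown")
  thr <- max(sex_min_het, ceiling(0.1 * n_usable))
  if (n_het >= thr) "F" else "M"
}

#' Call one embryo's inherited haplotype and disposition
#'
#' The winning maternal haplotype `w = argmax(m_x1, m_x2)` is called iff its
#' count reaches `min_informative` and the contradicting minority fraction
#' `min(m_x1, m_x2) / (m_x1 + m_x2)` does not exceed
#' `max_minority_fraction`; exact ties and insufficient support yield
#' `Undetermined` (no coin flips — outputs are deterministic). The
#' disposition then follows X-linked recessive logic: a male inheriting the
#' mutant-linked haplotype is `Affected`, a female inheriting it is a
#' `Carrier`, any embryo inheriting the other haplotype is `Normal`. A
#' called mutant-linked haplotype in an embryo of unknown sex cannot be
#' placed on the Affected/Carrier axis and is reported `Undetermined`.
#' `f_x` is tracking evidence only and takes no part in the decision.
#'
#' @param counts a [support_counts()].
#' @param sex `"M"`, `"F"`, or `"unknown"`.
#' @param mutant_linked `"X1"` or `"X2"`.
#' @param params a [call_params()].
#' @param id optional embryo identifier carried into the call.
#' @return an object of class `embryo_call` with fields `id`, `sex`,
#'   `haplotype` (`"X1"`, `"X2"`, `"none"`), `disposition`, `reason`,
#'   `counts`, `recombination`, `breakpoints`.
#' @export
call_embryo <- function(counts, sex = "unknown", mutant_linked = c("X1", "X2"),
                        params = call_params(), id = NULL) {
  stopifnot(inherits(counts, "support_counts"))
  mutant_linked <- match.arg(mutant_linked)
  m1 <- counts$m_x1; m2 <- counts$m_x2
  tot <- m1 + m2
  hap <- "none"; reason <- "ok"
  if (tot == 0) {
    reason <- "no_data"
  } else if (m1 == m2) {
    reason <- "tie"
  } else {
    w <- if (m1 > m2) "X1" else "X2"
    if (max(m1, m2) < params$min_informative) {
      reason <- "insufficient_support"
    } else if (min(m1, m2) / tot > params$max_minority_fraction) {
      reason <- "excess_minority"
    } else hap <- w
  }
  disposition <- if (hap == "none") "Undetermined"
    else if (hap != mutant_linked) "Normal"
    else if (sex == "M") "Affected"
    else if (sex == "F") "Carrier"
    else { reason <- "mutant_haplotype_unknown_sex"; "Undetermined" }
  structure(list(id = id, sex = sex, haplotype = hap,
                 disposition = disposition, reason = reason, counts = counts,
                 recombination = FALSE, breakpoints = NULL),
            class = "embryo_call")
}

#' @export
print.embryo_call <- function(x, ...) {
  cat(sprintf("embryo %s: sex=%s F(X)=%d M(X1)=%d M(X2)=%d -> %s [%s]%s\n",
              x$id %||% "?", x$sex, x$counts$f_x, x$counts$m_x1,
              x$counts$m_x2,
              if (x$haplotype == "none") "-" else paste0("M(", x$haplotype, ")"),
              x$disposition,
              if (isTRUE(x$recombination)) " (recombinant)" else ""))
  invisible(x)
}

#' Detect recombination breakpoints in a per-site support vector
#'
#' Collapses the ordered support vector to consecutive X1/X2 runs (ignoring
#' ambiguous and no-call sites) and reports a breakpoint between adjacent
#' runs whenever both flanking runs span at least `recomb_min_segment`
#' sites, with the breakpoint localised to the open interval between the
#' last site of the left run and the first site of the right run. When
#' breakpoints exist and the segment containing the mutation position spans
#' fewer than `recomb_min_segment` informative sites (including the case of
#' the mutation falling inside a breakpoint interval), the haplotype at the
#' mutation itself cannot be trusted and `mutation_flag` is set.
#'
#' @param sites per-site support data frame (`pos`, `support`) as produced
#'   by [count_support()], ordered by position.
#' @param params a [call_params()].
#' @param mutation_pos optional pathogenic-variant position (bp) used to set
#'   `mutation_flag`.
#' @return list with `breakpoints` (data frame `left_pos`, `right_pos`,
#'   `left_hap`, `right_hap`), `runs`, and logical `mutation_flag`.
#' @export
detect_recombination <- function(sites, params = call_params(),
                                 mutation_pos = NULL) {
  k <- params$recomb_min_segment
  empty <- data.frame(left_pos = numeric(0), right_pos = numeric(0),
                      left_hap = character(0), right_hap = character(0))
  s <- sites[sites$support %in% c("X1", "X2"), , drop = FALSE]
  if (nrow(s) == 0)
    return(list(breakpoints = empty, runs = NULL, mutation_flag = FALSE))
  r <- rle(s$support)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(hap = r$values, length = r$lengths,
                     start_pos = s$pos[starts], end_pos = s$pos[ends],
                     stringsAsFactors = FALSE)
  bp <- empty
  if (nrow(runs) > 1) {
    for (i in seq_len(nrow(runs) - 1)) {
      if (runs$length[i] >= k && runs$length[i + 1] >= k)
        bp <- rbind(bp, data.frame(
          left_pos = runs$end_pos[i], right_pos = runs$start_pos[i + 1],
          left_hap = runs$hap[i], right_hap = runs$hap[i + 1]))
    }
  }
  mutation_flag <- FALSE
  if (nrow(bp) > 0 && !is.null(mutation_pos)) {
    inside_gap <- any(mutation_pos > bp$left_pos & mutation_pos < bp$right_pos)
    if (inside_gap) {
      mutation_flag <- TRUE
    } else {
      # informative sites in the segment bounded by the flanking breakpoints
      left_bound <- max(c(-Inf, bp$right_pos[bp$right_pos <= mutation_pos]))
      right_bound <- min(c(Inf, bp$left_pos[bp$left_pos >= mutation_pos]))
      n_seg <- sum(s$pos >= left_bound & s$pos <= right_bound)
      mutation_flag <- n_seg < k
    }
  }
  list(breakpoints = bp, runs = runs, mutation_flag = mutation_flag)
}

#' Interpret direct nested-PCR mutation + SRY results
#'
#' First-cycle logic where the pathogenic variant is assayed directly
#' (Sanger-style call at the mutation site) alongside the SRY sex marker:
#' an SRY-positive embryo showing only the mutant allele is a hemizygous
#' `Affected` male; SRY-positive with only the reference allele is a
#' `Normal` male; SRY-negative heterozygous is a `Carrier` female;
#' SRY-negative reference-only is a `Normal` female; a failed amplification
#' is `Undetermined`. An SRY-positive heterozygous call is impossible in a
#' male and raises an error (contamination / allele drop-in evidence). An
#' SRY-negative mutant-only call (plausibly drop-out of the reference
#' allele in a carrier) is reported `Undetermined` with a warning, never
#' silently resolved.
#'
#' @param mutation_genotype character vector with values `"ref"`, `"alt"`,
#'   `"het"`, or `"failed"`.
#' @param sry_present logical vector: SRY amplification detected. `NA`
#'   allowed (not assayed / failed).
#' @param id optional embryo identifiers.
#' @return data frame of class `direct_calls` with columns `id`, `sex`,
#'   `disposition`, `reason`.
#' @export
interpret_direct_test <- function(mutation_genotype, sry_present, id = NULL) {
  mutation_genotype <- match.arg(mutation_genotype,
                                 c("ref", "alt", "het", "failed"),
                                 several.ok = TRUE)
  n <- length(mutation_genotype)
  sry_present <- rep_len(as.logical(sry_present), n)
  id <- id %||% paste0("embryo_", seq_len(n))

  bad <- which(mutation_genotype == "het" & isTRUE_vec(sry_present))
  if (length(bad))
    stop("heterozygous mutation call with SRY present (possible ",
         "contamination or allele drop-in) for: ",
         paste(id[bad], collapse = ", "), call. = FALSE)

  sex <- rep("unknown", n)
  disposition <- rep("Undetermined", n)
  reason <- rep("ok", n)
  for (i in seq_len(n)) {
    g <- mutation_genotype[i]; s <- sry_present[i]
    if (g == "failed") { reason[i] <- "failed_amplification"; next }
    if (is.na(s)) {
      if (g == "het") { sex[i] <- "F"; disposition[i] <- "Carrier" }
      else reason[i] <- "no_sex_marker"
      next
    }
    sex[i] <- if (s) "M" else "F"
    if (s) {
      disposition[i] <- if (g == "alt") "Affected" else "Normal"
    } else {
      if (g == "het") disposition[i] <- "Carrier"
      else if (g == "ref") disposition[i] <- "Normal"
      else {
        reason[i] <- "alt_only_female"
        warning("embryo ", id[i], ": SRY-negative with mutant-allele-only ",
                "call; possible allele drop-out in a carrier - Undetermined")
      }
    }
  }
  out <- data.frame(id = id, sex = sex, disposition = disposition,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("direct_calls", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
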