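#' Preimplantation genetic haplotyping analysis
#'
#' Runs the full indirect (linkage) analysis for one family: applies the
#' region and depth filter, classifies informative SNPs and phases the two
#' maternal X haplotypes against the reference sample, then for each embryo
#' infers sex, counts haplotype support, screens for recombination around
#' the mutation, and calls the disposition.
#'
#' A call whose detected recombination leaves fewer than
#' `params$recomb_min_segment` informative sites in the mutation-containing
#' segment is downgraded to `Undetermined` (reason `"recombinant"`): the
#' genome-wide majority haplotype need not be the one present at the
#' mutation itself.
#'
#' @param table a [snp_table()] (unfiltered is fine).
#' @param locus a [target_locus()].
#' @param params a [call_params()].
#' @param min_depth usability depth gate (strict `>`), applied globally to
#'   the parental/reference gDNA and per-embryo to embryo calls. Default 10.
#' @param sry optional named logical vector of SRY assay results per embryo
#'   sample; authoritative for sex where given.
#' @return an object of class `pgh` with elements `locus`, `params`,
#'   `phase`, `markers`, `calls` (list of [call_embryo()] results),
#'   `report` (the final per-embryo table), and `filter_log`.
#' @examples
#' fam <- simulate_family(sim_config(n_snps = 120, n_embryos = 4, seed = 42))
#' fit <- pgh(fam$table, fam$locus)
#' fit
#' summary(fit)
#' @export
pgh <- function(table, locus, params = call_params(), min_depth = 10,
                sry = NULL) {
  stopifnot(inherits(table, "snp_table"), inherits(locus, "target_locus"))
  filtered <- apply_region_depth_filter(table, locus, min_depth = min_depth)
  cs <- classify_sites(filtered, locus)
  phase <- cs$phase
  mutant <- attr(phase, "mutant_linked")
  embryos <- role_sample(filtered, "embryo")

  calls <- list()
  for (e in embryos) {
    s <- if (!is.null(sry)) sry[[e]] else NULL
    sex <- infer_sex(filtered, e, phase, min_depth = min_depth,
                     sex_min_het = params$sex_min_het, sry = s)
    cnt <- count_support(filtered, e, phase, sex = sex, min_depth = min_depth)
    cl <- call_embryo(cnt, sex = sex, mutant_linked = mutant,
                      params = params, id = e)
    rec <- detect_recombination(cnt$sites, params,
                                mutation_pos = locus$mutation_pos)
    cl$recombination <- nrow(rec$breakpoints) > 0
    cl$breakpoints <- rec$breakpoints
    if (rec$mutation_flag && cl$haplotype != "none") {
      cl$haplotype <- "none"
      cl$disposition <- "Undetermined"
      cl$reason <- "recombinant"
    }
    calls[[e]] <- cl
  }

  structure(list(locus = locus, params = params, min_depth = min_depth,
                 phase = phase, markers = cs$markers, calls = calls,
                 report = build_report(calls, locus),
                 filter_log = attr(filtered, "filter_log")),
            class = "pgh")
}

result_code <- c(Normal = "N", Affected = "A", Carrier = "C",
                 Undetermined = "-")

build_report <- function(calls, locus) {
  rows <- lapply(calls, function(cl) {
    bp <- cl$breakpoints
    has_bp <- !is.null(bp) && nrow(bp) > 0
    data.frame(
      sample_id = cl$id,
      gene = locus$gene_name %||% NA_character_,
      chrom = locus$chrom,
      gender = cl$sex,
      f_x = cl$counts$f_x, m_x1 = cl$counts$m_x1, m_x2 = cl$counts$m_x2,
      haplotype = if (cl$haplotype == "none") "-"
                  else paste0("M(", cl$haplotype, ")"),
      results = result_code[[cl$disposition]],
      recombinant = isTRUE(cl$recombination),
      breakpoint = if (has_bp)
        paste(sprintf("%.0f-%.0f", bp$left_pos, bp$right_pos), collapse = ";")
        else "",
      reason = cl$reason,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(sample_id = character(0), gene = character(0),
                      chrom = character(0), gender = character(0),
                      f_x = integer(0), m_x1 = integer(0), m_x2 = integer(0),
                      haplotype = character(0), results = character(0),
                      recombinant = logical(0), breakpoint = character(0),
                      reason = character(0))
  out
}

#' @export
print.pgh <- function(x, ...) {
  cat("Preimplantation genetic haplotyping analysis\n")
  cat("  gene:", x$locus$gene_name %||% "?", " mutant-linked:",
      attr(x$phase, "mutant_linked"), "\n")
  cat("  informative sites:", nrow(x$phase),
      sprintf("(X1-detecting %d, X2-detecting %d)\n",
              x$markers$n_x1_informative, x$markers$n_x2_informative))
  if (nrow(x$report)) {
    cols <- c("sample_id", "gender", "f_x", "m_x1", "m_x2", "haplotype",
              "results")
    tab <- x$report[, cols]
    names(tab) <- c("Sample ID", "Gender", "F(X)", "M(X1)", "M(X2)",
                    "Haplotype", "Results")
    print(tab, row.names = FALSE)
  } else cat("  (no embryo samples)\n")
  invisible(x)
}

#' @export
summary.pgh <- function(object, ...) {
  structure(list(
    markers = object$markers,
    filter_log = object$filter_log,
    n_embryos = length(object$calls),
    dispositions = table(vapply(object$calls, `[[`, "", "disposition")),
    n_recombinant = sum(vapply(object$calls, function(c)
      isTRUE(c$recombination), logical(1))),
    params = object$params),
    class = "summary.pgh")
}

#' @export
print.summary.pgh <- function(x, ...) {
  fl <- x$filter_log
  cat("PGH analysis summary\n")
  cat(sprintf("  sites: %d in, %d usable (%d outside window, %d low depth; depth > %g)\n",
              fl$n_in, fl$n_out, fl$n_outside_window, fl$n_low_depth,
              fl$min_depth))
  print(x$markers)
  cat("  embryos:", x$n_embryos, "\n  dispositions:\n")
  print(x$dispositions)
  cat("  recombination flagged in", x$n_recombinant, "embryo(s)\n")
  cat(sprintf("  calling rule: winner >= %g sites, minority fraction <= %g\n",
              x$params$min_informative, x$params$max_minority_fraction))
  invisible(x)
}

#' @export
as.data.frame.pgh <- function(x, ...) x$report

#' Plot per-embryo haplotype support along the chromosome
#'
#' One row per embryo; each usable informative site is drawn at its
#' position, coloured by the maternal haplotype it supports. The gene
#' interval is shaded and the mutation position marked.
#'
#' @param x a [pgh()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pgh <- function(x, ...) {
  n <- length(x$calls)
  if (n == 0 || nrow(x$phase) == 0) {
    warning("nothing to plot")
    return(invisible(x))
  }
  win <- locus_window(x$locus)
  graphics::plot(NA, xlim = win / 1e6, ylim = c(0.5, n + 0.5),
                 xlab = "position (Mb)", ylab = "", yaxt = "n",
                 main = "Haplotype support per embryo", ...)
  graphics::axis(2, at = seq_len(n), labels = names(x$calls), las = 1,
                 cex.axis = 0.7)
  graphics::rect(x$locus$gene_start / 1e6, 0.5, x$locus$gene_end / 1e6,
                 n + 0.5, col = grDevices::adjustcolor("grey", 0.4),
                 border = NA)
  graphics::abline(v = x$locus$mutation_pos / 1e6, lty = 2)
  cols <- c(X1 = "firebrick", X2 = "steelblue")
  for (i in seq_len(n)) {
    s <- x$calls[[i]]$counts$sites
    s <- s[s$support %in% c("X1", "X2"), ]
    if (nrow(s))
      graphics::points(s$pos / 1e6, rep(i, nrow(s)), pch = 15,
                       col = cols[s$support], cex = 0.5)
  }
  graphics::legend("topright", legend = c("supports X1", "supports X2"),
                   col = cols, pch = 15, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write the per-embryo report and marker table to an output directory
#'
#' Emits `report.tsv` and `report.json` (the per-embryo table),
#' `markers.tsv` (the per-site classification) and `log.txt` (filter counts
#' and effective parameters) so every number in the report is traceable.
#'
#' @param x a [pgh()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "pgh"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$report, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_markers_tsv(x$phase, file.path(dir, "markers.tsv"))
  fl <- x$filter_log
  log_lines <- c(
    sprintf("sites_in\t%d", fl$n_in),
    sprintf("sites_usable\t%d", fl$n_out),
    sprintf("sites_outside_window\t%d", fl$n_outside_window),
    sprintf("sites_low_depth\t%d", fl$n_low_depth),
    sprintf("min_depth\t%g", fl$min_depth),
    sprintf("window\t%g-%g", fl$window[1], fl$window[2]),
    sprintf("mutant_linked\t%s", attr(x$phase, "mutant_linked")),
    sprintf("n_informative\t%d", nrow(x$phase)),
    sprintf("min_informative\t%g", x$params$min_informative),
    sprintf("max_minority_fraction\t%g", x$params$max_minority_fraction),
    sprintf("recomb_min_segment\t%g", x$params$recomb_min_segment),
    sprintf("sex_min_het\t%g", x$params$sex_min_het))
  writeLines(log_lines, file.path(dir, "log.txt"))
  invisible(dir)
}
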