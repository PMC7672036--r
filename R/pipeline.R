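# Orchestration: one entry point running any stage from a config, plus the
# simulation-mode confusion summary.

#' Run a pipeline stage from a configuration
#'
#' Drives the package's stages headlessly from a single config (an R list,
#' or a path to a YAML/JSON file). `config$mode` selects the stage:
#'
#' * `"simulate"` — [simulate_family()]; writes `family.vcf`,
#'   `truth.json` and `locus.json` into `config$out`.
#' * `"haplotype"` — [load_vcf()] + [pgh()]; writes the report files via
#'   [write_report()].
#' * `"direct"` — [interpret_direct_test()] on `config$direct` (a data
#'   frame / list with `id`, `mutation_genotype`, `sry_present`, or a TSV
#'   path); writes `direct_report.tsv`.
#' * `"qc"` — [qc_rates()] + [validate_blanks()] on `config$qc` counts;
#'   writes `qc_report.tsv`.
#' * `"evaluate"` — [evaluate_against_truth()] on a haplotype report and a
#'   ground-truth sidecar.
#'
#' All outputs are deterministic given the config and seed.
#'
#' @param config list or path to a YAML/JSON config file. Common fields:
#'   `mode`, `out` (output directory), `seed`. Mode-specific fields:
#'   `sim` (a [sim_config()] field list), `vcf`, `roles` (named list
#'   sample -> role), `locus` (a [target_locus()] field list), `params`
#'   (a [call_params()] field list), `min_depth`, `direct`, `qc`,
#'   `report`, `truth`.
#' @return the stage's main result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config) || is.null(config$mode))
    stop("config must be a list (or YAML/JSON path) with a 'mode' field",
         call. = FALSE)
  mode <- match.arg(config$mode,
                    c("simulate", "haplotype", "direct", "qc", "evaluate"))
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- switch(mode,
    simulate = {
      sim_fields <- config$sim %||% list()
      if (!is.null(config$seed)) sim_fields$seed <- config$seed
      fam <- simulate_family(do.call(sim_config, sim_fields))
      write_family_vcf(fam$table, file.path(out_dir, "family.vcf"),
                       male_gt_dialect = fam$config$male_gt_dialect)
      write_ground_truth(fam$truth, file.path(out_dir, "truth.json"))
      jsonlite::write_json(unclass(fam$locus),
                           file.path(out_dir, "locus.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      fam
    },
    haplotype = {
      roles <- unlist(config$roles)
      table <- load_vcf(config$vcf, roles)
      locus <- do.call(target_locus, config$locus)
      params <- do.call(call_params, config$params %||% list())
      fit <- pgh(table, locus, params = params,
                 min_depth = config$min_depth %||% 10)
      write_report(fit, out_dir)
      fit
    },
    direct = {
      d <- config$direct
      if (is.character(d))
        d <- utils::read.delim(d, stringsAsFactors = FALSE)
      d <- as.data.frame(d)
      calls <- interpret_direct_test(d$mutation_genotype,
                                     as.logical(d$sry_present),
                                     id = d$id)
      utils::write.table(calls, file.path(out_dir, "direct_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      calls
    },
    qc = {
      counts <- do.call(qc_counts, config$qc)
      rates <- qc_rates(counts)
      blanks <- validate_blanks(counts)
      tab <- as.data.frame(rates)
      tab$percent <- sprintf("%.1f%%", 100 * tab$rate)
      utils::write.table(tab, file.path(out_dir, "qc_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(rates = rates, blanks = blanks)
    },
    evaluate = {
      report <- config$report
      if (is.character(report))
        report <- utils::read.delim(report, stringsAsFactors = FALSE)
      truth <- config$truth
      if (is.character(truth)) truth <- read_ground_truth(truth)
      ev <- evaluate_against_truth(report, truth)
      out <- unclass(ev)
      out$confusion <- as.data.frame(ev$confusion)  # long form for JSON
      jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      ev
    })
  invisible(res)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Compare a haplotyping report against simulation ground truth
#'
#' @param report a [pgh()] result or its report data frame.
#' @param truth a `family_truth` from [simulate_family()] /
#'   [read_ground_truth()].
#' @return an object of class `pgh_eval`: the per-disposition confusion
#'   matrix (`truth` x `called`), the call rate (fraction of embryos not
#'   `Undetermined`), accuracy among called embryos, and recombination
#'   detection sensitivity/localisation over embryos with at least one true
#'   crossover.
#' @export
evaluate_against_truth <- function(report, truth) {
  fit <- NULL
  if (inherits(report, "pgh")) { fit <- report; report <- report$report }
  stopifnot(inherits(truth, "family_truth"))
  unmatched <- setdiff(report$sample_id, truth$embryos$id)
  if (length(unmatched))
    stop("embryos absent from ground truth: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  m <- match(report$sample_id, truth$embryos$id)
  truth_disp <- truth$embryos$disposition[m]
  code_to_disp <- c(N = "Normal", A = "Affected", C = "Carrier",
                    "-" = "Undetermined")
  called_disp <- unname(code_to_disp[report$results])
  confusion <- table(truth = truth_disp, called = called_disp)
  called <- called_disp != "Undetermined"
  call_rate <- mean(called)
  accuracy_called <- if (any(called))
    mean(truth_disp[called] == called_disp[called]) else NA_real_

  # recombination: among embryos with >= 1 true crossover, was a breakpoint
  # reported, and does a reported interval contain a true crossover?
  rec_sens <- NA_real_; rec_loc <- NA_real_
  if (!is.null(fit)) {
    has_xov <- vapply(truth$crossovers[report$sample_id], length,
                      integer(1)) > 0
    if (any(has_xov)) {
      detected <- logical(sum(has_xov)); localised <- logical(sum(has_xov))
      ids <- report$sample_id[has_xov]
      for (k in seq_along(ids)) {
        bp <- fit$calls[[ids[k]]]$breakpoints
        xov <- truth$crossovers[[ids[k]]]
        detected[k] <- !is.null(bp) && nrow(bp) > 0
        localised[k] <- detected[k] &&
          any(vapply(seq_len(nrow(bp)), function(b)
            any(xov >= bp$left_pos[b] & xov <= bp$right_pos[b]),
            logical(1)))
      }
      rec_sens <- mean(detected); rec_loc <- mean(localised)
    }
  }
  structure(list(confusion = confusion, call_rate = call_rate,
                 accuracy_called = accuracy_called,
                 recomb_sensitivity = rec_sens,
                 recomb_localisation = rec_loc,
                 n_embryos = nrow(report)),
            class = "pgh_eval")
}

#' @export
print.pgh_eval <- function(x, ...) {
  cat("Evaluation against ground truth (", x$n_embryos, " embryos)\n", sep = "")
  print(x$confusion)
  cat(sprintf("  call rate: %.1f%%\n", 100 * x$call_rate))
  if (!is.na(x$accuracy_called))
    cat(sprintf("  accuracy among called: %.1f%%\n", 100 * x$accuracy_called))
  if (!is.na(x$recomb_sensitivity))
    cat(sprintf("  recombination detected: %.1f%%, localised: %.1f%%\n",
                100 * x$recomb_sensitivity, 100 * x$recomb_localisation))
  invisible(x)
}
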