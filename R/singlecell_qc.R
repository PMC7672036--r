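# Single-cell PCR validation statistics (preclinical workup arithmetic).

#' Single-cell PCR validation counts
#'
#' @param n_cells single cells attempted.
#' @param n_no_signal cells with no amplification signal at all.
#' @param n_ado amplified cells affected by allele drop-out.
#' @param n_blank_controls blank (wash-drop) controls run.
#' @param n_blank_positive blank controls showing an amplification signal.
#' @param n_locus_reactions,n_locus_amplified optional locus-level reaction
#'   counts, reported pass-through as a locus amplification rate when given
#'   (their denominator convention is the caller's).
#' @return an object of class `qc_counts`.
#' @export
qc_counts <- function(n_cells, n_no_signal = 0, n_ado = 0,
                      n_blank_controls = 0, n_blank_positive = 0,
                      n_locus_reactions = NULL, n_locus_amplified = NULL) {
  stopifnot(n_cells >= 1, n_no_signal >= 0, n_ado >= 0,
            n_blank_controls >= 0, n_blank_positive >= 0)
  if (n_no_signal + n_ado > n_cells)
    stop("n_no_signal + n_ado cannot exceed n_cells", call. = FALSE)
  if (n_blank_positive > n_blank_controls)
    stop("n_blank_positive cannot exceed n_blank_controls", call. = FALSE)
  structure(list(n_cells = n_cells, n_no_signal = n_no_signal, n_ado = n_ado,
                 n_blank_controls = n_blank_controls,
                 n_blank_positive = n_blank_positive,
                 n_locus_reactions = n_locus_reactions,
                 n_locus_amplified = n_locus_amplified),
            class = "qc_counts")
}

#' Single-cell PCR validation rates with Wilson intervals
#'
#' With `amplified = n_cells - n_no_signal`:
#' * cell amplification rate = `amplified / n_cells`;
#' * ADO rate = `n_ado / amplified` — the denominator is amplified cells,
#'   the only convention under which an 8-of-98 drop-out count and a 91.8%
#'   success figure are mutually consistent (90/98);
#' * successful amplification rate = `(amplified - n_ado) / amplified`,
#'   so `success_rate + ado_rate = 1` exactly.
#'
#' Each rate carries a Wilson 95% score interval (chosen over Wald for its
#' small-count behaviour).
#'
#' @param counts a [qc_counts()].
#' @param conf confidence level for the intervals.
#' @return an object of class `qc_rates`: a data frame with columns
#'   `metric`, `numerator`, `denominator`, `rate`, `lower`, `upper`
#'   (proportions), printed as percentages to one decimal. Returns `NULL`
#'   with a warning when no cell amplified (rates undefined).
#' @examples
#' qc_rates(qc_counts(n_cells = 100, n_no_signal = 2, n_ado = 8))
#' @export
qc_rates <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "qc_counts"))
  amplified <- counts$n_cells - counts$n_no_signal
  if (amplified == 0) {
    warning("no cells amplified: rates are undefined")
    return(NULL)
  }
  row <- function(metric, x, n) {
    ci <- wilson_ci(x, n, conf)
    data.frame(metric = metric, numerator = x, denominator = n,
               rate = x / n, lower = ci[["lower"]], upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("cell_amplification_rate", amplified, counts$n_cells),
    row("ado_rate", counts$n_ado, amplified),
    row("success_rate", amplified - counts$n_ado, amplified))
  if (!is.null(counts$n_locus_reactions) &&
      !is.null(counts$n_locus_amplified) && counts$n_locus_reactions > 0)
    out <- rbind(out, row("locus_amplification_rate",
                          counts$n_locus_amplified,
                          counts$n_locus_reactions))
  rownames(out) <- NULL
  class(out) <- c("qc_rates", "data.frame")
  attr(out, "conf") <- conf
  out
}

#' @export
print.qc_rates <- function(x, ...) {
  cat("Single-cell PCR validation rates (Wilson ",
      format(100 * attr(x, "conf")), "% CI)\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s %5.1f%%  (%d/%d; CI %.1f-%.1f%%)\n",
                x$metric[i], 100 * x$rate[i], x$numerator[i],
                x$denominator[i], 100 * x$lower[i], 100 * x$upper[i]))
  invisible(x)
}

#' Check blank (wash-drop) controls for contamination
#'
#' @param counts a [qc_counts()].
#' @return list with `pass` (logical) and `message`; passing requires zero
#'   blank controls with an amplification signal. Zero controls run passes
#'   vacuously, with a warning.
#' @export
validate_blanks <- function(counts) {
  stopifnot(inherits(counts, "qc_counts"))
  if (counts$n_blank_controls == 0) {
    warning("no blank controls run; contamination check is vacuous")
    return(list(pass = TRUE, message = "no controls run"))
  }
  if (counts$n_blank_positive == 0)
    list(pass = TRUE,
         message = sprintf("all %d blank controls negative",
                           counts$n_blank_controls))
  else
    list(pass = FALSE,
         message = sprintf("contamination evidence: %d of %d blank controls amplified",
                           counts$n_blank_positive, counts$n_blank_controls))
}
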