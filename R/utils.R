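# Internal helpers shared across modules.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level.
#' @return named numeric vector `c(lower, upper)` on the proportion scale.
#' @keywords internal
#' @noRd
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Canonical genotype encoding used throughout the package (allele indices
# relative to REF/ALT): "0", "1" single observed allele; "0/1" both alleles
# observed; NA no-call.  Homozygous diploid calls collapse to the single
# observed allele — zygosity is not recoverable from a WGA sample anyway,
# and no step downstream needs it beyond het / single-allele / no-call.
gt_alleles <- function(gt) {
  if (is.na(gt)) return(character(0))
  sort(unique(strsplit(gt, "/", fixed = TRUE)[[1]]))
}

is_het <- function(gt) !is.na(gt) & gt == "0/1"

is_single <- function(gt) !is.na(gt) & (gt == "0" | gt == "1")

other_allele <- function(a) ifelse(a == "0", "1", "0")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
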