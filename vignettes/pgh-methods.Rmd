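---
title: "Methods: haplotype-based PGT-M on chromosome X"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based PGT-M on chromosome X}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pghap)
```

## The problem

In preimplantation genetic testing for an X-linked recessive disease, each
embryo biopsy is a single (or few-cell) sample whose DNA has been
whole-genome amplified. Direct genotyping of the pathogenic variant in such
material is vulnerable to allele drop-out (ADO): in a heterozygous carrier
cell one allele may simply fail to amplify, and a carrier female can be
miscalled normal, or an affected male's single allele can vanish into a
failed call. Preimplantation genetic *haplotyping* (PGH) sidesteps the
single-locus fragility by reading many SNPs flanking the gene and asking a
redundant question: *which maternal haplotype did this embryo inherit?* A
wrong answer now requires many coordinated artifacts, not one.

This vignette records the model the package implements, the parameters that
matter, and the design decisions taken where published clinical practice is
silent.

## Phasing model

Let the mother's two X haplotypes over the marker window be X1 and X2. The
phase-reference sample — an affected proband or an unaffected relative such
as chorionic villus — is hemizygous, so its allele at any maternally
heterozygous site reads out one maternal haplotype directly. We *define* X1
as the haplotype carried by the reference. Polarity then follows from the
reference's disease status alone: affected reference ⇒ X1 carries the
mutation; unaffected reference ⇒ X2 does. Both anchors occur in practice
and `target_locus(reference_status =)` expresses either; no other part of
the analysis changes.

A site is maternally informative iff the mother is heterozygous (`0/1`) and
the reference has a usable single-allele call. With biallelic SNPs the
father's single allele always equals exactly one maternal allele, so every
informative site with a father call is either *X1-detecting* (father allele
= X2 allele, so seeing the X1 allele in a female embryo is unambiguous) or
*X2-detecting*. Sites lacking a father call are kept for male embryos only
(`male_only`), because female-embryo disambiguation requires subtracting
the paternal allele. "Paternally informative" has no independent existence
for biallelic X markers — a father allele differing from *both* maternal
alleles is impossible — so the package reports as paternally trackable the
informative sites with a usable father call, and published per-haplotype
marker counts are treated as descriptive, not reproducible.

## Support counting and calling

For embryo genotypes the package uses a collapsed allele-set encoding
(`"0"`, `"1"`, `"0/1"`, no-call): zygosity of a homozygous diploid call
carries no information in WGA material and is discarded at load time. Male
logic: each usable single-allele observation at an informative site votes
for the haplotype whose allele it shows; heterozygous observations (drop-in
artifacts in a true male) are ambiguous. Female logic at detecting sites:
a heterozygous observation subtracts the paternal allele and the residual
votes (also incrementing the paternal-X tally F(X)); a single allele
differing from the father's votes directly (the paternal copy dropped); a
single allele equal to the father's is ambiguous. Embryo depth gates votes
per embryo and per site (strictly `> min_depth`), while parental/reference
depth gates a site globally in `apply_region_depth_filter()` — a WGA
dropout in one embryo must not discard the marker for all embryos. The
strict inequality (`> 10×`, not `≥`) is the usability convention adopted
throughout.

Calling (`call_params()`): the winning haplotype needs
`min_informative = 10` votes and a minority fraction at most
`max_minority_fraction = 0.05`. Published clinical tables print calls but
no rule; these defaults are this package's own and were chosen so that a
clean 26-vs-0 embryo is comfortably callable while a 80-vs-20 mixture —
recombination or contamination territory — is not. Exact ties are
Undetermined by construction (no randomness anywhere in calling). F(X)
never enters the maternal decision: it is reported as tracking evidence
only, since no published decision role exists for it.

### Sex inference

When no SRY assay result is supplied (an SRY flag, when present, is
authoritative), sex is read from heterozygosity at informative sites,
which *is* the paternal-X evidence: a female is heterozygous wherever the
paternal allele differs from her maternal one (about half the informative
sites, thinned by ADO squared), a male only where drop-in fabricated an
allele. The package calls female at `≥ max(3, 10% of usable sites)`
heterozygous sites, male below that with at least 3 usable sites, unknown
otherwise. A tempting simpler rule — "any paternal evidence means female" —
is not robust: at a drop-in rate of 0.5–1% over ~150 sites, roughly one
fabricated heterozygote per male embryo is expected, and a single-site rule
would feminise a large fraction of true males (turning Affected males into
Carrier calls). The 10% threshold sits two orders of magnitude above the
artifact rate and well below the ~40% heterozygosity of a true female.
Embryos of unknown sex are counted under the male logic; with fewer than 3
usable sites the counts cannot reach `min_informative`, so such embryos end
Undetermined regardless.

### Recombination

The per-site votes, ordered by position, are collapsed to X1/X2 runs
(ambiguous and no-call sites dropped). A breakpoint is reported between
adjacent runs only when both flanks span at least `recomb_min_segment = 5`
sites — isolated contradicting votes are artifact noise, not crossovers.
The reported interval is the open gap between the last left-run site and
the first right-run site; with ~150 informative sites over 2 Mb that is a
localisation of a few tens of kilobases. If the segment containing the
mutation position spans fewer than 5 informative sites (or the mutation
falls inside a breakpoint gap), the haplotype *at the mutation* is not the
one the genome-wide majority vote reports, and the call is downgraded to
Undetermined with reason `recombinant`. The package deliberately does not
re-call from the mutation-proximal segment alone in this release: a
crossover close to the mutation is exactly the situation where an indirect
linkage test should abstain.

## Single-cell PCR validation

`qc_rates()` encodes the standard preclinical arithmetic on a panel of
single lymphocytes: with `amplified = n_cells − n_no_signal`, the cell
amplification rate is `amplified / n_cells`, the ADO rate is
`n_ado / amplified`, and the successful amplification rate is their exact
complement `(amplified − n_ado) / amplified`. The ADO denominator is
amplified cells, not attempted cells — the only convention under which an
8-of-98 drop-out count coexists with a 90/98 = 91.8% success figure.
Intervals are Wilson score intervals (better behaved than Wald at small
counts and near the boundaries). A separately quoted "mutation-locus
amplification rate" has no reconstructible denominator from cell-level
counts; it is reported pass-through when locus-level counts are supplied
and otherwise not computed. Blank wash-drop controls must all be negative
(`validate_blanks()`); zero controls passes only vacuously, with a warning.

## The synthetic-family generator

`simulate_family()` emulates the data a clinical PGH cycle produces —
never sequencing reads, only the genotype layer:

* `n_snps = 600`, `window_span = 2 Mb`, `maternal_het_fraction = 0.5`:
  about 300 informative sites, i.e. ~150 detecting markers per maternal
  haplotype, the order of magnitude of published per-haplotype marker
  counts in a 1 Mb-flank design.
* `ado_rate = 0.08` per allele: clinical validation work keeps single-cell
  ADO below 10%; 8% is a realistic operating point. Drop-out acts per
  allele independently; a site whose every allele drops becomes a no-call.
* `adi_rate = 0.005` per site: drop-in/contamination is an order of
  magnitude rarer than drop-out in practice.
* `sample_fail_rate = 0.1`: whole-biopsy amplification failures are common
  enough that any realistic cycle contains some; failed samples emit
  no-calls with zero depth.
* `recomb_rate_per_mb = 0.013`: ≈1.3 cM/Mb, the human X genome-wide
  average. Crossovers follow a Haldane process — Poisson count with mean
  `rate × window`, uniform positions, no interference — the simplest model
  consistent with the window sizes involved; over 2 Mb, interference is
  immaterial.
* `depth_mean = 50` (Poisson per site per sample), `depth_min_usable = 10`:
  sites at or below 10× are emitted but fail the strict `> 10×` gate, so
  the filter is exercised, not bypassed.
* `n_embryos = 10`, `embryo_sex_prob_female = 0.5`.

Hemizygous-male genotypes are written to VCF in either the haploid (`0`)
or homozygous-diploid (`0/0`) dialect (`male_gt_dialect`), since both occur
in the wild; `load_vcf()` normalises both. Embryos are always written
diploid-style, as a variant caller unaware of sex would.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: read-level error and capture bias, linkage
disequilibrium between markers (sites are independent), population allele
frequencies, aneuploidy and segmental CNVs in embryos, and the possibility
that the phase reference is itself recombinant relative to the maternal
haplotypes (the simulated reference carries X1 un-recombined; a real
proband's X is one meiotic product, and a crossover in *that* meiosis
shifts the phase anchor — a known limitation of single-reference PGH, not
of the simulator alone).

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive; the analysis window is a closed
interval. Multiallelic and non-SNP records are dropped (with a logged
count) rather than decomposed — the counting logic assumes biallelic
markers. A heterozygous call in a known-male sample is nulled and counted.
Zero informative sites is a warning, not an error: every embryo then
reports zero counts and Undetermined. All outputs are deterministic given
inputs and seed; the simulator restores the caller's RNG state.

## Problem sizes in the test suite

The bundled tests run the generator at 150–400 SNPs and up to 20 embryos
per family (1,000 embryos total for disposition-recovery checks, ~100
qualifying trials for crossover localisation, 10,000 replicates for the
ADO-estimator bias check), sizes at which the binomial noise on the
measured rates is far smaller than the margins being asserted while the
whole suite stays interactive.
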