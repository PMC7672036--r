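Package: pghap
Title: Preimplantation Genetic Haplotyping for X-Linked Monogenic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Trio-based preimplantation genetic haplotyping (PGH) for
    X-linked monogenic disease (PGT-M). Selects informative SNP markers
    flanking a target gene on chromosome X, phases the two maternal
    haplotypes against an affected or unaffected phase-reference sample,
    counts per-embryo haplotype support, detects recombination
    breakpoints, and calls embryo dispositions (Normal, Affected,
    Carrier, Undetermined). Includes a seeded synthetic-family simulator
    with whole-genome-amplification artifacts (allele drop-out, allele
    drop-in, sample failure), single-cell PCR validation statistics with
    Wilson intervals, and an interpreter for direct mutation-plus-SRY
    nested-PCR results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
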