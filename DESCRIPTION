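Package: snppull
Title: Allele-Specific Protein Binding from SILAC Label-Swap DNA Pull-Down Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of quantitative DNA-bait pull-down screens that test
    single-nucleotide polymorphisms (SNPs) for allele-specific protein
    binding. From a SNP panel and peptide-level SILAC evidence (simulated or
    supplied), the package constructs allele bait sequences, aggregates
    peptide heavy/light ratios to filtered protein log-ratios, computes
    robust ratio-outlier p-values per label orientation, combines the
    forward and reverse (label-swap) experiments with a direction-consistent
    Fisher test, classifies proteins on the two-dimensional interaction plot
    into allele-specific binders, contaminants and background, scans both
    alleles for IUPAC consensus transcription-factor motifs, and provides
    delta-delta-Ct and dual-reporter statistics for downstream validation.
    A seeded synthetic-evidence generator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
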