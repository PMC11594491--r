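Package: kdrcall
Title: Multi-Assay Knockdown-Resistance (kdr) Genotyping for Aedes aegypti
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calling and cross-method resolution of the voltage-gated
    sodium-channel knockdown-resistance (kdr) substitutions S989P, V1016I/G
    and F1534C in Aedes aegypti. Implements derivative melt-curve peak
    detection with the +/-0.3 degree-Celsius control-window calling rule, an
    explicit confusability model for the non-target 1016 allele in the
    V1016I and V1016G assays with constraint-intersection resolution of the
    three-allele 1016 locus, interpretation of allele-specific PCR band
    patterns, amplicon-read codon genotyping with barcode, quality and
    coverage filtering, COI consensus species verification, multi-method
    concordance reporting, and reflex ("gatekeeper") screening workflow
    rules. Includes seeded synthetic-data generators for melt curves,
    diploid cohorts with kdr haplotype linkage, and barcoded amplicon reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
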