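# kdrcall

Multi-assay genotyping of knockdown-resistance (*kdr*) mutations in
*Aedes aegypti*, for insecticide-resistance surveillance programs and the
laboratories that support them.

## Why

Pyrethroid resistance in *Ae. aegypti* is dominated by substitutions in
the voltage-gated sodium channel: the Western-Hemisphere ensemble
(1016I + 1534C) and the Indopacific ensemble (989P + 1016G), in
*M. domestica* numbering. The standard melt-curve assays (MCAs) used in
the Americas were designed for a two-allele world, and the third 1016
allele breaks them silently:

* in the **V1016I** assay, a 1016G product melts like 1016V — the map is
  V→Vclass, G→Vclass, I→Iclass, so {VV, VG, GG} are indistinguishable;
* in the **V1016G** assay, 1016I melts 0.8 °C below 1016V but both read
  "non-G" — G→Gclass, V→nonG, I→nonG, so {VV, VI, II} are
  indistinguishable;
* in the 1016 allele-specific PCR, 1016I can amplify weakly with the
  V-specific primer.

A GG (strongly resistant) population screens as VV (susceptible) under
the legacy assay. `kdrcall` makes the confusability explicit and
computable: each assay is a total map from alleles to observable classes,
each observation constrains the set of diploid genotypes, and the 1016
genotype is resolved by intersecting constraints across assays and
methods. Running both 1016 MCAs yields an injective joint outcome map
over all six diploid genotypes (proven exhaustively in the test suite) —
one assay alone never suffices.

The package also implements:

* derivative melt-curve peak detection and the ±0.3 °C control-window
  calling rule, with control-based run validation;
* AS-PCR band interpretation (weak-V semantics, dropout-tolerant absent
  bands) and Sanger allele calls as resolver inputs;
* an amplicon-sequencing pipeline — mean-Q ≥ 10 read filter,
  double-ended barcode demultiplexing (> 37 aligned bases, > 95%
  identity per end), Smith–Waterman alignment to an annotated amplicon
  panel, per-codon pileup genotyping with the 100× per-amplicon coverage
  rule, and COI consensus species verification at a 99% identity
  threshold;
* multi-method concordance tables and per-allele confirmation
  (≥ 2 independent unambiguous detections), including a packaged
  transcription of the published 18-sample multi-method comparison;
* reflex ("gatekeeper") screening rules: keep the legacy V1016I + F1534C
  tier and reflex every 1534F-bearing sample to V1016G and S989P, or run
  both 1016 assays on everything;
* seeded synthetic-data generators (Gaussian-peak melt curves, linked
  Hardy–Weinberg cohorts, barcoded diploid amplicon reads with
  configurable error and dropout) so every stage is testable against
  known truth.

## Worked example

```r
library(kdrcall)

# The packaged 18-row multi-method comparison (11 field samples, 7 controls)
tbl <- load_table1()
cc  <- build_concordance(tbl)
cc
#> <concordance_table> 18 records (11 field, 7 control)
#> MCA genotype tallies:
#>
#> GGFF GIFC IICC IIFC VGFC VICC VIFC VVFF
#>    1    7    2    1    1    2    2    1
#> 1016G-positive (field): MCA 8, AS-PCR 5, Sanger 4, NGS 6
#> 989P among NGS 1016G-positives (field): 3
#> NGS no-calls among tested: 4 of 16
#> COI identity >= 99%: 12 of 14
```

Eight field samples show a 1016G by melt assay (seven GIFC, one VGFC);
five are corroborated by a G band in AS-PCR, four by Sanger, six by
amplicon sequencing, and three of the sequenced G-positives also carry
989P — the package recomputes every one of these tallies from the raw
record strings. Resolving one sample across its methods:

```r
resolve_1016(list(
  mca_observation("V1016I_MCA", c("Vclass", "Iclass")),  # het pattern
  mca_observation("V1016G_MCA", c("Gclass", "nonG"))))   # G plus non-G
#> <resolution_result> resolved: {GI}
```

Simulated end-to-end genotyping of one mosquito:

```r
panel    <- build_reference_panel()
barcodes <- make_barcodes(8)
truth    <- parse_shorthand("SPGIFC")
reads    <- gen_reads(truth, panel, barcodes$sequence[2],
                      generator_config(), seed = 77, sample_id = "demo")
genotype_sample(reads, barcodes$barcode_id[2], barcodes, panel)
#> <sample_genotype> SPGIFC
#> <species_call> Aedes aegypti (synthetic) (KY022526.1) 100.00% PASS
```

And the screening workload question a program manager actually asks:

```r
plan <- screen_cohort(tbl, screening_strategy("legacy_reflex"))
plan
#> <screening_plan legacy_reflex> 18 samples, 13 trigger reflex testing
```

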