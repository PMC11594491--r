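---
title: "Multi-assay kdr genotyping: models, calling rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-assay kdr genotyping: models, calling rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrcall)
```

## The problem

Pyrethroid resistance in *Aedes aegypti* is driven largely by knockdown
resistance (*kdr*) substitutions in the voltage-gated sodium channel,
named by *Musca domestica* residue numbering. Two ensembles matter
operationally: 1016I with 1534C (the Western-Hemisphere ensemble) and 989P
with 1016G (the Indopacific ensemble). Surveillance programs in the
Americas have historically assayed only V1016I and F1534C, because 1016G
and 989P were assumed absent — but the standard allele-specific melt-curve
assays (MCAs) are *confusable*: a non-target allele produces a product
whose melting temperature (Tm) matches a target allele's. A 1016G sample
looks like 1016V in the V1016I assay, and a 1016I sample reports as non-G
in the V1016G assay. A population fixed for the strongly resistant GG
genotype would therefore screen as wild-type VV under the legacy assay —
the worst possible surveillance failure.

`kdrcall` implements the full reasoning chain a laboratory needs once both
ensembles can co-occur: explicit confusability models per assay,
constraint-intersection resolution of the three-allele 1016 locus across
methods (MCA, allele-specific PCR, Sanger, amplicon sequencing),
multi-method confirmation bookkeeping, an amplicon-read genotyping
pipeline with coverage rules and COI species verification, and the
reflex-testing workflow rules.

## Domain model

Genotypes are unordered diploid allele pairs at 989 (S/P), 1016 (V/I/G)
and 1534 (F/C), serialized in the field's shorthand ("SSGIFC", "VGFC").
The per-locus print order (S<P, V<G<I, F<C) was inferred from published
genotype strings and lives on the locus object as data, not in code, since
its generalization to other loci is not established. A 4-letter shorthand
leaves 989 *unknown* — it is never silently promoted to "SS", because the
legacy assay tier simply does not observe that locus.

```{r}
parse_shorthand("SPGIFC")
classify_ensemble("SPGIFC")
```

The ensemble classifier is total over all 54 genotypes: western-hemisphere
(some I and some C, no Indopacific allele), indopacific (some G or P, no
I), mixed (both), susceptible-like (VV/FF with SS-or-unknown 989), other.

## Melt-curve calling

A derivative melt curve is reduced to peaks by a centered moving average
(window 5 grid points, configurable — the published calling is
instrument-side, so some smoothing convention had to be fixed), local
maxima with parabolic apex refinement, a relative secondary-peak floor
(`min_rel_height = 0.2` of the tallest peak; how small a true
heterozygote's minor peak may be is not reported, so this is a calibration
chosen to keep artificial-heterozygote fixtures callable), and a cap of
three reported peaks.

Calling follows the control-window rule: a peak asserts the allele class
whose control Tm lies within ±0.3 °C; if two classes qualify the nearest
control wins and a warning is attached. Control Tm values are **run data**
from control wells, never constants: the source study prints no absolute
Tm values, only the ±0.3 °C window and the 0.8 °C offset of the 1016I
product below the 1016V product in the V1016G assay. The packaged fixture
table is therefore synthetic:

| assay | Tm classes (°C) | interpretive classes |
|---|---|---|
| V1016I | V-class 79.0 (G alleles also land here), I-class 84.0 | Vclass / Iclass |
| V1016G | G 80.0, I-product 83.2, non-G (V) 84.0 | Gclass / nonG (both non-G products fold to nonG) |
| F1534C | F 78.0, C 82.0 | Fclass / Cclass |

Two deliberate choices here. First, the V-class and I-class products of
the V1016I assay are separated widely (5 °C): competitive allele-specific
primers are designed to yield well-separated products, and a spacing
smaller than twice the calling window would make the assay's own
homozygote calls unstable — the assay-definition constructor enforces
pairwise spacing > 2× tolerance unless a pair is documented confusable.
Second, the V1016G assay carries a *finer* Tm-class table than its
interpretive output: the I product is distinguishable by Tm (0.8 °C below
V), but the assay's epistemic content is only "G versus not-G", so both
non-G Tm classes fold to `nonG`. This keeps the Tm-level physics (needed
to reproduce the 0.8 °C offset measurement) separate from the inference
layer (where I-vs-V from this assay alone is never asserted).

Run validation mirrors laboratory practice: every allele needs a
homozygous control, alternate alleles need heterozygous controls
(competitive-primer balance), and the blank must be silent. A failed
*heterozygous* control downgrades the run to valid-with-warning rather
than invalid — the observed failure mode in practice — while a failed
homozygous or negative control invalidates it.

## The confusability model and 1016 resolution

Each assay is a total map from alleles to observable classes:

```{r}
virtual_assay_models()
```

An observation constrains the six diploid 1016 genotypes to those whose
predicted outcome matches (MCA, Sanger pair, sequencing genotype) or is
compatible with it (AS-PCR bands: strong V ⇒ ≥1 V; weak V ⇒ ≥1 V or I,
encoding the observed cross-amplification of the I allele with the
V-specific primer; any G band ⇒ ≥1 G). An **absent band excludes
nothing** by default: record tables show true heterozygotes with single
bands and frequent whole-method no-calls, so treating absence as evidence
would fabricate conflicts. A `strict_bands` mode is available when band
dropout can be ruled out.

A lone Sanger symbol is likewise read as "allele present", not
homozygosity: a field record shows a Sanger "G" on a sample that
sequencing resolves as VG, so a single clean peak is weaker evidence than
two in-phase peaks.

Resolution intersects the per-method constraint sets. Either 1016 MCA
alone leaves three genotypes indistinguishable ({VV, VG, GG} for V1016I;
{VV, VI, II} for V1016G — and, necessarily, each assay also merges the
two heterozygote patterns it cannot separate); together the joint outcome
map is injective over all six genotypes, which is the package's central
theorem and is verified exhaustively in the test suite. An allele is
*confirmed* when it appears in every candidate genotype and was
unambiguously detected — its own class, band or base — by at least two
distinct methods (threshold configurable). The resolver trusts
observations, not sample labels: a mislabeled control resolves cleanly to
what the data say, and conflicts are reported with a minimal conflicting
method pair.

```{r}
resolve_1016(list(
  mca_observation("V1016I_MCA", c("Vclass", "Iclass")),
  mca_observation("V1016G_MCA", c("Gclass", "nonG"))))
```

## Amplicon-read genotyping

The sequencing pipeline replaces external mapping/inspection tools with
internal, fully specified equivalents, all built on exact Smith–Waterman
alignment (`Biostrings`), scores fixed at match +2 / mismatch −4 / gap
open −4 / gap extend −2:

* **Read filter**: mean per-base Phred quality ≥ 10, interpreting the
  platform's read-level pass filter; bases are not individually masked.
  Only Phred+33 is accepted; out-of-range quality characters are refused,
  never reinterpreted.
* **Demultiplexing**: a read is assigned to a barcode when a local
  alignment of the barcode region against *each* read end spans more than
  37 aligned columns at more than 95% identity (aligned length, i.e.
  alignment columns, is used — the published filter does not say whether
  raw or aligned length is meant, and aligned length is the quantity the
  filter can actually compute). Reads matching zero or several barcodes
  are unassigned. A k-mer prescreen picks candidate barcodes and an exact
  substring hit short-circuits the alignment; both affect speed only.
* **Alignment**: best local alignment over all panel references and both
  strands; minus-strand reads are reverse-complemented first, so all
  downstream coordinates are reference-sense. The unaligned floor is 40%
  of the read's perfect-match score, far above the score a 500-base random
  read attains against the panel (checked empirically in the tests).
* **Codon pileup**: each spanning read's codon is adjudicated by
  allele-aware local realignment — the read segment covering the codon
  neighborhood (±10 bases) is aligned against the reference window
  carrying each known allele codon, and the observed 3-mer is taken from
  the strictly best-scoring variant; a tie between variants, or a
  deletion inside the winning codon, excludes the read for either allele
  equally, and bases inserted between codon positions are not part of the
  3-mer. Reading the codon straight off the whole-amplicon alignment is
  measurably reference-biased: that alignment knows only the reference
  codon, so when a read carries an alternate codon plus a nearby indel,
  equally scoring gap placements are resolved toward hiding the codon
  mismatch — for example, an inserted copy of a flank base pairing with
  the reference codon base while the read's true allele base is written
  off as the insertion. Variant-aware scoring removes this asymmetry (the
  simulation suite verifies pooled heterozygote allele fractions against
  99% binomial bounds). Reporting is sense-strand throughout — a single
  convention avoids double-complement errors even where displays
  conventionally show the antisense strand.
* **Genotype call**: coverage below 100 spanning reads is a no-call and
  excludes the whole sample (the coverage rule is per amplicon — "any
  amplicon" — not per sample total). Codons translate through a
  per-locus codon table (fixture data: 989 TCC/CCC, 1016 GTA/ATA/GGA,
  1534 TTC/TGC); unknown codons pool as `other`, and an `other` fraction
  above 1 − 0.80 is a no-call (`unknown_codon`). The homozygote (0.80)
  and heterozygote (0.20) fraction thresholds apply to fractions
  renormalized over reads with a recognized allele codon: at a 5%
  per-base error rate roughly 11% of spanning reads carry an unrecognized
  codon, and thresholding raw fractions of total coverage would
  mis-reject several percent of true homozygotes for no biological
  reason. The raw per-allele fractions (including `other`) are reported
  alongside every call.
* **COI species check**: per-column majority consensus (ties → N,
  majority-deletion columns omitted) over columns with ≥ 100 spanning
  reads, then ends-free alignment against the packaged COI reference set;
  identity is matches over aligned columns excluding end gaps, pass at
  ≥ 99%.

## Synthetic data: what it emulates, what it does not

The generators provide every stage's inputs with the statistical
structure the analysis assumes. Melt curves are sums of one Gaussian per
distinct product Tm class (centers jittered, sd 0.1 °C; white noise;
heights 1.0 ± 20% — relative heterozygote peak heights are not reported,
so equal heights are an assumption). The peak width (sd 0.25 °C) is
chosen so the two non-G products of the V1016G assay, 0.8 °C apart,
remain bimodal in a heterozygote; a substantially wider peak would merge
them into one uncallable bump, contradicting the premise that the assay
resolves its own heterozygous controls. Class-targeted dropout
(`dropout$mca_class = c(Gclass = 1)`) reproduces the known failure mode
of a heterozygous control losing its G peak.

Cohorts are Hardy–Weinberg draws; in linkage mode haplotypes rather than
alleles are sampled, so every 1016G allele sits on a 1534F background and
every 1016I on 1534C, the documented unidirectional linkage. Default
frequencies (I 0.85, G 0.036, C 0.96, P on half of G haplotypes) emulate
a contemporary Florida population with rare Indopacific arrivals.

Reads are full-length amplicons (four per sample: three kdr regions plus
COI) drawn fairly from the two haplotypes, with 5% substitutions and 0.5%
insertions/deletions per base, barcode regions at both ends (1%
substitution error) and random strand. The panel itself is a synthetic
stand-in — pseudo-random flanks at a fixed seed with the real kdr codons
embedded, and COI references labeled with accession-style strings but
generated, not downloaded; users genotyping real data supply their own
FASTA panel. What the simulator does **not** model: signal-level
basecalling, homopolymer-biased indels, chimeric reads, or quality values
correlated with true error positions. Passing the recovery suite
therefore demonstrates the pipeline's logic and thresholds, not
performance on a real flow cell.

## Numerical and procedural choices

* Grid: 70–95 °C at 0.05 °C; peak Tm refined by parabolic interpolation,
  so grid discretization contributes < 0.01 °C.
* Tolerance comparisons use `<= tolerance + 1e-9`: a peak exactly at the
  window edge is inside it.
* Nearest-control tie-breaks always attach a warning; unassignable peaks
  are ignored with a warning rather than failing the call.
* `find_peaks` returns at most 3 peaks (no assay here has more than three
  classes) sorted by height, with a simple saddle-based prominence.
* The fraction thresholds (0.80/0.20) are deliberately far from both the
  heterozygote expectation (0.5 ± binomial noise at 100×) and the
  error-driven minor-allele load (~2–3%), and are exposed as parameters
  and in the run report.
* Deterministic throughout: every stochastic operation takes an explicit
  seed; identical seed and inputs give byte-identical outputs.

## Problem sizes used by the packaged checks

The shipped verification suite proves the disambiguation theorem
exhaustively (6 genotypes, 2 assays), checks shorthand round-trips over
all 54 full genotypes, measures the Tm offset over 100 simulated curves
per homozygote, calls 1,000 noisy homozygote curves for the accuracy
bound, and runs the full read pipeline over 200 simulated samples
spanning all 54 genotypes at 200× coverage and 5% substitution error
(with smaller targeted runs for the coverage-exclusion and
strand-invariance properties). These sizes were chosen to make the
binomial error bounds meaningful while keeping a full run on a single
CPU comfortable.

## Known limitations and open points

* A published tally ("6 of the 10" samples giving an AS-PCR result) does
  not match the transcribed record table (11 field rows, 7 with a
  non-empty AS-PCR cell); the package reports counts from the table as
  printed and leaves the discrepancy documented rather than reconciled.
* With the 0.8 °C I-product offset and the ±0.3 °C window, a whole-curve
  shift of +1.0 °C moves an I-homozygote peak *into* the non-G window:
  large calibration drift in the V1016G assay changes that call's class
  rather than voiding it. This is a geometric property of the published
  numbers, and is asserted as such in the tests; the safeguard against
  drift is the control-validation step, not the window rule.
* The set-valued resolution logic deliberately carries no probabilities;
  a likelihood layer over the same constraint structure would be the
  natural extension.
* Phasing across loci is out of reach of these assays (and of dried
  field specimens); linkage is used only generatively, never inferentially.
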