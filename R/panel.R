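# Synthetic stand-in reference panel. The study mapped reads to genome
# slices and a GenBank COI record; those sequences are not redistributed
# here, so the packaged panel is generated pseudo-randomly at a fixed,
# documented seed with the real kdr codons embedded at annotated positions.
# Users genotyping real data should load their own FASTA panel.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# vectorized reverse complement; base-R (utf8 codes) because the per-call
# overhead of an XStringSet round-trip dominates short-sequence workloads
revcomp <- function(x) {
  vapply(chartr("ACGTN", "TGCAN", x),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

#' Codon tables for the packaged kdr loci
#'
#' Sense-strand codons for each allele: 989 S=TCC/P=CCC, 1016
#' V=GTA/I=ATA/G=GGA, 1534 F=TTC/C=TGC. Codon tables are data, not code;
#' supply your own named list to the pileup caller for other loci.
#'
#' @return Named list (by locus) of named character vectors codon -> allele.
#' @export
default_codon_tables <- function() {
  list("989"  = c(TCC = "S", CCC = "P"),
       "1016" = c(GTA = "V", ATA = "I", GGA = "G"),
       "1534" = c(TTC = "F", TGC = "C"))
}

#' Build the synthetic amplicon reference panel
#'
#' Four amplicons — M1 (carries codon 989), M2 (1016), M3 (1534) and COI —
#' plus a small COI reference set for species identification. Amplicon
#' flanks are pseudo-random at the given seed; each kdr amplicon embeds the
#' locus's reference codon at an annotated 1-based start position. The COI
#' reference set contains several *Ae. aegypti*-labeled synthetic sequences
#' (a few substitutions apart, labeled with accession-style strings) and
#' one diverged outgroup.
#'
#' @param seed Integer seed for the pseudo-random flanks (default 10863).
#' @param amplicon_length Length of the kdr amplicons (default 360).
#' @param coi_length Length of the COI amplicon/references (default 658).
#' @return An object of class `reference_panel`: list with `amplicons`
#'   (named character vector M1/M2/M3/COI), `codon_start`, `locus_amplicon`,
#'   `codon_tables`, `coi_references` (data.frame taxon, accession,
#'   sequence).
#' @export
build_reference_panel <- function(seed = 10863, amplicon_length = 360,
                                  coi_length = 658) {
  stopifnot(amplicon_length >= 60, coi_length >= 100)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  tables <- default_codon_tables()
  ref_codon <- c("989" = "TCC", "1016" = "GTA", "1534" = "TTC")
  codon_start <- floor(amplicon_length / 2) + 1L
  mk_amp <- function(locus) {
    s <- rand_dna(amplicon_length)
    paste0(substr(s, 1, codon_start - 1L), ref_codon[[locus]],
           substr(s, codon_start + 3L, amplicon_length))
  }
  amplicons <- c(M1 = mk_amp("989"), M2 = mk_amp("1016"), M3 = mk_amp("1534"),
                 COI = rand_dna(coi_length))
  # COI references: aegypti-like = the COI amplicon with 0-4 substitutions;
  # outgroup ~12% diverged
  mutate_k <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  coi <- amplicons[["COI"]]
  coi_references <- data.frame(
    taxon = c(rep("Aedes aegypti (synthetic)", 5),
              "Aedes albopictus-like outgroup (synthetic)"),
    accession = c("KY022526.1", "MN299016.1", "MK300224.1", "MK300218.1",
                  "PP902511.1", "SYN000001.1"),
    sequence = c(coi, coi, mutate_k(coi, 2), mutate_k(coi, 4),
                 mutate_k(coi, 3), mutate_k(coi, round(0.12 * coi_length))),
    stringsAsFactors = FALSE)
  structure(list(
    amplicons = amplicons,
    codon_start = c("989" = codon_start, "1016" = codon_start,
                    "1534" = codon_start),
    locus_amplicon = c("989" = "M1", "1016" = "M2", "1534" = "M3"),
    codon_tables = tables,
    coi_references = coi_references),
    class = "reference_panel")
}

# save/restore .Random.seed so fixture builders do not disturb user RNG state
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>\n")
  for (nm in names(x$amplicons))
    cat(sprintf("  %s: %d bp%s\n", nm, nchar(x$amplicons[[nm]]),
                if (nm %in% x$locus_amplicon)
                  sprintf(" (codon %s at %d)",
                          names(x$locus_amplicon)[x$locus_amplicon == nm],
                          x$codon_start[[names(x$locus_amplicon)[
                            x$locus_amplicon == nm]]])
                else ""))
  cat(sprintf("  COI references: %d\n", nrow(x$coi_references)))
  invisible(x)
}

#' Write / read a reference panel as FASTA + JSON annotations
#'
#' The amplicons and COI references go to FASTA (COI reference names are
#' `accession|taxon`); codon starts, locus-amplicon mapping and codon
#' tables go to a JSON sidecar.
#'
#' @param panel A `reference_panel`.
#' @param fasta_path,json_path Output paths.
#' @export
write_panel <- function(panel, fasta_path, json_path) {
  seqs <- c(panel$amplicons,
            stats::setNames(panel$coi_references$sequence,
                            paste0("COIREF:", panel$coi_references$accession,
                                   "|", panel$coi_references$taxon)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  jsonlite::write_json(
    list(codon_start = as.list(panel$codon_start),
         locus_amplicon = as.list(panel$locus_amplicon),
         codon_tables = lapply(panel$codon_tables, as.list)),
    json_path, auto_unbox = TRUE)
  invisible(panel)
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta_path, json_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- jsonlite::fromJSON(json_path)
  nm <- names(seqs)
  is_coi_ref <- startsWith(nm, "COIREF:")
  amps <- stats::setNames(as.character(seqs[!is_coi_ref]), nm[!is_coi_ref])
  refs <- nm[is_coi_ref]
  acc_tax <- strsplit(sub("^COIREF:", "", refs), "|", fixed = TRUE)
  coi_references <- data.frame(
    taxon = vapply(acc_tax, `[`, character(1), 2),
    accession = vapply(acc_tax, `[`, character(1), 1),
    sequence = as.character(seqs[is_coi_ref]),
    stringsAsFactors = FALSE)
  structure(list(
    amplicons = amps,
    codon_start = unlist(ann$codon_start),
    locus_amplicon = unlist(ann$locus_amplicon),
    codon_tables = lapply(ann$codon_tables, unlist),
    coi_references = coi_references),
    class = "reference_panel")
}

#' Generate a synthetic barcode table
#'
#' Pseudo-random barcode-region sequences (default 40 bp, i.e. longer than
#' the 37-base aligned-length filter) attached to both read ends by the
#' read simulator.
#'
#' @param n Number of barcodes.
#' @param length Barcode region length in bases.
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return A data.frame with columns `barcode_id`, `sequence`.
#' @export
make_barcodes <- function(n, length = 40L, seed = 4242, prefix = "BC") {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  repeat {
    seqs <- vapply(seq_len(n), function(i) rand_dna(length), character(1))
    if (!anyDuplicated(seqs)) break
  }
  data.frame(barcode_id = sprintf("%s%03d", prefix, seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}
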