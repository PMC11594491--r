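# Codon pileup genotyping and COI consensus / species identification.

#' Build a codon pileup at a kdr locus
#'
#' Counts the read 3-mer over the annotated codon for every read whose
#' alignment spans all three codon positions. Minus-strand reads were
#' reverse-complemented at alignment time, so all counting is on the sense
#' strand; bases inserted between codon positions are not part of the
#' reported 3-mer. Coverage is the number of counted reads.
#'
#' The 3-mer is adjudicated by allele-aware local realignment rather than
#' read off the whole-amplicon alignment: the read segment covering the
#' codon neighborhood is aligned against the reference window carrying
#' each known allele codon, and the codon comes from the strictly
#' best-scoring variant. The whole-amplicon alignment knows only the
#' reference codon, so when a read carries an alternate codon plus a
#' nearby indel, equally scoring gap placements are resolved toward hiding
#' the codon mismatch — depleting alternate alleles (reference bias).
#' Variant-aware scoring is symmetric; a scoring tie between variants, or
#' a deletion inside the winning variant's codon, excludes the read for
#' either allele equally.
#'
#' @param alignments An `alignment_set` from [align_reads()].
#' @param panel The `reference_panel` carrying the codon annotation.
#' @param locus Locus name (`"989"`, `"1016"`, `"1534"`).
#' @param realign_window Half-width (bases) of the codon neighborhood used
#'   for allele-aware realignment (default 10).
#' @return An object of class `codon_pileup`: list with `locus`,
#'   `codon_counts` (named integer vector), `coverage`.
#' @export
codon_pileup <- function(alignments, panel, locus, realign_window = 10L) {
  if (!locus %in% names(panel$locus_amplicon))
    stop("locus ", locus, " is not annotated on the panel")
  amp <- panel$locus_amplicon[[locus]]
  cs <- panel$codon_start[[locus]]
  a <- alignments[alignments$ref == amp, , drop = FALSE]
  codons <- character(0)
  if (nrow(a)) {
    spans <- a$ref_start <= cs & a$ref_end >= cs + 2L
    a <- a[spans, , drop = FALSE]
    # Every spanning read's codon is adjudicated by local realignment of
    # its codon neighborhood against the reference window carrying each
    # known allele codon. Extracting the 3-mer from the whole-amplicon
    # alignment alone is reference-biased: that alignment knows only the
    # reference codon, and when a read carries an alternate codon plus a
    # nearby indel, equally scoring gap placements are resolved in favor
    # of hiding the codon mismatch — i.e. toward the reference allele.
    # Allele-aware scoring is symmetric, and a scoring tie between
    # variants excludes the read (for either allele equally).
    codons <- realign_codon(a, panel, amp, cs, locus, realign_window)
    codons <- codons[!grepl("-", codons, fixed = TRUE) & nchar(codons) == 3L]
  }
  counts <- integer(0)
  if (length(codons)) {
    tab <- table(codons)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(locus = locus, codon_counts = counts,
                 coverage = sum(counts)),
            class = "codon_pileup")
}

# Allele-aware local realignment of reads whose codon alignment is gapped.
# Returns the recovered 3-mer per read, or "-" when the read stays excluded.
realign_codon <- function(rows, panel, amp, cs, locus, w) {
  ref <- panel$amplicons[[amp]]
  ws <- max(1L, cs - w)
  we <- min(nchar(ref), cs + 2L + w)
  codon_pos <- cs - ws + 1L
  variants <- names(panel$codon_tables[[locus]])
  win <- substr(ref, ws, we)
  var_windows <- vapply(variants, function(cd)
    paste0(substr(win, 1L, codon_pos - 1L), cd,
           substr(win, codon_pos + 3L, nchar(win))), character(1))
  # approximate read segment covering the window (slack absorbs indels)
  slack <- 6L
  seg_start <- pmax(1L, rows$read_start + (ws - rows$ref_start) - slack)
  seg_end <- pmin(nchar(rows$read_bases),
                  rows$read_start + (we - rows$ref_start) + slack)
  segs <- substr(rows$read_bases, seg_start, seg_end)
  n <- nrow(rows)
  scores <- matrix(-Inf, n, length(variants))
  cod <- matrix("-", n, length(variants))
  usable <- nchar(segs) >= (we - ws + 1L) - slack
  for (v in seq_along(variants)) {
    if (!any(usable)) break
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(segs[usable]),
      Biostrings::DNAString(var_windows[[v]]), type = "overlap",
      substitutionMatrix = sub_matrix(),
      gapOpening = aln_scores()$gap_open,
      gapExtension = aln_scores()$gap_extend)
    scores[usable, v] <- Biostrings::score(aln)
    al <- as.character(Biostrings::aligned(aln))
    cod[usable, v] <- substr(al, codon_pos, codon_pos + 2L)
  }
  out <- rep("-", n)
  for (i in seq_len(n)) {
    if (!usable[i]) next
    best <- which(scores[i, ] == max(scores[i, ]))
    if (length(best) != 1L) next  # tie: stay excluded
    out[i] <- cod[i, best]
  }
  out
}

#' @export
print.codon_pileup <- function(x, ...) {
  cat(sprintf("<codon_pileup %s> coverage %d\n", x$locus, x$coverage))
  if (length(x$codon_counts)) print(sort(x$codon_counts, decreasing = TRUE))
  invisible(x)
}

#' Call a diploid genotype from a codon pileup
#'
#' Applies the coverage rule first: fewer than `min_coverage` spanning
#' reads is a no-call with reason `low_coverage`. Codons are translated to
#' alleles through `codon_table`; unrecognized codons (sequencing error) are
#' pooled as `other`, and an `other` fraction above `1 - hom_min_fraction`
#' is a no-call with reason `unknown_codon`. Calling thresholds are applied
#' to allele fractions renormalized over reads carrying a recognized allele
#' codon (so a uniform error load does not bias calls): homozygous when the
#' top allele reaches `hom_min_fraction`, heterozygous when the top two
#' each reach `het_min_fraction`, otherwise a no-call with reason
#' `ambiguous_fraction`.
#'
#' @param pileup A [codon_pileup()].
#' @param codon_table Named character vector codon -> allele symbol for the
#'   locus.
#' @param min_coverage Minimum spanning reads (default 100).
#' @param het_min_fraction Minimum renormalized fraction for each allele of
#'   a heterozygote (default 0.20).
#' @param hom_min_fraction Minimum renormalized fraction of a homozygote's
#'   allele (default 0.80).
#' @return An object of class `pileup_call`: list with `locus`, `genotype`
#'   (length-2 allele vector or `NULL`), `status`, `no_call_reason`,
#'   `allele_fractions` (of total coverage, including `other`), `coverage`.
#' @export
call_genotype <- function(pileup, codon_table, min_coverage = 100L,
                          het_min_fraction = 0.20, hom_min_fraction = 0.80) {
  stopifnot(inherits(pileup, "codon_pileup"))
  mk <- function(genotype, status, reason, fracs) {
    structure(list(locus = pileup$locus, genotype = genotype, status = status,
                   no_call_reason = reason, allele_fractions = fracs,
                   coverage = pileup$coverage),
              class = "pileup_call")
  }
  if (pileup$coverage < min_coverage)
    return(mk(NULL, "no_call", "low_coverage", NULL))
  alleles <- codon_table[names(pileup$codon_counts)]
  alleles[is.na(alleles)] <- "other"
  by_allele <- tapply(pileup$codon_counts, alleles, sum)
  fracs <- as.numeric(by_allele) / pileup$coverage
  names(fracs) <- names(by_allele)
  other <- if ("other" %in% names(fracs)) fracs[["other"]] else 0
  if (other > 1 - hom_min_fraction)
    return(mk(NULL, "no_call", "unknown_codon", fracs))
  known <- fracs[names(fracs) != "other"]
  if (!length(known))
    return(mk(NULL, "no_call", "unknown_codon", fracs))
  ren <- known / sum(known)
  ren <- sort(ren, decreasing = TRUE)
  if (ren[1] >= hom_min_fraction)
    return(mk(rep(names(ren)[1], 2L), "called", NA_character_, fracs))
  if (length(ren) >= 2L && ren[1] >= het_min_fraction &&
      ren[2] >= het_min_fraction)
    return(mk(c(names(ren)[1], names(ren)[2]), "called", NA_character_, fracs))
  mk(NULL, "no_call", "ambiguous_fraction", fracs)
}

#' @export
print.pileup_call <- function(x, ...) {
  if (x$status == "called") {
    cat(sprintf("<pileup_call %s> %s (coverage %d)\n", x$locus,
                paste(x$genotype, collapse = "/"), x$coverage))
  } else {
    cat(sprintf("<pileup_call %s> no_call: %s (coverage %d)\n", x$locus,
                x$no_call_reason, x$coverage))
  }
  if (!is.null(x$allele_fractions)) {
    f <- sort(x$allele_fractions, decreasing = TRUE)
    cat(" ", paste(sprintf("%s=%.3f", names(f), f), collapse = " "), "\n")
  }
  invisible(x)
}

#' COI consensus from aligned reads
#'
#' Per-column majority base over the reads aligned to the COI amplicon,
#' restricted to reference columns covered by at least `min_coverage`
#' spanning reads. Ties go to `N`; columns whose majority vote is a
#' deletion are omitted from the consensus.
#'
#' @param alignments An `alignment_set`.
#' @param panel The `reference_panel`.
#' @param min_coverage Minimum per-column coverage (default 100).
#' @return The consensus sequence (character scalar), or `NULL` when no
#'   column reaches `min_coverage`.
#' @export
coi_consensus <- function(alignments, panel, min_coverage = 100L) {
  a <- alignments[alignments$ref == "COI", , drop = FALSE]
  if (!nrow(a)) return(NULL)
  L <- nchar(panel$amplicons[["COI"]])
  # aligned strings are padded to full reference length: a position matrix
  m <- matrix(unlist(strsplit(a$aligned, "")), nrow = nrow(a), ncol = L,
              byrow = TRUE)
  # padding '-' outside [ref_start, ref_end] is absence, not a deletion vote
  col_idx <- matrix(rep(seq_len(L), each = nrow(a)), nrow = nrow(a))
  inside <- col_idx >= a$ref_start & col_idx <= a$ref_end
  m[!inside] <- " "
  lv <- c("A", "C", "G", "T", "N", "-")
  votes <- vapply(lv, function(b) colSums(m == b), numeric(L))
  cov <- rowSums(votes)
  keep <- cov >= min_coverage
  if (!any(keep)) return(NULL)
  votes <- votes[keep, , drop = FALSE]
  top <- max.col(votes, ties.method = "first")
  is_tie <- vapply(seq_len(nrow(votes)), function(i)
    sum(votes[i, ] == max(votes[i, ])) > 1L, logical(1))
  base <- lv[top]
  base[is_tie] <- "N"
  paste(base[base != "-"], collapse = "")
}

#' Identify species from a COI consensus
#'
#' Ends-free (overlap) alignment of the consensus against each reference in
#' the panel's COI set; percent identity is matches over aligned columns
#' (internal gaps counted, end gaps excluded). Passing threshold is 99%
#' identity. A consensus shorter than half the best reference is flagged
#' low-confidence.
#'
#' @param consensus Consensus sequence (character scalar).
#' @param coi_references Data.frame with `taxon`, `accession`, `sequence`
#'   (e.g. `panel$coi_references`).
#' @param threshold Percent-identity pass threshold (default 99).
#' @return An object of class `species_call`: list with `taxon`,
#'   `accession`, `percent_identity`, `pass_threshold`, `low_confidence`,
#'   `all_identities`.
#' @export
identify_species <- function(consensus, coi_references, threshold = 99) {
  stopifnot(nrow(coi_references) >= 1L)
  if (is.null(consensus) || !nchar(consensus))
    return(structure(list(taxon = NA_character_, accession = NA_character_,
                          percent_identity = NA_real_, pass_threshold = FALSE,
                          low_confidence = TRUE, all_identities = NULL),
                     class = "species_call"))
  pid <- numeric(nrow(coi_references))
  for (i in seq_len(nrow(coi_references))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(consensus),
      Biostrings::DNAString(coi_references$sequence[i]),
      type = "overlap", substitutionMatrix = sub_matrix(),
      gapOpening = aln_scores()$gap_open,
      gapExtension = aln_scores()$gap_extend)
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    pid[i] <- 100 * Biostrings::nmatch(aln) / cols
  }
  best <- which.max(pid)
  structure(list(
    taxon = coi_references$taxon[best],
    accession = coi_references$accession[best],
    percent_identity = pid[best],
    pass_threshold = pid[best] >= threshold,
    low_confidence = nchar(consensus) <
      0.5 * nchar(coi_references$sequence[best]),
    all_identities = stats::setNames(pid, coi_references$accession)),
    class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  if (is.na(x$percent_identity)) {
    cat("<species_call> no consensus\n")
  } else {
    cat(sprintf("<species_call> %s (%s) %.2f%%%s%s\n", x$taxon, x$accession,
                x$percent_identity,
                if (x$pass_threshold) " PASS" else " below threshold",
                if (x$low_confidence) " [low confidence]" else ""))
  }
  invisible(x)
}

#' End-to-end amplicon genotyping of one sample
#'
#' Composition of the pipeline stages: mean-quality filter, double-ended
#' barcode demultiplexing, panel alignment, per-locus codon pileup and
#' genotype call, COI consensus and species identification. The sample is
#' a no-call whenever any kdr amplicon fails the coverage rule (the
#' exclusion applies per amplicon, not per sample-wide total).
#'
#' @param reads A `read_set` (the run's reads, or the sample's).
#' @param barcode_id The sample's barcode identifier.
#' @param barcodes Barcode table (all run barcodes, for rejection of
#'   cross-talk).
#' @param panel A `reference_panel`.
#' @param min_mean_q,min_coverage,het_min_fraction,hom_min_fraction,
#'   min_match_length,min_identity,min_score_frac Stage parameters; see the
#'   stage functions.
#' @return An object of class `sample_genotype`: list with `status`
#'   (`"called"`/`"no_call"`), `no_call_reason`, `genotype` (a
#'   [multilocus_genotype()] or `NULL`), `shorthand`, `locus_calls`,
#'   `species`, `metrics` (reads in / passing / assigned, per-amplicon
#'   coverage).
#' @export
genotype_sample <- function(reads, barcode_id, barcodes, panel,
                            min_mean_q = 10, min_coverage = 100L,
                            het_min_fraction = 0.20, hom_min_fraction = 0.80,
                            min_match_length = 37L, min_identity = 0.95,
                            min_score_frac = 0.4) {
  mk <- function(status, reason, genotype, locus_calls, species, metrics) {
    shorthand <- if (!is.null(genotype)) format_shorthand(genotype)
                 else NA_character_
    structure(list(status = status, no_call_reason = reason,
                   genotype = genotype, shorthand = shorthand,
                   locus_calls = locus_calls, species = species,
                   metrics = metrics),
              class = "sample_genotype")
  }
  metrics <- list(reads_in = nrow(reads))
  passed <- quality_filter(reads, min_mean_q = min_mean_q)
  metrics$reads_passing <- nrow(passed)
  dmx <- demultiplex(passed, barcodes, min_match_length = min_match_length,
                     min_identity = min_identity)
  mine <- dmx$assigned[[barcode_id]]
  metrics$reads_assigned <- if (is.null(mine)) 0L else nrow(mine)
  if (is.null(mine) || nrow(mine) == 0L)
    return(mk("no_call", "no reads assigned at demultiplexing", NULL,
              NULL, NULL, metrics))
  aln <- align_reads(mine, panel, min_score_frac = min_score_frac)
  metrics$reads_aligned <- nrow(aln)

  loci <- names(panel$locus_amplicon)
  locus_calls <- list()
  for (locus in loci) {
    pu <- codon_pileup(aln, panel, locus)
    locus_calls[[locus]] <- call_genotype(
      pu, panel$codon_tables[[locus]], min_coverage = min_coverage,
      het_min_fraction = het_min_fraction,
      hom_min_fraction = hom_min_fraction)
  }
  metrics$coverage <- vapply(locus_calls, `[[`, numeric(1), "coverage")
  cons <- coi_consensus(aln, panel, min_coverage = min_coverage)
  species <- identify_species(cons, panel$coi_references)

  low <- vapply(locus_calls, function(x)
    x$status == "no_call" && identical(x$no_call_reason, "low_coverage"),
    logical(1))
  if (any(low))
    return(mk("no_call",
              paste0("low coverage at amplicon(s): ",
                     paste(panel$locus_amplicon[loci[low]], collapse = ",")),
              NULL, locus_calls, species, metrics))
  if (any(vapply(locus_calls, function(x) x$status != "called", logical(1))))
    return(mk("no_call", "locus-level no-call", NULL, locus_calls, species,
              metrics))
  g <- multilocus_genotype(g1016 = locus_calls[["1016"]]$genotype,
                           g1534 = locus_calls[["1534"]]$genotype,
                           g989 = locus_calls[["989"]]$genotype)
  mk("called", NA_character_, g, locus_calls, species, metrics)
}

#' @export
print.sample_genotype <- function(x, ...) {
  if (x$status == "called") {
    cat("<sample_genotype>", x$shorthand, "\n")
  } else {
    cat("<sample_genotype> no_call:", x$no_call_reason, "\n")
  }
  if (!is.null(x$species)) print(x$species)
  invisible(x)
}
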