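mk_reads <- function(bases, q = 20L) {
  qs <- vapply(nchar(bases), function(n)
    paste(rep(intToUtf8(q + 33L), n), collapse = ""), character(1))
  out <- data.frame(read_id = sprintf("r%03d", seq_along(bases)),
                    bases = bases, quals = qs, stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

test_that("the mean-quality filter keeps Q20, drops Q9 and rejects malformed reads", {
  reads <- mk_reads(c("ACGTACGTACGT", "ACGTACGTACGT"), q = 20L)
  reads$quals[2] <- paste(rep(intToUtf8(9L + 33L), 12L), collapse = "")
  out <- quality_filter(reads)
  expect_identical(out$read_id, "r001")
  expect_true(grepl("mean quality", attr(out, "rejected")$reason[1]))

  bad <- mk_reads("ACGTXCGT")
  out2 <- quality_filter(bad)
  expect_identical(nrow(out2), 0L)
  expect_identical(attr(out2, "rejected")$reason, "non-ACGTN symbol")

  mism <- mk_reads("ACGTACGT")
  mism$quals <- substr(mism$quals, 1, 4)
  expect_identical(attr(quality_filter(mism), "rejected")$reason,
                   "bases/quality length mismatch")

  empty <- mk_reads(character(0))
  expect_identical(nrow(quality_filter(empty)), 0L)
})

test_that("FASTQ round-trips and refuses out-of-range quality characters", {
  reads <- mk_reads(c("ACGTACGTAA", "TTTTACGTAC"), q = 30L)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$bases, reads$bases)
  expect_identical(back$quals, reads$quals)
})

test_that("demultiplexing requires a long, near-exact barcode match at both ends", {
  bcs <- make_barcodes(3, seed = 99)
  amp <- substr(fx_panel$amplicons[["M2"]], 1, 200)
  bc1 <- bcs$sequence[1]
  both <- paste0(bc1, amp, revcomp(bc1))
  one_end <- paste0(bc1, amp)
  trunc36 <- paste0(substr(bc1, 1, 36), amp, revcomp(substr(bc1, 1, 36)))
  two_codes <- paste0(bcs$sequence[2], amp, revcomp(bc1))
  reads <- mk_reads(c(both, one_end, trunc36, two_codes))

  dmx <- demultiplex(reads, bcs)
  expect_identical(dmx$assigned[[bcs$barcode_id[1]]]$read_id, "r001")
  expect_true(all(c("r002", "r003") %in% dmx$unassigned$read_id))
  # an end matching barcode 2 and an end matching barcode 1: unassigned
  expect_true("r004" %in% dmx$unassigned$read_id)

  # reads from the minus strand still demultiplex
  rc <- mk_reads(revcomp(both))
  dmx2 <- demultiplex(rc, bcs)
  expect_identical(nrow(dmx2$assigned[[bcs$barcode_id[1]]]), 1L)
})

test_that("local alignment maps exact substrings on both strands and rejects noise", {
  sub <- substr(fx_panel$amplicons[["M2"]], 51, 300)
  hit <- align_read(sub, fx_panel)
  expect_identical(hit$ref, "M2")
  expect_identical(hit$strand, "+")
  expect_equal(hit$identity, 1)
  expect_identical(c(hit$ref_start, hit$ref_end), c(51L, 300L))

  rc_hit <- align_read(revcomp(sub), fx_panel)
  expect_identical(rc_hit$ref, "M2")
  expect_identical(rc_hit$strand, "-")
  expect_identical(c(rc_hit$ref_start, rc_hit$ref_end), c(51L, 300L))

  set.seed(31)
  nulls <- vapply(1:200, function(i) {
    r <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    is.null(align_read(r, fx_panel))
  }, logical(1))
  expect_true(all(nulls))
})

test_that("batch alignment agrees with the exhaustive per-read search", {
  g <- parse_shorthand("SSVIFC")
  bcs <- make_barcodes(2, seed = 5)
  cfg <- generator_config(coverage = 6L)
  reads <- gen_reads(g, fx_panel, bcs$sequence[1], cfg, seed = 88,
                     sample_id = "cmp")
  batch <- align_reads(reads, fx_panel)
  for (i in seq_len(nrow(reads))) {
    single <- align_read(reads$bases[i], fx_panel,
                         read_id = reads$read_id[i])
    row <- batch[batch$read_id == reads$read_id[i], ]
    if (is.null(single)) {
      expect_identical(nrow(row), 0L)
    } else {
      expect_identical(row$ref, single$ref)
      expect_identical(row$strand, single$strand)
      expect_equal(row$score, single$score)
    }
  }
})

test_that("codon pileups count spanning reads and honor the gap rule", {
  g <- parse_shorthand("SSVVFF")
  bcs <- make_barcodes(1, seed = 7)
  cfg0 <- generator_config(sub_rate = 0, ins_rate = 0, del_rate = 0,
                           barcode_error = 0, coverage = 150L)
  reads <- gen_reads(g, fx_panel, bcs$sequence[1], cfg0, seed = 3,
                     sample_id = "vv")
  aln <- align_reads(reads, fx_panel)
  pu <- codon_pileup(aln, fx_panel, "1016")
  expect_identical(names(pu$codon_counts), "GTA")
  expect_identical(pu$coverage, 150L)

  # heterozygote: two codons near 50/50
  gh <- parse_shorthand("SSGIFC")
  rh <- gen_reads(gh, fx_panel, bcs$sequence[1], cfg0, seed = 4,
                  sample_id = "gi")
  ph <- codon_pileup(align_reads(rh, fx_panel), fx_panel, "1016")
  expect_setequal(names(ph$codon_counts), c("GGA", "ATA"))
  expect_identical(sum(ph$codon_counts), 150L)
  expect_gt(min(ph$codon_counts), 150 * 0.3)

  # a read with a deletion inside the codon is excluded
  cs <- fx_panel$codon_start[["1016"]]
  amp <- fx_panel$amplicons[["M2"]]
  del_read <- paste0(substr(amp, 1, cs), substr(amp, cs + 2, nchar(amp)))
  pu2 <- codon_pileup(align_reads(mk_reads(del_read), fx_panel),
                      fx_panel, "1016")
  expect_identical(pu2$coverage, 0L)
  expect_error(codon_pileup(aln, fx_panel, "1017"), "not annotated")
})

test_that("genotype calling applies the coverage, fraction and unknown-codon rules", {
  tab <- fx_panel$codon_tables[["1016"]]
  mkpu <- function(counts) structure(
    list(locus = "1016", codon_counts = counts, coverage = sum(counts)),
    class = "codon_pileup")
  low <- call_genotype(mkpu(c(GTA = 80L)), tab)
  expect_identical(low$no_call_reason, "low_coverage")

  het <- call_genotype(mkpu(c(GGA = 110L, ATA = 86L, TTT = 4L)), tab)
  expect_identical(het$status, "called")
  expect_setequal(het$genotype, c("G", "I"))

  hom <- call_genotype(mkpu(c(GTA = 194L, ATA = 2L, CCA = 4L)), tab)
  expect_identical(hom$genotype, c("V", "V"))

  junk <- call_genotype(mkpu(c(GTA = 140L, TTT = 60L)), tab)
  expect_identical(junk$no_call_reason, "unknown_codon")

  ambi <- call_genotype(mkpu(c(GTA = 140L, ATA = 30L, GGA = 30L)), tab)
  expect_identical(ambi$no_call_reason, "ambiguous_fraction")
})

test_that("raising the coverage floor never converts a no-call into a call", {
  tab <- fx_panel$codon_tables[["1016"]]
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(40:250, 1)
    counts <- stats::setNames(
      as.integer(stats::rmultinom(1, n, prob = c(0.5, 0.35, 0.1, 0.05))),
      c("GTA", "ATA", "GGA", "TTT"))
    pu <- structure(list(locus = "1016", codon_counts = counts,
                         coverage = sum(counts)), class = "codon_pileup")
    called <- vapply(c(50L, 100L, 150L, 300L), function(mc)
      call_genotype(pu, tab, min_coverage = mc)$status == "called",
      logical(1))
    # once FALSE, never TRUE again as the floor rises
    expect_true(all(diff(called) <= 0))
  }
})

test_that("COI consensus is exact for clean reads and error-tolerant at depth", {
  bcs <- make_barcodes(1, seed = 15)
  g <- parse_shorthand("SSVVFF")
  cfg0 <- generator_config(sub_rate = 0, ins_rate = 0, del_rate = 0,
                           barcode_error = 0, coverage = 120L)
  aln <- align_reads(gen_reads(g, fx_panel, bcs$sequence[1], cfg0, seed = 9,
                               sample_id = "c"), fx_panel)
  expect_identical(coi_consensus(aln, fx_panel),
                   fx_panel$amplicons[["COI"]])

  cfg5 <- generator_config(sub_rate = 0.05, ins_rate = 0, del_rate = 0,
                           barcode_error = 0, coverage = 200L)
  aln5 <- align_reads(gen_reads(g, fx_panel, bcs$sequence[1], cfg5,
                                seed = 10, sample_id = "c5"), fx_panel)
  expect_identical(coi_consensus(aln5, fx_panel),
                   fx_panel$amplicons[["COI"]])

  none <- align_reads(mk_reads(character(0)), fx_panel)
  expect_null(coi_consensus(none, fx_panel))
})

test_that("species identity is exact matches over aligned columns", {
  refs <- fx_panel$coi_references
  cons <- refs$sequence[refs$accession == "KY022526.1"]
  sp <- identify_species(cons, refs)
  expect_equal(sp$percent_identity, 100)
  expect_true(sp$pass_threshold)

  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  two <- mutate_at(cons, c(100, 400))
  sp2 <- identify_species(two, refs[refs$accession == "KY022526.1", ])
  expect_equal(sp2$percent_identity, 100 * 656 / 658, tolerance = 1e-6)
  expect_true(sp2$pass_threshold)

  thirteen <- mutate_at(cons, seq(25, 625, by = 50))
  sp3 <- identify_species(thirteen, refs[refs$accession == "KY022526.1", ])
  expect_equal(sp3$percent_identity, 100 * 645 / 658, tolerance = 1e-6)
  expect_false(sp3$pass_threshold)

  short <- substr(cons, 1, 200)
  expect_true(identify_species(short, refs)$low_confidence)
})

test_that("the sample pipeline recovers a genotype and no-calls degraded inputs", {
  bcs <- make_barcodes(3, seed = 21)
  g <- parse_shorthand("SPGIFC")
  cfg <- generator_config(coverage = 160L)
  reads <- gen_reads(g, fx_panel, bcs$sequence[2], cfg, seed = 77,
                     sample_id = "e2e")
  res <- genotype_sample(reads, bcs$barcode_id[2], bcs, fx_panel)
  expect_identical(res$status, "called")
  expect_identical(res$shorthand, "SPGIFC")
  expect_true(res$species$pass_threshold)

  # one amplicon at 50x: the whole sample is excluded
  reads50 <- gen_reads(g, fx_panel, bcs$sequence[2], cfg, seed = 78,
                       sample_id = "m1low", coverage = c(M1 = 50L))
  res50 <- genotype_sample(reads50, bcs$barcode_id[2], bcs, fx_panel)
  expect_identical(res50$status, "no_call")
  expect_true(grepl("M1", res50$no_call_reason))

  # a water blank produces no assigned reads
  blank <- mk_reads(character(0))
  resb <- genotype_sample(blank, bcs$barcode_id[1], bcs, fx_panel)
  expect_identical(resb$status, "no_call")
  expect_true(grepl("demultiplex", resb$no_call_reason))
})

test_that("genotype calls are invariant under reverse-complementing every read", {
  bcs <- make_barcodes(2, seed = 33)
  g <- parse_shorthand("SSVICC")
  reads <- gen_reads(g, fx_panel, bcs$sequence[1],
                     generator_config(coverage = 150L), seed = 55,
                     sample_id = "rc")
  flipped <- reads
  flipped$bases <- revcomp(reads$bases)
  flipped$quals <- vapply(reads$quals, function(q)
    intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  a <- genotype_sample(reads, bcs$barcode_id[1], bcs, fx_panel)
  b <- genotype_sample(flipped, bcs$barcode_id[1], bcs, fx_panel)
  expect_identical(a$shorthand, b$shorthand)
  expect_identical(a$status, b$status)
})
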