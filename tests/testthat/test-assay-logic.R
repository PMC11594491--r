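# Independent oracle: filter the enumerated genotypes through
# predict_assay_outcome with the compatibility relation stated per method.
oracle_mca <- function(classes, model) {
  keys_1016[vapply(keys_1016, function(k)
    setequal(predict_assay_outcome(alleles_of(k), model), classes),
    logical(1))]
}
oracle_aspcr <- function(band_V, band_G, model) {
  keys_1016[vapply(keys_1016, function(k) {
    p <- predict_assay_outcome(alleles_of(k), model)
    ok <- TRUE
    if (band_V == "strong") ok <- ok && "strongV" %in% p
    if (band_V == "weak") ok <- ok && ("strongV" %in% p || "weakV" %in% p)
    if (band_G != "absent") ok <- ok && "Gband" %in% p
    ok
  }, logical(1))]
}

test_that("assay outcome prediction encodes the non-target-allele confusability", {
  expect_identical(predict_assay_outcome(c("G", "G"), fx_models$V1016I_MCA),
                   "Vclass")
  expect_identical(predict_assay_outcome(c("I", "I"), fx_models$V1016G_MCA),
                   "nonG")
  expect_identical(predict_assay_outcome(c("V", "G"), fx_models$V1016I_MCA),
                   "Vclass")
  expect_setequal(predict_assay_outcome(c("G", "I"), fx_models$V1016G_MCA),
                  c("Gclass", "nonG"))
  expect_error(predict_assay_outcome(c("V", "X"), fx_models$V1016I_MCA),
               "alphabet")
})

test_that("constraint sets match the worked examples", {
  expect_setequal(constraint_set(mca_observation("V1016I_MCA", "Vclass")),
                  c("VV", "VG", "GG"))
  expect_setequal(constraint_set(mca_observation("V1016G_MCA",
                                                 c("Gclass", "nonG"))),
                  c("VG", "GI"))
  expect_setequal(constraint_set(aspcr_observation("weak", "strong")),
                  c("VG", "GI"))
  # no-call observations constrain nothing
  expect_setequal(constraint_set(sanger_observation(NULL)), keys_1016)
  # a lone Sanger symbol asserts presence, not homozygosity
  expect_setequal(constraint_set(sanger_observation("G")),
                  c("VG", "GG", "GI"))
  expect_identical(constraint_set(sanger_observation(c("G", "I"))), "GI")
})

test_that("declarative constraint sets equal the brute-force oracle for every outcome", {
  for (aid in c("V1016I_MCA", "V1016G_MCA")) {
    model <- fx_models[[aid]]
    outcomes <- unique(lapply(keys_1016, function(k)
      predict_assay_outcome(alleles_of(k), model)))
    for (cls in outcomes) {
      expect_setequal(constraint_set(mca_observation(aid, cls)),
                      oracle_mca(cls, model))
    }
  }
  model <- fx_models$ASPCR_1016
  for (bv in c("absent", "weak", "strong")) for (bg in c("absent", "strong")) {
    if (bv == "absent" && bg == "absent") next
    expect_setequal(constraint_set(aspcr_observation(bv, bg)),
                    oracle_aspcr(bv, bg, model))
  }
})

test_that("strict band semantics make an absent band exclude its allele", {
  expect_setequal(constraint_set(aspcr_observation("strong", "absent"),
                                 strict_bands = TRUE),
                  c("VV", "VI"))
})

test_that("the two 1016 melt assays jointly resolve every genotype", {
  for (k in keys_1016) {
    obs <- list(
      mca_observation("V1016I_MCA",
                      predict_assay_outcome(alleles_of(k),
                                            fx_models$V1016I_MCA)),
      mca_observation("V1016G_MCA",
                      predict_assay_outcome(alleles_of(k),
                                            fx_models$V1016G_MCA)))
    res <- resolve_1016(obs)
    expect_identical(res$status, "resolved")
    expect_identical(res$candidates, k)
  }
})

test_that("resolution handles the worked intersection examples", {
  r1 <- resolve_1016(list(
    mca_observation("V1016I_MCA", c("Vclass", "Iclass")),
    mca_observation("V1016G_MCA", c("Gclass", "nonG"))))
  expect_identical(r1$candidates, "GI")
  r2 <- resolve_1016(list(mca_observation("V1016I_MCA", "Vclass"),
                          mca_observation("V1016G_MCA", "nonG")))
  expect_identical(r2$candidates, "VV")
  expect_identical(resolve_1016(list())$status, "no_call")
})

test_that("an allele is confirmed by >= 2 methods detecting it unambiguously", {
  obs <- list(genotype_observation(c("G", "I"), source = "MCA"),
              sanger_observation(c("G", "I")),
              genotype_observation(c("G", "I"), source = "NGS"))
  res <- resolve_1016(obs)
  conf <- res$confirmation
  g_row <- conf[conf$allele == "G", ]
  expect_true(g_row$confirmed)
  expect_identical(g_row$n_methods, 3L)
  # a weak V band alone never confirms V
  res2 <- resolve_1016(list(aspcr_observation("weak", "absent"),
                            sanger_observation("I")))
  expect_false(res2$confirmation$confirmed[res2$confirmation$allele == "V"])
})

test_that("conflicting methods are reported with a minimal conflicting pair", {
  res <- resolve_1016(list(sanger_observation(c("I", "I")),
                           mca_observation("V1016G_MCA", "Gclass")))
  expect_identical(res$status, "conflict")
  expect_setequal(res$conflicting_methods, c("Sanger", "V1016G_MCA"))
})

test_that("adding observations never enlarges the candidate set", {
  pool <- list(mca_observation("V1016I_MCA", c("Vclass", "Iclass")),
               mca_observation("V1016G_MCA", "nonG"),
               aspcr_observation("weak", "absent"),
               sanger_observation("I"),
               genotype_observation(c("V", "I"), source = "NGS"))
  set.seed(404)
  for (rep in 1:20) {
    ord <- sample(pool)
    prev <- keys_1016
    for (m in seq_along(ord)) {
      cand <- resolve_1016(ord[seq_len(m)])$candidates
      expect_true(all(cand %in% prev))
      prev <- cand
    }
  }
})

test_that("joint disambiguation holds while single assays collide", {
  both <- disambiguation_check(fx_models[c("V1016I_MCA", "V1016G_MCA")])
  expect_true(both$injective)
  expect_length(both$collisions, 0L)

  i_only <- disambiguation_check(fx_models["V1016I_MCA"])
  expect_false(i_only$injective)
  expect_true(any(vapply(i_only$collisions, setequal, logical(1),
                         c("VV", "VG", "GG"))))
  g_only <- disambiguation_check(fx_models["V1016G_MCA"])
  expect_false(g_only$injective)
  expect_true(any(vapply(g_only$collisions, setequal, logical(1),
                         c("VV", "VI", "II"))))
})

test_that("the packaged comparison table loads verbatim and parses losslessly", {
  tbl <- load_table1()
  expect_identical(nrow(tbl), 18L)
  expect_identical(sum(grepl("^Osceola", tbl$site)), 11L)
  nfw <- tbl[tbl$site == "Control-NFW", ]
  expect_identical(nfw$mca, "no call")
  expect_identical(nfw$ngs, "no call")
  expect_identical(nfw$coi_status, "no call")
  # compound AS-PCR cells parse reversibly
  for (cell in unique(tbl$aspcr[!tbl$aspcr %in% c("no call", "not tested")]))
    expect_identical(format_aspcr(parse_aspcr(cell)), cell)
  expect_identical(parse_aspcr("weakV G")$band_V, "weak")
  expect_identical(parse_aspcr("weakV G")$band_G, "strong")
})

test_that("record tables round-trip through the published TSV layout", {
  tbl <- load_table1()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records_tsv(tbl, path)
  back <- read_records_tsv(path)
  expect_identical(back$mca, tbl$mca)
  expect_identical(back$aspcr, tbl$aspcr)
  expect_identical(back$coi_accession, tbl$coi_accession)
  expect_equal(back$coi_pid, tbl$coi_pid)
})

test_that("concordance summaries count the fixture the way the study reports it", {
  cc <- build_concordance(load_table1())
  s <- cc$summary
  expect_identical(unname(s$mca_counts[["GIFC"]]), 7L)
  expect_identical(unname(s$g_positive$field[["MCA"]]), 8L)
  expect_identical(unname(s$g_positive$field[["Sanger"]]), 4L)
  expect_identical(unname(s$g_positive$field[["ASPCR"]]), 5L)
  expect_identical(unname(s$g_positive$field[["NGS"]]), 6L)
  expect_identical(s$ngs_p989_among_g$field, 3L)
  expect_identical(s$ngs_no_call, 4L)
  expect_identical(s$coi_pass, 12L)
  expect_identical(s$coi_tested, 14L)
  # the resolver trusts observations: the mislabeled het control resolves II
  tab <- cc$table
  spg <- tab[tab$site == "Control-SPGIFC", ]
  expect_identical(spg$resolved_1016, "II")
})

test_that("degenerate concordance inputs behave", {
  empty <- as_kdr_records(site = character(0), mca = character(0),
                          aspcr = character(0), sanger = character(0),
                          ngs = character(0), coi = character(0))
  cc <- build_concordance(empty)
  expect_identical(cc$summary$n_records, 0L)
  expect_identical(cc$summary$coi_pass, 0L)
  expect_error(as_kdr_records(site = c("a", "a"), mca = c("VVFF", "VVFF"),
                              aspcr = c("V", "V"), sanger = c("VV", "VV"),
                              ngs = c("SSVVFF", "SSVVFF"),
                              coi = c("no call", "no call"),
                              sample_id = c("s1", "s1")),
               "duplicate")
})
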