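gauss_curve <- function(centers, heights = rep(1, length(centers)),
                        sd = 0.25) {
  tt <- seq(70, 95, by = 0.05)
  y <- numeric(length(tt))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-0.5 * ((tt - centers[i]) / sd)^2)
  melt_curve(tt, y)
}

test_that("peak detection finds unimodal and bimodal peaks and rejects flat curves", {
  pk <- find_peaks(gauss_curve(78.50))
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$tm - 78.50), 0.05)

  pk2 <- find_peaks(gauss_curve(c(76.0, 79.0)))
  expect_identical(nrow(pk2), 2L)
  expect_lt(max(abs(sort(pk2$tm) - c(76.0, 79.0))), 0.05)

  flat <- melt_curve(seq(70, 95, by = 0.05),
                     rep(0, length(seq(70, 95, by = 0.05))))
  expect_identical(nrow(find_peaks(flat)), 0L)
})

test_that("small secondary bumps below the relative height threshold are dropped", {
  pk <- find_peaks(gauss_curve(c(76, 82), heights = c(1, 0.1)))
  expect_identical(nrow(pk), 1L)
  pk2 <- find_peaks(gauss_curve(c(76, 82), heights = c(1, 0.3)))
  expect_identical(nrow(pk2), 2L)
})

test_that("the Tm-window rule calls classes, with nearest-control tie-break", {
  gdef <- fx_assays$V1016G_MCA
  # one peak 0.1 above the G control: homozygous G pattern
  call <- call_mca(find_peaks(gauss_curve(gdef$class_tms[["Gclass"]] + 0.1)),
                   gdef)
  expect_identical(call$status, "called")
  expect_identical(call$detected_classes, "Gclass")

  # G-class and non-G peaks: heterozygous pattern
  call2 <- call_mca(find_peaks(gauss_curve(c(gdef$class_tms[["Gclass"]],
                                             gdef$class_tms[["nonG"]]))),
                    gdef)
  expect_setequal(call2$detected_classes, c("Gclass", "nonG"))

  # a peak 0.5 degrees from every control: no call
  far <- max(gdef$class_tms) + 0.5
  call3 <- call_mca(find_peaks(gauss_curve(far)), gdef)
  expect_identical(call3$status, "no_call")
  expect_identical(call3$no_call_reason, "no peak within tolerance")

  # empty peak list: no amplification
  call4 <- call_mca(find_peaks(gauss_curve(numeric(0))), gdef)
  expect_identical(call4$no_call_reason, "no amplification")

  # within tolerance of two classes: nearest wins, warning attached
  idef <- fx_assays$V1016I_MCA
  mid <- idef$class_tms[["Vclass"]] + 0.2
  idef2 <- assay_definition("tight", "1016",
                            class_tms = c(A = mid - 0.2, B = mid + 0.25),
                            allele_tm_class = c(V = "A", G = "A", I = "B"),
                            confusable = list(c("A", "B")))
  call5 <- call_mca(data.frame(tm = mid, height = 1), idef2)
  expect_identical(call5$detected_classes, "A")
  expect_true(any(grepl("nearest", call5$warnings)))
})

test_that("noiseless generated curves reproduce the virtual-model classes for all genotypes", {
  for (aid in c("V1016I_MCA", "V1016G_MCA")) {
    for (key in keys_1016) {
      cv <- gen_melt_curve(fx_assays[[aid]], alleles_of(key), cfg_noiseless,
                           seed = 7)
      call <- call_mca(find_peaks(cv), fx_assays[[aid]])
      expect_setequal(call$detected_classes,
                      predict_assay_outcome(alleles_of(key), fx_models[[aid]]))
    }
  }
})

test_that("Tm-class calls tolerate small shifts and change under large ones", {
  for (aid in c("V1016I_MCA", "V1016G_MCA", "F1534C_MCA")) {
    adef <- fx_assays[[aid]]
    genos <- if (aid == "F1534C_MCA") c("FF", "CC", "FC") else keys_1016
    for (key in genos) {
      g <- alleles_of(key)
      cv <- gen_melt_curve(adef, g, cfg_noiseless, seed = 11)
      base <- call_mca(find_peaks(cv), adef)$tm_classes
      # delta below tolerance minus grid step: identical Tm classes
      small <- call_mca(find_peaks(shift_curve(cv, 0.25)), adef)$tm_classes
      expect_identical(small, base)
      # delta above tolerance plus a peak-width guard: never the same classes
      big <- call_mca(find_peaks(shift_curve(cv, 0.55)), adef)$tm_classes
      expect_false(identical(big, base))
    }
  }
})

test_that("homozygote calling is >= 99% accurate at the fixture noise level", {
  homs <- list(V1016I_MCA = c("VV", "II"), V1016G_MCA = c("VV", "II", "GG"))
  n <- 0L; ok <- 0L
  for (i in 1:1000) {
    aid <- names(homs)[(i %% 2L) + 1L]
    key <- homs[[aid]][(i %% length(homs[[aid]])) + 1L]
    cv <- gen_melt_curve(fx_assays[[aid]], alleles_of(key),
                         generator_config(), seed = 20000L + i)
    call <- call_mca(find_peaks(cv), fx_assays[[aid]])
    expected <- predict_assay_outcome(alleles_of(key), fx_models[[aid]])
    n <- n + 1L
    if (call$status == "called" &&
        setequal(call$detected_classes, expected)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.99)
})

test_that("control validation distinguishes valid, warn and invalid runs", {
  gdef <- fx_assays$V1016G_MCA
  mkcall <- function(genotype, seed = 5, cfg = cfg_noiseless)
    call_mca(find_peaks(gen_melt_curve(gdef, genotype, cfg, seed)), gdef)
  geno <- list(ROCK = c("V", "V"), PR = c("I", "I"), CKR = c("G", "G"),
               VI_het = c("V", "I"), GI_het = c("G", "I"), NFW = "negative")
  calls <- list(ROCK = mkcall(c("V", "V")), PR = mkcall(c("I", "I")),
                CKR = mkcall(c("G", "G")), VI_het = mkcall(c("V", "I")),
                GI_het = mkcall(c("G", "I")),
                NFW = call_mca(NULL, gdef))
  expect_identical(validate_controls(calls, geno, gdef)$status, "valid")

  # the GI het control loses its G peak: run downgraded, control named
  cfg_gdrop <- generator_config(tm_noise_sd = 0, curve_noise_sd = 0,
                                height_jitter = 0,
                                dropout = list(mca_class = c(Gclass = 1)))
  calls$GI_het <- mkcall(c("G", "I"), cfg = cfg_gdrop)
  v <- validate_controls(calls, geno, gdef)
  expect_identical(v$status, "valid_with_warning")
  expect_true("GI_het" %in% v$failures$control)

  # a called peak in the negative control invalidates the run
  calls$GI_het <- mkcall(c("G", "I"))
  calls$NFW <- mkcall(c("V", "V"))
  expect_identical(validate_controls(calls, geno, gdef)$status, "invalid")

  # missing a required control is invalid with reason
  v2 <- validate_controls(calls[-3], geno[-3], gdef)
  expect_identical(v2$status, "invalid")
  expect_identical(v2$reason, "control absent")
})

test_that("melt-curve construction validates its grid and values", {
  tt <- seq(70, 95, by = 0.05)
  expect_error(melt_curve(tt, rep(1, 10)), "equal length")
  expect_error(melt_curve(rev(tt), rep(1, length(tt))), "increasing")
  expect_error(melt_curve(tt[1:20], rep(1, 20)), "at least 50")
  expect_error(melt_curve(tt, rep(-1, length(tt))), "nonnegative")
})

test_that("curve CSV round-trips through the long format", {
  curves <- list(S1 = list(V1016G_MCA = gen_melt_curve(
    fx_assays$V1016G_MCA, c("G", "I"), cfg_noiseless, seed = 2)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(curves, path)
  back <- read_curves_csv(path)
  expect_equal(back$S1$V1016G_MCA$derivative,
               curves$S1$V1016G_MCA$derivative, tolerance = 1e-12)
})
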