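# Shared fixtures, built once per test run.

fx_panel <- build_reference_panel()
fx_models <- virtual_assay_models()
fx_assays <- default_assay_definitions()
fx_loci <- kdr_loci()

# noiseless generator settings for deterministic curve checks
cfg_noiseless <- generator_config(tm_noise_sd = 0, curve_noise_sd = 0,
                                  height_jitter = 0)

keys_1016 <- vapply(enumerate_diploid_genotypes(fx_loci[["1016"]]),
                    paste, character(1), collapse = "")

alleles_of <- function(key) strsplit(key, "")[[1]]

# shift a melt curve along the temperature axis by delta degrees
shift_curve <- function(curve, delta) {
  melt_curve(curve$temperature + delta, curve$derivative)
}
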