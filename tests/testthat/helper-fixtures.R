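# shared fixtures: small, fast instrument configs built in code

# tiny single-band toy on a short axis, for structural tests
toy_config <- function(noise_sd = 0, mode = "linearized",
                       n_replicates = 1L) {
  instrument_config(
    axis = spectral_axis("wavelength_nm", seq(200, 300, by = 2)),
    bands = list(
      band_spec(250, 10, 0.05, "solute", dheight = c(0, -1e-3, 0)),
      band_spec(225, 7, 0.10, "solvent", dheight = c(0, -5e-4, 0))
    ),
    noise_sd = noise_sd, n_replicates = n_replicates, mode = mode)
}

# a small random-but-reproducible dataset for round-trip tests
random_dataset <- function(seed = 42L, n_replicates = 2L) {
  cfg <- toy_config(noise_sd = 0.01, mode = "realistic",
                    n_replicates = n_replicates)
  d <- generate_calibration_set(table1_design(), cfg, seed = seed)
  # exercise the missing-concentration path
  d$meta$concentration[1] <- NA
  d
}

expect_dataset_equal <- function(a, b) {
  expect_identical(a$axis$kind, b$axis$kind)
  expect_identical(a$axis$values, b$axis$values)
  expect_identical(a$unit, b$unit)
  expect_identical(dim(a$intensities), dim(b$intensities))
  expect_true(nrow(a$intensities) == 0L ||
                max(abs(a$intensities - b$intensities)) == 0)
  expect_identical(a$meta, b$meta)
}
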