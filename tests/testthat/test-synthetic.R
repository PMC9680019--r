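test_that("the bundled calibration design matches its printed layout", {
  des <- table1_design()
  s <- des$samples
  expect_identical(nrow(s), 40L)
  expect_identical(sort(unique(s$concentration)), c(4, 8, 12, 16, 20))
  for (cc in c(4, 8, 12)) {
    expect_identical(sort(s$temperature[s$concentration == cc]),
                     c(-10, 0, 10, 20, 30, 40, 50, 60, 70, 75))
  }
  expect_identical(sort(s$temperature[s$concentration == 16]),
                   c(30, 40, 50, 60, 70, 75))
  expect_identical(sort(s$temperature[s$concentration == 20]),
                   c(50, 60, 70, 75))
})

test_that("solubility model evaluates its closed form", {
  sol <- solubility_model(A = 8.1, B = 1600)
  # direct evaluation of exp(A - B/(T + 273.15))
  expect_equal(solubility_at(sol, 50), exp(8.1 - 1600 / 323.15))
  expect_equal(solubility_at(sol, 50), 23.3, tolerance = 0.005)
  # constant limit at B = 0
  flat <- solubility_model(A = 2, B = 0)
  expect_equal(solubility_at(flat, c(-10, 25, 70)), rep(exp(2), 3))
  # monotone increasing for B > 0
  expect_gt(solubility_at(sol, 70), solubility_at(sol, 0))
  expect_equal(predict(sol, 50), solubility_at(sol, 50))
})

test_that("simulated spectra follow Beer-Lambert and the configured drifts", {
  cfg <- toy_config()

  # solvent-free config at zero concentration is identically zero
  solute_only <- instrument_config(cfg$axis,
                                   list(band_spec(250, 10, 0.05, "solute")),
                                   noise_sd = 0)
  expect_identical(simulate_spectrum(solute_only, 0, 20),
                   rep(0, length(cfg$axis$values)))

  # affine in concentration at every axis point
  s0 <- simulate_spectrum(cfg, 0, 35)
  s1 <- simulate_spectrum(cfg, 6, 35)
  s2 <- simulate_spectrum(cfg, 12, 35)
  expect_equal(s2 - s1, s1 - s0, tolerance = 1e-12)

  # no temperature coefficients -> identical spectra at 20 and 70 degC
  frozen <- instrument_config(cfg$axis,
                              list(band_spec(250, 10, 0.05, "solute"),
                                   band_spec(225, 7, 0.10, "solvent")),
                              noise_sd = 0)
  expect_identical(simulate_spectrum(frozen, 8, 20),
                   simulate_spectrum(frozen, 8, 70))

  # identical seed, identical draw; different seed differs
  noisy <- toy_config(noise_sd = 0.01)
  expect_identical(simulate_spectrum(noisy, 8, 20, seed = 5),
                   simulate_spectrum(noisy, 8, 20, seed = 5))
  expect_false(identical(simulate_spectrum(noisy, 8, 20, seed = 5),
                         simulate_spectrum(noisy, 8, 20, seed = 6)))

  # band pushed off the axis support is a configuration error
  edge <- instrument_config(cfg$axis,
                            list(band_spec(290, 8, 0.05, "solute")),
                            noise_sd = 0)
  expect_error(simulate_spectrum(edge, 8, 20), "axis support")
})

test_that("calibration set generation counts and replicate structure", {
  cfg <- toy_config()
  d5 <- generate_calibration_set(table1_design(), cfg, seed = 1,
                                 n_replicates = 5)
  expect_identical(n_spectra(d5), 200L)
  expect_true(all(d5$meta$role == "calibration"))

  # the study's replicate minima are supported
  d14 <- generate_calibration_set(table1_design(), cfg, seed = 1,
                                  n_replicates = 14)
  expect_identical(n_spectra(d14), 40L * 14L)
  d22 <- generate_calibration_set(table1_design(), cfg, seed = 1,
                                  n_replicates = 22)
  expect_identical(n_spectra(d22), 40L * 22L)

  # noise-free replicates of one sample are bit-identical
  i <- which(d5$meta$sample_id == d5$meta$sample_id[1])
  expect_identical(d5$intensities[i[1], ], d5$intensities[i[2], ])

  # noisy replicates differ only by noise (same clean part)
  noisy <- toy_config(noise_sd = 0.01, n_replicates = 3)
  dn <- generate_calibration_set(table1_design(), noisy, seed = 1)
  j <- which(dn$meta$sample_id == dn$meta$sample_id[1])
  expect_false(identical(dn$intensities[j[1], ], dn$intensities[j[2], ]))
})

test_that("validation set contains exactly the two printed samples", {
  cfg <- toy_config(n_replicates = 22)
  v <- generate_validation_set(cfg, seed = 2)
  expect_identical(n_spectra(v), 44L)
  pairs <- unique(v$meta[, c("concentration", "temperature")])
  expect_identical(nrow(pairs), 2L)
  expect_setequal(pairs$concentration, c(5, 15))
  expect_identical(pairs$temperature[pairs$concentration == 5], 20)
  expect_identical(pairs$temperature[pairs$concentration == 15], 65)
  expect_true(all(v$meta$role == "validation"))
  expect_true(all(v$meta$concentration %in% c(5, 15)))
})

test_that("slurry experiment relaxes toward the solubility curve", {
  cfg <- toy_config()
  sol <- solubility_model()
  sl <- generate_slurry_experiment(cfg, sol, seed = 3)
  expect_identical(nrow(sl$profile), 8L)
  expect_identical(sl$profile$setpoint, seq(0, 70, by = 10))
  expect_true(all(sl$dataset$meta$role == "slurry"))

  # instantaneous kinetics: final concentration per hold equals S(T_hold)
  fast <- generate_slurry_experiment(cfg, sol, kinetics_tau = 0, seed = 3)
  ep <- extract_hold_endpoints(fast$dataset, fast$profile)
  expect_equal(ep$meta$concentration,
               solubility_at(sol, fast$profile$setpoint))

  # hold_duration = 6 tau: endpoint within e^-6 of equilibrium, exactly
  tau <- 300
  six <- generate_slurry_experiment(cfg, sol, hold_duration = 6 * tau,
                                    kinetics_tau = tau, seed = 3)
  epe <- extract_hold_endpoints(six$dataset, six$profile)
  s_eq <- solubility_at(sol, six$profile$setpoint)
  gap_in <- c(s_eq[1], epe$meta$concentration[-8]) - s_eq  # entering each hold
  expect_equal(epe$meta$concentration - s_eq, gap_in * exp(-6),
               tolerance = 1e-9)
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- toy_config(noise_sd = 0.01, n_replicates = 2)
  sol <- solubility_model()
  a <- generate_calibration_set(table1_design(), cfg, seed = 9)
  b <- generate_calibration_set(table1_design(), cfg, seed = 9)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$meta, b$meta)
  expect_false(identical(
    a$intensities,
    generate_calibration_set(table1_design(), cfg, seed = 10)$intensities))
  expect_identical(generate_validation_set(cfg, seed = 4)$intensities,
                   generate_validation_set(cfg, seed = 4)$intensities)
  expect_identical(generate_slurry_experiment(cfg, sol, seed = 5)$dataset$intensities,
                   generate_slurry_experiment(cfg, sol, seed = 5)$dataset$intensities)
})

test_that("linearized noise-free isothermal slices have rank <= 2", {
  cfg <- toy_config(mode = "linearized", n_replicates = 2)
  d <- generate_calibration_set(table1_design(), cfg, seed = 1)
  for (tm in c(-10, 30, 75)) {
    sl <- subset_spectra(d, d$meta$temperature == tm)
    expect_lte(qr(sl$intensities, tol = 1e-10)$rank, 2L)
  }
})

test_that("default instruments support the full design space", {
  for (ctor in list(uv_instrument, ir_instrument)) {
    cfg <- ctor(noise_sd = 0, n_replicates = 1)
    d <- generate_calibration_set(table1_design(), cfg, seed = 1)
    expect_identical(n_spectra(d), 40L)
    expect_identical(validate_dataset(d), character())
  }
})
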