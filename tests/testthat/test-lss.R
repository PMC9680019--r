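# linearized noise-free fixture: 3 compositions x 10 temperatures
lss_fixture <- function(n_replicates = 2L) {
  cfg <- toy_config(mode = "linearized", n_replicates = n_replicates)
  d <- generate_calibration_set(table1_design(), cfg, seed = 11)
  list(cfg = cfg,
       sub = subset_spectra(d, d$meta$concentration %in% c(4, 8, 12)),
       full = d)
}

test_that("component selection follows cumulative squared singular values", {
  # fractions of (10, 5, 1e-9): 100/125 = 0.8 at one factor, ~1 at two
  expect_identical(select_n_components(c(10, 5, 1e-9), 0.995), 2L)
  expect_identical(select_n_components(c(10, 5, 1e-9), 0.75), 1L)
  expect_identical(select_n_components(c(7, 0, 0)), 1L)
  # threshold 1.0 on full-rank data needs every positive singular value
  expect_identical(select_n_components(c(5, 3, 2, 1), 1.0), 4L)
  expect_error(factor_diagnostics(numeric()), "empty")
  expect_error(factor_diagnostics(c(1, 2)), "non-increasing")
})

test_that("two-factor structure is detected at the default threshold", {
  cfg <- uv_instrument("linearized", noise_sd = 0, n_replicates = 1)
  d <- generate_calibration_set(table1_design(), cfg, seed = 11)
  sub <- subset_spectra(d, d$meta$concentration %in% c(4, 8, 12))
  m <- lss(sub, k = 2, t_ref = 50, t_target = 50)
  expect_identical(select_n_components(m$diagnostics), 2L)
})

test_that("quadratic loading fits reproduce the per-temperature loadings", {
  fx <- lss_fixture()
  m <- lss(fx$sub, k = 2, t_ref = 50, t_target = 50)
  sdz <- m$temp_standardization
  for (i in seq_along(m$temps_used)) {
    P_fit <- loading_matrix_at(m, m$temps_used[i])
    expect_lt(max(abs(P_fit - m$fitted_loadings[, , i])), 1e-8)
  }
})

test_that("loading evaluation is entrywise polynomial evaluation", {
  # hand-built single-point single-factor model: coeffs (1, 2, 3)
  m <- structure(list(
    k = 1L, temps_used = c(0, 25, 50), t_ref = 25, t_target = 25,
    ref_scores = matrix(1, 3, 1),
    coeffs = array(c(1, 2, 3), c(1, 1, 3)),
    temp_standardization = c(mean = 25, sd = 25),
    axis = spectral_axis("wavelength_nm", 218),
    unit = "absorbance",
    diagnostics = factor_diagnostics(1),
    fitted_loadings = NULL, compositions = 1,
    n_replicates_used = 1L), class = "lss")
  # standardized temperature 1 at 50 degC: 1 + 2 + 3 = 6
  expect_identical(drop(loading_matrix_at(m, 50)), 6)
  # constant loading when a1 = a2 = 0
  m$coeffs <- array(c(4, 0, 0), c(1, 1, 3))
  expect_identical(drop(loading_matrix_at(m, 0)), 4)
  expect_identical(drop(loading_matrix_at(m, 50)), 4)
})

test_that("fitting preconditions are enforced", {
  fx <- lss_fixture()
  two_t <- subset_spectra(fx$sub, fx$sub$meta$temperature %in% c(40, 50))
  expect_error(lss(two_t, k = 2, t_ref = 50), "at least 3")
  # missing cell: drop one (composition, temperature) entirely
  holey <- subset_spectra(fx$sub, !(fx$sub$meta$concentration == 8 &
                                      fx$sub$meta$temperature == 20))
  expect_error(lss(holey, k = 2, t_ref = 50), "design error")
  expect_error(lss(fx$sub, k = 2, t_ref = 33), "not a dataset temperature")
})

test_that("unequal replicate counts are truncated to the minimum", {
  fx <- lss_fixture(n_replicates = 3L)
  # remove one replicate of one cell; fit must still work on 2 per cell
  drop_one <- which(fx$sub$meta$concentration == 4 &
                      fx$sub$meta$temperature == 50 &
                      fx$sub$meta$replicate == 3)
  uneven <- subset_spectra(fx$sub, -drop_one)
  m <- lss(uneven, k = 2, t_ref = 50)
  expect_identical(m$n_replicates_used, 2L)
  expect_identical(nrow(m$ref_scores), 6L)  # 3 compositions x 2 replicates
})

test_that("standardization to the measurement temperature is the identity", {
  fx <- lss_fixture()
  m <- lss(fx$sub, k = 2, t_ref = 50, t_target = 50)
  x <- simulate_spectrum(fx$cfg, 10, 20)
  expect_identical(apply_lss(m, x, 20, 20), x)
  d_at_50 <- subset_spectra(fx$full, fx$full$meta$temperature == 50)
  expect_identical(apply_lss_dataset(m, d_at_50, 50)$intensities,
                   d_at_50$intensities)
})

test_that("linearized noise-free transforms are exact (generator oracle)", {
  fx <- lss_fixture()
  m <- lss(fx$sub, k = 2, t_ref = 50, t_target = 50)
  for (cc in c(5, 10, 18)) {       # includes compositions not in the fit
    for (tm in c(-10, 20, 75)) {
      got <- apply_lss(m, simulate_spectrum(fx$cfg, cc, tm), tm, 50)
      want <- simulate_spectrum(fx$cfg, cc, 50)
      expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
    }
  }
  # zero spectrum maps to zero
  expect_equal(apply_lss(m, rep(0, length(fx$cfg$axis$values)), 20, 50),
               rep(0, length(fx$cfg$axis$values)), tolerance = 1e-12)
})

test_that("transform is idempotent and conserves the residual norm", {
  cfg <- toy_config(noise_sd = 0.01, mode = "realistic", n_replicates = 2)
  d <- generate_calibration_set(table1_design(), cfg, seed = 21)
  sub <- subset_spectra(d, d$meta$concentration %in% c(4, 8, 12))
  m <- lss(sub, k = 2, t_ref = 50, t_target = 50)
  x <- simulate_spectrum(cfg, 9, 30, seed = 77)
  once <- apply_lss(m, x, 30, 50)
  twice <- apply_lss(m, once, 50, 50)
  expect_identical(twice, once)

  # residual carried over unchanged: || out - s P_t' || = || in - s P_m' ||
  P_m <- loading_matrix_at(m, 30)
  s <- solve(crossprod(P_m), crossprod(P_m, x))
  r_in <- x - drop(P_m %*% s)
  P_t <- loading_matrix_at(m, 50)
  r_out <- once - drop(P_t %*% s)
  expect_equal(sqrt(sum(r_out^2)), sqrt(sum(r_in^2)), tolerance = 1e-10)
})

test_that("scores of one composition agree across temperatures (noise-free)", {
  fx <- lss_fixture()
  m <- lss(fx$sub, k = 2, t_ref = 50, t_target = 50)
  scores <- sapply(c(-10, 10, 40, 75), function(tm) {
    P <- loading_matrix_at(m, tm)
    x <- simulate_spectrum(fx$cfg, 8, tm)
    solve(crossprod(P), crossprod(P, x))
  })
  rel_sd <- apply(scores, 1, stats::sd) / abs(rowMeans(scores))
  expect_lt(max(rel_sd), 1e-6)
})

test_that("dataset-level correction collapses between-temperature variance", {
  fx <- lss_fixture()
  m <- lss(fx$sub, k = 2, t_ref = 50, t_target = 50)
  corrected <- apply_lss_dataset(m, fx$full, 50)
  for (cc in c(4, 12, 20)) {
    raw <- fx$full$intensities[fx$full$meta$concentration == cc, ]
    cor <- corrected$intensities[corrected$meta$concentration == cc, ]
    v_raw <- sum(apply(raw, 2, stats::var))
    v_cor <- sum(apply(cor, 2, stats::var))
    expect_gt(v_raw / max(v_cor, 1e-300), 10)
  }
  # empty dataset passes through
  empty <- subset_spectra(fx$full, integer())
  expect_identical(n_spectra(apply_lss_dataset(m, empty, 50)), 0L)
  # unit mismatch is a pipeline error
  dd <- fx$full
  dd$unit <- "absorbance_deriv"
  expect_error(apply_lss_dataset(m, dd, 50), "pipeline error")
})

test_that("LSS models survive a JSON round trip", {
  fx <- lss_fixture()
  m <- lss(fx$sub, k = 2, t_ref = 50, t_target = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_lss_json(m, path)
  m2 <- read_lss_json(path)
  expect_equal(m2$coeffs, m$coeffs, tolerance = 1e-14)
  expect_equal(m2$ref_scores, m$ref_scores, tolerance = 1e-14)
  expect_identical(m2$k, m$k)
  expect_equal(m2$temps_used, m$temps_used)
  x <- simulate_spectrum(fx$cfg, 10, 20)
  expect_equal(apply_lss(m2, x, 20, 50), apply_lss(m, x, 20, 50),
               tolerance = 1e-12)
})
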