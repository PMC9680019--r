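# light-weight realistic scenario shared by the workflow tests
workflow_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- uv_instrument("realistic", n_replicates = 6)
    cal <- generate_calibration_set(table1_design(), cfg, seed = 101)
    val <- generate_validation_set(cfg, seed = 102)
    rep <- run_calibration_comparison(
      cal, val, uv_variant_set(),
      cv = cv_config(n_iterations = 5, max_lv = 8, seed = 103))
    cache <<- list(cfg = cfg, cal = cal, val = val, report = rep)
    cache
  }
})

test_that("the comparison trains each variant on its intended subset", {
  fx <- workflow_fixture()
  det <- fx$report$details

  # local variant trains only on the 50 degC slice: 5 samples x 6 replicates
  expect_identical(length(det$local_isothermal$pls$y), 30L)

  # LSS variant fits the transform on concentrations {4, 8, 12} only,
  # then the PLS model sees all 5 concentrations
  expect_identical(det$global_lss$lss$compositions, c(4, 8, 12))
  expect_setequal(unique(det$global_lss$pls$y), c(4, 8, 12, 16, 20))

  # derivative variant carries the derivative unit tag end to end
  expect_identical(det$global_deriv$pls$unit, "absorbance_deriv")

  # report table has one row per variant with finite metrics
  expect_identical(nrow(fx$report$table), 4L)
  num <- vapply(fx$report$table, is.numeric, logical(1))
  expect_true(all(is.finite(as.matrix(fx$report$table[, num]))))
})

test_that("temperature correction beats the uncorrected global model", {
  tab <- workflow_fixture()$report$table
  row <- function(l) tab[tab$label == l, ]
  expect_gte(row("global_raw")$n_lv, row("global_lss")$n_lv)
  expect_identical(row("global_lss")$n_lv, row("local_isothermal")$n_lv)
  expect_lte(row("local_isothermal")$rmsecv, row("global_lss")$rmsecv)
  expect_lte(row("global_lss")$rmsecv, row("global_raw")$rmsecv)
  expect_lt(row("global_lss")$val5_rsd, row("global_raw")$val5_rsd)
  expect_lt(row("global_lss")$val15_rsd, row("global_raw")$val15_rsd)
})

test_that("the comparison run is bit-identical under a fixed seed", {
  fx <- workflow_fixture()
  rep2 <- run_calibration_comparison(
    fx$cal, fx$val, uv_variant_set(),
    cv = cv_config(n_iterations = 5, max_lv = 8, seed = 103))
  expect_identical(rep2$table, fx$report$table)
})

test_that("reports serialize to JSON and CSV side by side", {
  fx <- workflow_fixture()
  stem <- tempfile()
  paths <- write_model_report(fx$report, stem)
  on.exit(unlink(paths))
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
  expect_identical(back$label, fx$report$table$label)
  expect_equal(back$rmsecv, fx$report$table$rmsecv, tolerance = 1e-12)
  csv <- utils::read.csv(paths[2])
  expect_identical(nrow(csv), 4L)
})

test_that("hold endpoints are the last spectrum of each hold window", {
  cfg <- toy_config(noise_sd = 0.01, mode = "realistic")
  sol <- solubility_model()
  sl <- generate_slurry_experiment(cfg, sol, seed = 44)
  ep <- extract_hold_endpoints(sl$dataset, sl$profile)
  expect_identical(n_spectra(ep), 8L)
  expect_identical(ep$meta$temperature, sl$profile$setpoint)
  for (h in seq_len(8)) {
    in_window <- sl$dataset$meta$time >= sl$profile$start[h] &
      sl$dataset$meta$time <= sl$profile$end[h]
    expect_identical(ep$meta$time[h], max(sl$dataset$meta$time[in_window]))
  }
  # ramp spectra lie outside every hold window
  ramp <- grepl("^ramp", sl$dataset$meta$sample_id)
  in_any <- outer(sl$dataset$meta$time, seq_len(8), function(tt, h) {
    tt >= sl$profile$start[h] & tt <= sl$profile$end[h]
  })
  expect_false(any(rowSums(in_any)[ramp] > 0))
  # a hold with no spectra is a coverage error
  chopped <- subset_spectra(sl$dataset,
                            !(sl$dataset$meta$temperature == 30 &
                                !grepl("^ramp", sl$dataset$meta$sample_id)))
  expect_error(extract_hold_endpoints(chopped, sl$profile), "coverage error")
})

test_that("solubility curves are recovered through the full chain", {
  cfg <- uv_instrument("linearized", noise_sd = 0)
  sol <- solubility_model()
  cal <- generate_calibration_set(table1_design(), cfg, seed = 51,
                                  n_replicates = 2)
  d <- crop_range(cal, 218, 285)
  sub <- subset_spectra(d, d$meta$concentration %in% c(4, 8, 12))
  m <- lss(sub, 2, t_ref = 50, t_target = 50)
  fit <- pls1(apply_lss_dataset(m, d), n_lv = 1)
  chain <- model_chain(preprocess_spec(218, 285), fit, m, "uv_lss")

  sl <- generate_slurry_experiment(cfg, sol, kinetics_tau = 0, seed = 52)
  ep <- extract_hold_endpoints(sl$dataset, sl$profile)
  curve <- predict_solubility_curve(chain, ep)
  expect_identical(curve$points$temperature, sl$profile$setpoint)
  expect_true(all(diff(curve$points$temperature) > 0))
  truth <- solubility_at(sol, sl$profile$setpoint)
  expect_lt(max(abs(curve$points$concentration - truth) / truth), 0.01)

  # empty endpoints give an empty curve
  empty <- subset_spectra(ep, integer())
  expect_identical(nrow(predict_solubility_curve(chain, empty)$points), 0L)
})

test_that("bias metrics are exact arithmetic on matching grids", {
  a <- solubility_curve(c(0, 10, 20), c(5, 6, 7), "a")
  expect_identical(bias_metrics(a, a)$mean_bias, 0)
  expect_identical(bias_metrics(a, a)$bias_range, 0)

  b <- solubility_curve(c(0, 10, 20), c(5, 6, 7) + 0.5, "b")
  expect_equal(bias_metrics(b, a)$mean_bias, 0.5)
  expect_identical(bias_metrics(b, a)$bias_range, 0)

  c3 <- solubility_curve(c(0, 10, 20), c(5.2, 5.9, 7.3), "c")
  bm <- bias_metrics(c3, a)
  expect_equal(bm$mean_bias, mean(c(0.2, -0.1, 0.3)))
  expect_equal(bm$bias_range, 0.4)

  shifted <- solubility_curve(c(0, 10, 25), c(5, 6, 7), "d")
  expect_error(bias_metrics(shifted, a), "alignment error")
})

test_that("temperature correction tightens the solubility bias spread", {
  fx <- workflow_fixture()
  sol <- solubility_model()
  sl <- generate_slurry_experiment(fx$cfg, sol, seed = 105)
  ep <- extract_hold_endpoints(sl$dataset, sl$profile)
  ref <- reference_curve(sol, sl$profile$setpoint)
  b_lss <- bias_metrics(
    predict_solubility_curve(chain_from_report(fx$report, "global_lss"), ep),
    ref)
  b_raw <- bias_metrics(
    predict_solubility_curve(chain_from_report(fx$report, "global_raw"), ep),
    ref)
  expect_lte(b_lss$bias_range, b_raw$bias_range)
})

test_that("van 't Hoff fits recover the generating curve", {
  sol <- solubility_model(A = 8.1, B = 1600)
  exact <- reference_curve(sol, seq(0, 70, by = 10))
  fit <- fit_vant_hoff(exact)
  expect_lt(abs(fit$A - 8.1), 1e-9)
  expect_lt(abs(fit$B - 1600), 1e-9)

  # two points interpolate exactly
  two <- reference_curve(sol, c(10, 60))
  fit2 <- fit_vant_hoff(two)
  expect_equal(solubility_at(fit2, c(10, 60)), two$points$concentration,
               tolerance = 1e-12)

  # noisy points still recover B within 10%
  noisy <- reference_curve(sol, seq(0, 70, by = 10), noise_sd = 0.1,
                           seed = 61)
  expect_lt(abs(fit_vant_hoff(noisy)$B - 1600) / 1600, 0.10)

  bad <- solubility_curve(c(0, 10), c(-1, 2))
  expect_error(fit_vant_hoff(bad), "domain error")
  expect_error(fit_vant_hoff(solubility_curve(0, 5)), "at least 2")
})
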