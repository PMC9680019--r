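#' Calibration model variant
#'
#' One row of the model-comparison experiment: a preprocessing recipe
#' plus optional temperature handling — loading space standardization of
#' the whole set to `t_target`, or restriction to an isothermal slice
#' (the "local" benchmark in which temperature effects are absent by
#' construction).
#'
#' @param label One of `"global_raw"`, `"global_deriv"`, `"global_lss"`,
#'   `"local_isothermal"` (free-text suffixes allowed after the prefix).
#' @param preprocess A [preprocess_spec()].
#' @param lss_enabled Fit and apply an [lss()] transform.
#' @param lss_input_concentrations Concentrations (g/100 g) used to fit
#'   the LSS model; they must be measured at every temperature. The
#'   fitted transform is then applied to the entire calibration set.
#' @param lss_k Number of LSS factors.
#' @param local_temperature Isothermal slice temperature for local
#'   variants, degC.
#' @param t_target Standardization target temperature, degC.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(label, preprocess, lss_enabled = FALSE,
                          lss_input_concentrations = NULL, lss_k = 2L,
                          local_temperature = NULL, t_target = 50) {
  stopifnot(inherits(preprocess, "preprocess_spec"))
  is_local <- startsWith(label, "local")
  if (is_local && is.null(local_temperature)) {
    stop("local variants require local_temperature", call. = FALSE)
  }
  if (lss_enabled && is.null(lss_input_concentrations)) {
    stop("LSS variants require lss_input_concentrations", call. = FALSE)
  }
  structure(list(label = label, preprocess = preprocess,
                 lss_enabled = isTRUE(lss_enabled),
                 lss_input_concentrations = lss_input_concentrations,
                 lss_k = as.integer(lss_k),
                 local_temperature = local_temperature,
                 t_target = t_target),
            class = "model_variant")
}

#' Standard four-variant comparison sets
#'
#' The four model variants compared by [run_calibration_comparison()],
#' mirroring the conventional layout of such studies: a global model on
#' raw absorbance, a global model on first-derivative spectra, a global
#' model after standardization of all spectra to 50 degC, and an
#' isothermal local model at 50 degC as the benchmark without
#' temperature effects.
#'
#' For UV the working range is 218-285 nm with a 15-point derivative
#' window, and the standardization variant operates on raw absorbance;
#' for mid-IR the range is 709-1831 cm-1 with a 7-point window, and the
#' standardization variant operates on first-derivative spectra (whose
#' baseline effects would otherwise dominate).
#'
#' @param lss_concentrations Concentrations used to fit the LSS model
#'   (those measured at every temperature in the bundled design).
#' @param t_target Standardization / local temperature, degC.
#' @return List of four [model_variant()] objects.
#' @export
uv_variant_set <- function(lss_concentrations = c(4, 8, 12),
                           t_target = 50) {
  uv_raw <- preprocess_spec(218, 285)
  uv_sg <- preprocess_spec(218, 285, sg_window = 15)
  list(
    model_variant("global_raw", uv_raw),
    model_variant("global_deriv", uv_sg),
    model_variant("global_lss", uv_raw, lss_enabled = TRUE,
                  lss_input_concentrations = lss_concentrations,
                  t_target = t_target),
    model_variant("local_isothermal", uv_raw,
                  local_temperature = t_target)
  )
}

#' @rdname uv_variant_set
#' @export
ir_variant_set <- function(lss_concentrations = c(4, 8, 12),
                           t_target = 50) {
  ir_raw <- preprocess_spec(709, 1831)
  ir_sg <- preprocess_spec(709, 1831, sg_window = 7)
  list(
    model_variant("global_raw", ir_raw),
    model_variant("global_deriv", ir_sg),
    model_variant("global_lss", ir_sg, lss_enabled = TRUE,
                  lss_input_concentrations = lss_concentrations,
                  t_target = t_target),
    model_variant("local_isothermal", ir_sg,
                  local_temperature = t_target)
  )
}

#' Run the calibration-model comparison
#'
#' For each variant: preprocess the calibration and validation sets; for
#' standardization variants, fit the LSS model on the designated
#' concentrations only and transform both sets to `t_target`; for local
#' variants, restrict training to the isothermal slice; run
#' random-subset cross-validation, select the parsimonious number of
#' latent variables, refit on all training spectra, and evaluate every
#' validation sample with replicate-level prediction summaries.
#'
#' @param cal Calibration [spectral_dataset()].
#' @param val Validation [spectral_dataset()] (distinct known samples,
#'   replicate spectra each).
#' @param variants List of [model_variant()], e.g. [uv_variant_set()].
#' @param cv A [cv_config()].
#' @param lv_tolerance Passed to [select_latent_variables()].
#' @return An object of class `model_report`: `$table` (one row per
#'   variant: label, n_lv, rmsec, r2_cal, rmsecv, r2_cv, then per
#'   validation sample rmse/mean/min/max/rsd) and `$details` (per
#'   variant: the fitted `pls1`, `lss` model if any, and `cv_result`).
#' @export
run_calibration_comparison <- function(cal, val, variants, cv = cv_config(),
                                       lv_tolerance = 0.10) {
  details <- list()
  rows <- list()
  val_conc <- sort(unique(val$meta$concentration))
  for (variant in variants) {
    d <- apply_preprocess(cal, variant$preprocess)
    v <- apply_preprocess(val, variant$preprocess)
    lss_model <- NULL
    if (variant$lss_enabled) {
      sub <- subset_spectra(
        d, d$meta$concentration %in% variant$lss_input_concentrations)
      lss_model <- lss(sub, k = variant$lss_k,
                       t_ref = variant$t_target,
                       t_target = variant$t_target)
      d <- apply_lss_dataset(lss_model, d)
      v <- apply_lss_dataset(lss_model, v)
    }
    if (!is.null(variant$local_temperature)) {
      keep <- abs(d$meta$temperature - variant$local_temperature) < 1e-9
      if (!any(keep)) {
        stop(sprintf("design error: no calibration spectra at %g degC",
                     variant$local_temperature), call. = FALSE)
      }
      d <- subset_spectra(d, keep)
      missing <- setdiff(unique(cal$meta$concentration),
                         unique(d$meta$concentration))
      if (length(missing)) {
        stop(sprintf(
          "design error: concentrations %s absent from the %g degC slice",
          paste(missing, collapse = ", "), variant$local_temperature),
          call. = FALSE)
      }
    }
    cvres <- random_subset_cv(d, cfg = cv)
    n_lv <- select_latent_variables(cvres, lv_tolerance)
    fit <- pls1(d, n_lv = n_lv)
    mc <- regression_metrics(fit$y, fit$fitted.values)
    row <- data.frame(label = variant$label, n_lv = n_lv,
                      rmsec = mc$rmse, r2_cal = mc$r2,
                      rmsecv = cvres$rmsecv[n_lv],
                      r2_cv = cvres$r2cv[n_lv],
                      stringsAsFactors = FALSE)
    summaries <- list()
    for (cc in val_conc) {
      vi <- subset_spectra(v, v$meta$concentration == cc)
      ps <- prediction_summary(predict(fit, vi), cc)
      summaries[[as.character(cc)]] <- ps
      tag <- sprintf("val%g", cc)
      row[[paste0(tag, "_rmse")]] <- ps$rmse
      row[[paste0(tag, "_mean")]] <- ps$mean
      row[[paste0(tag, "_min")]] <- ps$min
      row[[paste0(tag, "_max")]] <- ps$max
      row[[paste0(tag, "_rsd")]] <- ps$rsd
    }
    rows[[variant$label]] <- row
    details[[variant$label]] <- list(variant = variant, pls = fit,
                                     lss = lss_model, cv = cvres,
                                     validation = summaries)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a model report to JSON and CSV
#'
#' Emits machine-readable copies of the comparison table side by side:
#' `<stem>.json` (full table, one object per variant) and `<stem>.csv`.
#'
#' @param report A `model_report` from [run_calibration_comparison()].
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_model_report <- function(report, stem) {
  paths <- paste0(stem, c(".json", ".csv"))
  jsonlite::write_json(report$table, paths[1], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$table, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Extract hold-endpoint spectra from a slurry experiment
#'
#' For each hold window of the temperature profile, selects the
#' latest-timestamped spectrum within the window (the point at which the
#' supernatant is closest to equilibrium) and sets its metadata
#' temperature to the hold setpoint. Spectra acquired during ramps fall
#' outside every window and are excluded.
#'
#' @param dataset Slurry [spectral_dataset()] with timestamps.
#' @param profile Data frame with columns `start`, `end`, `setpoint`
#'   (one row per hold), as returned by [generate_slurry_experiment()].
#' @return A [spectral_dataset()] with one spectrum per hold, in profile
#'   order.
#' @export
extract_hold_endpoints <- function(dataset, profile) {
  stopifnot(all(c("start", "end", "setpoint") %in% names(profile)))
  idx <- integer(nrow(profile))
  for (h in seq_len(nrow(profile))) {
    in_window <- which(dataset$meta$time >= profile$start[h] &
                         dataset$meta$time <= profile$end[h])
    if (length(in_window) == 0L) {
      stop(sprintf("coverage error: no spectra in hold %d (%g degC)",
                   h, profile$setpoint[h]), call. = FALSE)
    }
    idx[h] <- in_window[which.max(dataset$meta$time[in_window])]
  }
  out <- subset_spectra(dataset, idx)
  out$meta$temperature <- profile$setpoint
  out
}

#' Prediction chain: preprocessing + optional LSS + PLS
#'
#' Bundles the full path from a raw spectrum to a predicted
#' concentration so it can be applied consistently to new data: crop,
#' optional Savitzky-Golay derivative, optional standardization of each
#' spectrum from its own temperature to `t_target`, then PLS prediction.
#'
#' @param preprocess A [preprocess_spec()].
#' @param pls A fitted [pls1()] model.
#' @param lss A fitted [lss()] model, or `NULL` for no temperature
#'   correction.
#' @param label Free-text chain label carried into curves.
#' @return An object of class `model_chain`.
#' @export
model_chain <- function(preprocess, pls, lss = NULL, label = "chain") {
  stopifnot(inherits(preprocess, "preprocess_spec"),
            inherits(pls, "pls1"),
            is.null(lss) || inherits(lss, "lss"))
  structure(list(preprocess = preprocess, pls = pls, lss = lss,
                 label = label),
            class = "model_chain")
}

#' Chain from a comparison report variant
#'
#' Convenience accessor: rebuilds the [model_chain()] of one variant of a
#' [run_calibration_comparison()] report.
#'
#' @param report A `model_report`.
#' @param label Variant label present in the report.
#' @return A [model_chain()].
#' @export
chain_from_report <- function(report, label) {
  det <- report$details[[label]]
  if (is.null(det)) {
    stop(sprintf("no variant '%s' in report", label), call. = FALSE)
  }
  model_chain(det$variant$preprocess, det$pls, det$lss, label = label)
}

#' @export
predict.model_chain <- function(object, newdata, ...) {
  d <- apply_preprocess(newdata, object$preprocess)
  if (!is.null(object$lss)) {
    d <- apply_lss_dataset(object$lss, d)
  }
  predict(object$pls, d)
}

#' Solubility curve container
#'
#' @param temperature Strictly increasing temperatures, degC.
#' @param concentration Concentrations, g/100 g solvent.
#' @param method_label Free-text provenance label.
#' @return An object of class `solubility_curve` with a `$points` data
#'   frame.
#' @export
solubility_curve <- function(temperature, concentration,
                             method_label = "") {
  stopifnot(length(temperature) == length(concentration))
  if (length(temperature) > 1L && any(diff(temperature) <= 0)) {
    stop("curve temperatures must be strictly increasing", call. = FALSE)
  }
  structure(list(points = data.frame(temperature = as.numeric(temperature),
                                     concentration = as.numeric(concentration)),
                 method_label = method_label),
            class = "solubility_curve")
}

#' @export
print.solubility_curve <- function(x, ...) {
  cat(sprintf("<solubility_curve> '%s', %d points\n", x$method_label,
              nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
plot.solubility_curve <- function(x, ...) {
  graphics::plot(x$points$temperature, x$points$concentration, type = "b",
                 xlab = "temperature (degC)",
                 ylab = "solubility (g/100 g solvent)", ...)
  invisible(x)
}

#' Predict a solubility curve from hold-endpoint spectra
#'
#' Applies a full prediction chain to each hold-endpoint spectrum and
#' records (hold temperature, predicted concentration).
#'
#' @param chain A [model_chain()].
#' @param endpoints Hold-endpoint [spectral_dataset()] from
#'   [extract_hold_endpoints()].
#' @return A [solubility_curve()] labelled with the chain's label.
#' @export
predict_solubility_curve <- function(chain, endpoints) {
  if (n_spectra(endpoints) == 0L) {
    return(solubility_curve(numeric(), numeric(), chain$label))
  }
  preds <- predict(chain, endpoints)
  ord <- order(endpoints$meta$temperature)
  solubility_curve(endpoints$meta$temperature[ord], preds[ord],
                   method_label = chain$label)
}

#' Reference solubility curve from a ground-truth model
#'
#' Evaluates a [solubility_model()] on a temperature grid, optionally
#' with Gaussian measurement noise — a synthetic stand-in for a
#' gravimetric or transmittance reference curve.
#'
#' @param sol A [solubility_model()].
#' @param temperatures Strictly increasing grid, degC.
#' @param noise_sd Measurement noise sd, g/100 g (0 = exact).
#' @param seed Seed for the noise draw.
#' @param method_label Curve label.
#' @return A [solubility_curve()].
#' @export
reference_curve <- function(sol, temperatures, noise_sd = 0, seed = NULL,
                            method_label = "ground_truth") {
  s <- solubility_at(sol, temperatures)
  if (noise_sd > 0) {
    s <- s + with_seed(seed, stats::rnorm(length(s), 0, noise_sd))
  }
  solubility_curve(temperatures, s, method_label)
}

#' Bias between a predicted and a reference solubility curve
#'
#' Per-temperature bias (predicted minus reference) on exactly matching
#' temperature grids — no interpolation between grids is performed —
#' summarized by its mean and range.
#'
#' @param predicted,reference [solubility_curve()] objects on identical
#'   temperature grids.
#' @return An object of class `bias_summary`: `biases` (named by
#'   temperature), `mean_bias`, `bias_range` (max - min).
#' @export
bias_metrics <- function(predicted, reference) {
  tp <- predicted$points$temperature
  tr <- reference$points$temperature
  if (length(tp) != length(tr) || any(abs(tp - tr) > 1e-9)) {
    stop("alignment error: curves are not on matching temperature grids",
         call. = FALSE)
  }
  b <- predicted$points$concentration - reference$points$concentration
  names(b) <- tp
  structure(list(biases = b, mean_bias = mean(b),
                 bias_range = max(b) - min(b)),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("<bias_summary> mean %.4g, range %.4g g/100 g over %d points\n",
              x$mean_bias, x$bias_range, length(x$biases)))
  invisible(x)
}

#' Fit a van 't Hoff solubility model to a curve
#'
#' Ordinary least squares of `ln S` against inverse absolute temperature
#' `1/(T + 273.15)`: the intercept is `A` and the negated slope is `B`.
#' Exact for points generated from the same functional form.
#'
#' @param curve A [solubility_curve()] with >= 2 points, all
#'   concentrations > 0.
#' @return A [solubility_model()] (with `metastable_factor = 1`).
#' @export
fit_vant_hoff <- function(curve) {
  pts <- curve$points
  if (nrow(pts) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(pts$concentration <= 0)) {
    stop("domain error: concentrations must be positive", call. = FALSE)
  }
  invT <- 1 / (pts$temperature + 273.15)
  fit <- stats::lm.fit(cbind(1, invT), log(pts$concentration))
  solubility_model(A = unname(fit$coefficients[1]),
                   B = -unname(fit$coefficients[2]),
                   metastable_factor = 1)
}
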