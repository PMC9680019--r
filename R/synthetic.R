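#' Gaussian band specification
#'
#' One absorption band of the synthetic instrument model. The band is a
#' Gaussian in the axis variable whose center, width and height drift
#' smoothly with temperature, each modelled by a quadratic polynomial in
#' temperature (degrees Celsius):
#' \deqn{center(T) = center_0 + k_0 + k_1 T + k_2 T^2}
#' and likewise for width, while the height scales multiplicatively as
#' `height0 * (1 + dheight(T))`. Solute bands scale linearly with
#' concentration (Beer-Lambert); solvent bands do not.
#'
#' @param center0 Band center at the quadratic's origin, in axis units.
#' @param width0 Gaussian sigma in axis units, > 0.
#' @param height0 Peak absorbance per (g/100 g) for `species = "solute"`,
#'   absolute absorbance for `species = "solvent"`.
#' @param species `"solute"` or `"solvent"`.
#' @param dcenter,dwidth,dheight Length-3 quadratic coefficient vectors
#'   `(k0, k1, k2)` describing the temperature drift of center shift,
#'   width shift, and fractional height change respectively.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center0, width0, height0,
                      species = c("solute", "solvent"),
                      dcenter = c(0, 0, 0), dwidth = c(0, 0, 0),
                      dheight = c(0, 0, 0)) {
  species <- match.arg(species)
  stopifnot(length(dcenter) == 3L, length(dwidth) == 3L,
            length(dheight) == 3L, is.finite(center0), is.finite(height0))
  if (!is.finite(width0) || width0 <= 0) {
    stop("width0 must be positive", call. = FALSE)
  }
  structure(list(center0 = center0, width0 = width0, height0 = height0,
                 species = species, dcenter = as.numeric(dcenter),
                 dwidth = as.numeric(dwidth), dheight = as.numeric(dheight)),
            class = "band_spec")
}

#' Synthetic instrument configuration
#'
#' Bundles the axis, the band list, baseline drift, noise level and
#' replicate count that define one simulated spectrometer. Two modes are
#' supported: `"realistic"`, in which band centers and widths shift with
#' temperature so that per-temperature loading vectors are only
#' approximately quadratic in temperature (exercising the robustness of
#' the temperature correction), and `"linearized"`, in which band shapes
#' are frozen and only the quadratic height and baseline scalings act, so
#' the data are exactly low-rank with loadings exactly quadratic in
#' temperature (the regime in which the correction is provably exact).
#'
#' The baseline is `offset(T) + slope(T) * (x - min(axis))` with
#' `offset` and `slope` each quadratic in temperature.
#'
#' @param axis A [spectral_axis()].
#' @param bands List of [band_spec()]; at least one solute band.
#' @param baseline_offset,baseline_slope Length-3 quadratic coefficient
#'   vectors in absorbance units and absorbance per axis unit.
#' @param noise_sd Standard deviation of i.i.d. Gaussian channel noise,
#'   absorbance units, >= 0.
#' @param n_replicates Default replicate spectra per sample, >= 1.
#' @param mode `"realistic"` or `"linearized"`.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(axis, bands,
                              baseline_offset = c(0, 0, 0),
                              baseline_slope = c(0, 0, 0),
                              noise_sd = 0, n_replicates = 1L,
                              mode = c("realistic", "linearized")) {
  mode <- match.arg(mode)
  stopifnot(inherits(axis, "spectral_axis"), length(bands) >= 1L,
            all(vapply(bands, inherits, logical(1), "band_spec")),
            length(baseline_offset) == 3L, length(baseline_slope) == 3L,
            noise_sd >= 0, n_replicates >= 1L)
  if (!any(vapply(bands, function(b) b$species == "solute", logical(1)))) {
    stop("at least one solute band is required", call. = FALSE)
  }
  structure(list(axis = axis, bands = bands,
                 baseline_offset = as.numeric(baseline_offset),
                 baseline_slope = as.numeric(baseline_slope),
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 mode = mode),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf("<instrument_config> %s mode, %d bands, noise_sd=%g, %d replicates\n",
              x$mode, length(x$bands), x$noise_sd, x$n_replicates))
  print(x$axis)
  invisible(x)
}

band_center <- function(band, temperature, mode) {
  if (mode == "linearized") band$center0
  else band$center0 + poly2(band$dcenter, temperature)
}

band_width <- function(band, temperature, mode) {
  if (mode == "linearized") band$width0
  else band$width0 + poly2(band$dwidth, temperature)
}

check_band_support <- function(config, temperature) {
  rng <- range(config$axis$values)
  for (b in config$bands) {
    ctr <- band_center(b, temperature, config$mode)
    wid <- band_width(b, temperature, config$mode)
    if (wid <= 0) {
      stop(sprintf("band at %g has non-positive width at %g degC",
                   b$center0, temperature), call. = FALSE)
    }
    if (ctr - 3 * wid < rng[1] || ctr + 3 * wid > rng[2]) {
      stop(sprintf(
        "configuration error: band at %g leaves axis support at %g degC",
        b$center0, temperature), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# noiseless spectrum: sum of bands + baseline
clean_spectrum <- function(config, concentration, temperature) {
  check_band_support(config, temperature)
  x <- config$axis$values
  s <- numeric(length(x))
  for (b in config$bands) {
    ctr <- band_center(b, temperature, config$mode)
    wid <- band_width(b, temperature, config$mode)
    h <- b$height0 * (1 + poly2(b$dheight, temperature))
    if (b$species == "solute") h <- h * concentration
    s <- s + h * exp(-(x - ctr)^2 / (2 * wid^2))
  }
  s + poly2(config$baseline_offset, temperature) +
    poly2(config$baseline_slope, temperature) * (x - x[1])
}

#' Simulate one spectrum
#'
#' Evaluates the instrument model at one (concentration, temperature)
#' point: Gaussian bands (solute bands scaled by concentration), baseline
#' drift, plus i.i.d. Gaussian channel noise. With `noise_sd = 0` the
#' result is deterministic and affine in concentration at every axis
#' point (Beer-Lambert).
#'
#' @param config An [instrument_config()].
#' @param concentration Solute concentration, g/100 g solvent, >= 0.
#' @param temperature Temperature in degrees Celsius.
#' @param seed Integer seed for the noise draw; identical seeds give
#'   identical spectra. `NULL` uses the current RNG stream.
#' @return Numeric intensity vector of length `length(config$axis$values)`.
#' @export
simulate_spectrum <- function(config, concentration, temperature,
                              seed = NULL) {
  stopifnot(concentration >= 0)
  s <- clean_spectrum(config, concentration, temperature)
  if (config$noise_sd > 0) {
    s <- s + with_seed(seed, stats::rnorm(length(s), 0, config$noise_sd))
  }
  s
}

#' Ground-truth solubility model (van 't Hoff form)
#'
#' Equilibrium solubility as a function of temperature:
#' \deqn{S(T) = \exp(A - B / (T + 273.15))}
#' in g solute per 100 g solvent, strictly increasing in temperature for
#' `B > 0`. This is the ground truth the slurry generator equilibrates
#' toward and the curve the analysis workflow is asked to recover. The
#' metastable factor bounds how far above saturation a clear calibration
#' sample may sit before nucleating.
#'
#' @param A Dimensionless intercept of `ln S` against inverse absolute
#'   temperature.
#' @param B Slope parameter in Kelvin (dissolution enthalpy over R).
#' @param metastable_factor Supersaturation ratio >= 1 tolerated by clear
#'   metastable samples.
#' @return An object of class `solubility_model`.
#' @examples
#' sol <- solubility_model()
#' solubility_at(sol, 50)
#' @export
solubility_model <- function(A = 8.1, B = 1600, metastable_factor = 1.6) {
  stopifnot(is.finite(A), is.finite(B), metastable_factor >= 1)
  structure(list(A = A, B = B, metastable_factor = metastable_factor),
            class = "solubility_model")
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf("<solubility_model> S(T) = exp(%.6g - %.6g/(T + 273.15)) g/100 g\n",
              x$A, x$B))
  invisible(x)
}

#' Evaluate a solubility model
#'
#' @param model A [solubility_model()].
#' @param temperature Temperature(s) in degrees Celsius, > -273.15.
#' @return Solubility in g/100 g solvent.
#' @export
solubility_at <- function(model, temperature) {
  stopifnot(all(temperature > -273.15))
  exp(model$A - model$B / (temperature + 273.15))
}

#' @export
predict.solubility_model <- function(object, temperature, ...) {
  solubility_at(object, temperature)
}

#' Calibration design
#'
#' A set of (concentration, list of temperatures) entries describing which
#' samples make up a calibration set.
#'
#' @param entries Named list: names are concentrations (g/100 g solvent,
#'   coercible to numeric), values are numeric vectors of temperatures in
#'   degrees Celsius (unique within an entry).
#' @return An object of class `calibration_design` with a long-format
#'   `$samples` data frame (columns `concentration`, `temperature`).
#' @export
calibration_design <- function(entries) {
  conc <- as.numeric(names(entries))
  if (any(is.na(conc)) || anyDuplicated(conc)) {
    stop("entry names must be unique numeric concentrations", call. = FALSE)
  }
  for (i in seq_along(entries)) {
    if (anyDuplicated(entries[[i]])) {
      stop("temperatures must be unique within an entry", call. = FALSE)
    }
  }
  samples <- do.call(rbind, lapply(seq_along(entries), function(i) {
    data.frame(concentration = conc[i],
               temperature = as.numeric(entries[[i]]))
  }))
  structure(list(samples = samples), class = "calibration_design")
}

#' @export
print.calibration_design <- function(x, ...) {
  cat(sprintf("<calibration_design> %d samples, %d concentrations\n",
              nrow(x$samples), length(unique(x$samples$concentration))))
  invisible(x)
}

#' The study's stepped-cooling calibration design
#'
#' The solubility-limited design used throughout the package's worked
#' examples: concentrations 4, 8 and 12 g/100 g solvent measured at all
#' ten temperatures (-10, 0, 10, 20, 30, 40, 50, 60, 70, 75 degC),
#' 16 g/100 g at 30-75 degC, and 20 g/100 g at 50-75 degC only, for 40
#' (concentration, temperature) samples in total. Higher concentrations
#' are absent at low temperature because such samples would nucleate:
#' 50 degC is the lowest temperature at which every concentration is
#' present, which is why it serves as the standardization target.
#'
#' @return A [calibration_design()] with 40 samples.
#' @export
table1_design <- function() {
  all_t <- c(-10, 0, 10, 20, 30, 40, 50, 60, 70, 75)
  calibration_design(list(
    "4" = all_t,
    "8" = all_t,
    "12" = all_t,
    "16" = c(30, 40, 50, 60, 70, 75),
    "20" = c(50, 60, 70, 75)
  ))
}

#' Default synthetic UV instrument
#'
#' A single-solute ATR-UV emulation: axis 200-320 nm at 1 nm spacing, a
#' solute band near 244 nm whose center, width and height drift with
#' temperature (blue-shift and broadening on heating), a broad weak
#' solvent band, and mild temperature-dependent baseline drift. Defaults
#' give peak absorbance about 1 AU at 20 g/100 g against channel noise of
#' 0.002 AU, with 22 replicate spectra per sample.
#'
#' @param mode `"realistic"` (band shapes shift with temperature) or
#'   `"linearized"` (exactly low-rank, loadings exactly quadratic).
#' @param noise_sd Channel noise sd in absorbance units.
#' @param n_replicates Replicate spectra per sample.
#' @return An [instrument_config()].
#' @export
uv_instrument <- function(mode = c("realistic", "linearized"),
                          noise_sd = 0.002, n_replicates = 22L) {
  mode <- match.arg(mode)
  axis <- spectral_axis("wavelength_nm", seq(200, 320, by = 1))
  bands <- list(
    band_spec(244, 12, 0.05, "solute",
              dcenter = c(0, -0.055, 1.5e-4),
              dwidth = c(0, 0.015, 0),
              dheight = c(0, -2.2e-3, -6e-6)),
    band_spec(220, 6, 0.15, "solvent",
              dcenter = c(0, 0.010, 0),
              dwidth = c(0, 0.002, 0),
              dheight = c(0, -8e-4, -2e-6))
  )
  instrument_config(axis, bands,
                    baseline_offset = c(0.01, 2e-4, 1e-6),
                    baseline_slope = c(1e-4, 1e-6, 0),
                    noise_sd = noise_sd, n_replicates = n_replicates,
                    mode = mode)
}

#' Default synthetic mid-IR instrument
#'
#' A multi-band ATR mid-IR emulation: axis 650-1900 cm-1 at 4 cm-1
#' spacing; solute carbonyl/ene bands near 1765 and 1695 cm-1 that drift
#' considerably with temperature plus ester/alcohol bands near 1200, 1140
#' and 1040 cm-1; solvent bands near 1620, 1380 and 920 cm-1 that drift
#' much less; 14 replicate spectra per sample.
#'
#' @inheritParams uv_instrument
#' @return An [instrument_config()].
#' @export
ir_instrument <- function(mode = c("realistic", "linearized"),
                          noise_sd = 0.001, n_replicates = 14L) {
  mode <- match.arg(mode)
  axis <- spectral_axis("wavenumber_cm-1", seq(650, 1900, by = 4))
  sol_dc <- c(0, 0.030, 2e-4)
  sol_dw <- c(0, 0.010, 0)
  sol_dh <- c(0, -2.0e-3, -8e-6)
  solv_dc <- c(0, 0.004, 0)
  solv_dh <- c(0, -4e-4, 0)
  bands <- list(
    band_spec(1765, 12, 0.010, "solute", sol_dc, sol_dw, sol_dh),
    band_spec(1695, 14, 0.012, "solute", sol_dc, sol_dw, sol_dh),
    band_spec(1200, 18, 0.006, "solute", sol_dc, sol_dw, sol_dh),
    band_spec(1140, 12, 0.005, "solute", sol_dc, sol_dw, sol_dh),
    band_spec(1040, 14, 0.007, "solute", sol_dc, sol_dw, sol_dh),
    band_spec(1620, 20, 0.15, "solvent", solv_dc, c(0, 0.002, 0), solv_dh),
    band_spec(1380, 10, 0.25, "solvent", solv_dc, c(0, 0.001, 0), solv_dh),
    band_spec(920, 12, 0.20, "solvent", solv_dc, c(0, 0.001, 0), solv_dh)
  )
  instrument_config(axis, bands,
                    baseline_offset = c(0.02, 3e-4, 1e-6),
                    baseline_slope = c(2e-5, 2e-7, 0),
                    noise_sd = noise_sd, n_replicates = n_replicates,
                    mode = mode)
}

#' Generate a calibration dataset
#'
#' Simulates `config$n_replicates` replicate spectra for every
#' (concentration, temperature) sample of a design, in composition-major,
#' temperature-minor order, with metadata populated and
#' `role = "calibration"`. Replicate spectra of a sample differ only by
#' channel noise. The design is taken literally: no censoring by
#' solubility is applied.
#'
#' @param design A [calibration_design()], e.g. [table1_design()].
#' @param config An [instrument_config()].
#' @param seed Integer master seed; the run is fully reproducible.
#' @param n_replicates Override of `config$n_replicates`.
#' @return A [spectral_dataset()] with
#'   `nrow(design$samples) * n_replicates` spectra.
#' @export
generate_calibration_set <- function(design, config, seed = 1L,
                                     n_replicates = config$n_replicates) {
  samples <- design$samples
  n_rep <- as.integer(n_replicates)
  n <- nrow(samples) * n_rep
  seeds <- derive_seeds(seed, n)
  p <- length(config$axis$values)
  X <- matrix(NA_real_, n, p)
  meta <- vector("list", nrow(samples))
  row <- 0L
  for (i in seq_len(nrow(samples))) {
    ci <- samples$concentration[i]
    ti <- samples$temperature[i]
    for (r in seq_len(n_rep)) {
      row <- row + 1L
      X[row, ] <- simulate_spectrum(config, ci, ti, seed = seeds[row])
    }
    meta[[i]] <- spectrum_meta(
      sample_id = sprintf("cal_c%g_T%g", ci, ti),
      concentration = ci, temperature = ti,
      time = (row - n_rep + seq_len(n_rep) - 1L) * 30,
      replicate = seq_len(n_rep), role = "calibration")
  }
  spectral_dataset(config$axis, X, do.call(rbind, meta))
}

#' Generate the two-point validation dataset
#'
#' Simulates replicate spectra for the two validation samples used by the
#' calibration-comparison workflow: 5 g/100 g solvent held at 20 degC and
#' 15 g/100 g solvent held at 65 degC, chosen to sit at low and high
#' concentration/temperature within the design space.
#'
#' @param config An [instrument_config()].
#' @param seed Integer master seed.
#' @param n_replicates Override of `config$n_replicates`.
#' @return A [spectral_dataset()] with `2 * n_replicates` spectra,
#'   `role = "validation"`.
#' @export
generate_validation_set <- function(config, seed = 1L,
                                    n_replicates = config$n_replicates) {
  points <- data.frame(concentration = c(5, 15), temperature = c(20, 65))
  design <- calibration_design(
    stats::setNames(as.list(points$temperature),
                    as.character(points$concentration)))
  d <- generate_calibration_set(design, config, seed = seed,
                                n_replicates = n_replicates)
  d$meta$role <- "validation"
  d$meta$sample_id <- sub("^cal_", "val_", d$meta$sample_id)
  d
}

#' Generate a stepped-heating slurry experiment
#'
#' Emulates solubility determination by heated-slurry monitoring: a
#' slurry with excess solid is stepped through increasing hold
#' temperatures (linear ramps between holds); during each hold the
#' supernatant concentration relaxes exponentially, with time constant
#' `kinetics_tau`, from its previous value toward the equilibrium
#' solubility `S(T_hold)` of the ground-truth model. Spectra are
#' timestamped within holds (and, sparsely, during ramps, where the
#' concentration is held at its last value); metadata carries the true
#' supernatant concentration so recovery can be tested.
#'
#' @param config An [instrument_config()].
#' @param sol A [solubility_model()] providing the ground truth `S(T)`.
#' @param hold_temps Increasing hold setpoints in degC.
#' @param hold_duration Hold length in seconds.
#' @param spectra_per_hold Spectra acquired per hold, evenly spaced with
#'   the last at the hold's end.
#' @param kinetics_tau Dissolution time constant in seconds; `0` means
#'   instantaneous equilibration.
#' @param ramp_rate Heating rate between holds, degC per minute.
#' @param spectra_per_ramp Spectra acquired during each ramp (excluded
#'   from hold windows; default 2).
#' @param seed Integer master seed.
#' @return A list with elements `dataset` (a [spectral_dataset()],
#'   `role = "slurry"`) and `profile` (data frame with one row per hold:
#'   `start`, `end`, `setpoint`).
#' @export
generate_slurry_experiment <- function(config, sol,
                                       hold_temps = seq(0, 70, by = 10),
                                       hold_duration = 1800,
                                       spectra_per_hold = 10L,
                                       kinetics_tau = 300,
                                       ramp_rate = 5,
                                       spectra_per_ramp = 2L,
                                       seed = 1L) {
  stopifnot(length(hold_temps) >= 1L, all(diff(hold_temps) > 0),
            hold_duration > 0, spectra_per_hold >= 1L, kinetics_tau >= 0,
            ramp_rate > 0)
  n_h <- length(hold_temps)
  relax <- function(c0, s_eq, dt) {
    if (kinetics_tau == 0) s_eq else s_eq + (c0 - s_eq) * exp(-dt / kinetics_tau)
  }
  recs <- list()
  t_now <- 0
  conc <- solubility_at(sol, hold_temps[1])  # equilibrated before first hold
  profile <- data.frame(start = numeric(n_h), end = numeric(n_h),
                        setpoint = hold_temps)
  for (h in seq_len(n_h)) {
    if (h > 1L) {
      ramp_time <- (hold_temps[h] - hold_temps[h - 1]) / ramp_rate * 60
      if (spectra_per_ramp >= 1L) {
        frac <- seq_len(spectra_per_ramp) / (spectra_per_ramp + 1)
        for (f in frac) {
          recs[[length(recs) + 1L]] <- list(
            time = t_now + f * ramp_time,
            temp = hold_temps[h - 1] + f * (hold_temps[h] - hold_temps[h - 1]),
            conc = conc, id = sprintf("ramp_%02d", h - 1L))
        }
      }
      t_now <- t_now + ramp_time
    }
    profile$start[h] <- t_now
    profile$end[h] <- t_now + hold_duration
    s_eq <- solubility_at(sol, hold_temps[h])
    offs <- hold_duration * seq_len(spectra_per_hold) / spectra_per_hold
    for (o in offs) {
      recs[[length(recs) + 1L]] <- list(
        time = t_now + o, temp = hold_temps[h],
        conc = relax(conc, s_eq, o), id = sprintf("hold_T%g", hold_temps[h]))
    }
    conc <- relax(conc, s_eq, hold_duration)
    t_now <- t_now + hold_duration
  }
  n <- length(recs)
  seeds <- derive_seeds(seed, n)
  p <- length(config$axis$values)
  X <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    X[i, ] <- simulate_spectrum(config, recs[[i]]$conc, recs[[i]]$temp,
                                seed = seeds[i])
  }
  meta <- spectrum_meta(
    sample_id = vapply(recs, `[[`, character(1), "id"),
    concentration = vapply(recs, `[[`, numeric(1), "conc"),
    temperature = vapply(recs, `[[`, numeric(1), "temp"),
    time = vapply(recs, `[[`, numeric(1), "time"),
    replicate = 1L, role = "slurry")
  # replicate index within each hold/ramp group keeps (id, replicate, time)
  # unique even if two groups shared a timestamp
  meta$replicate <- stats::ave(seq_len(n), meta$sample_id,
                               FUN = seq_along)
  list(dataset = spectral_dataset(config$axis, X, meta), profile = profile)
}
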