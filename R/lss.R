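#' Factor diagnostics from a singular value decomposition
#'
#' @param singular_values Non-increasing, non-negative singular values of
#'   the reference-temperature data matrix.
#' @return An object of class `factor_diagnostics` with elements
#'   `singular_values` and `variance_explained` (cumulative fractions of
#'   squared singular values).
#' @export
factor_diagnostics <- function(singular_values) {
  sv <- as.numeric(singular_values)
  if (length(sv) == 0L) {
    stop("input error: empty singular value vector", call. = FALSE)
  }
  if (any(sv < 0) || any(diff(sv) > 0)) {
    stop("singular values must be non-increasing and non-negative",
         call. = FALSE)
  }
  tot <- sum(sv^2)
  ve <- if (tot > 0) cumsum(sv^2) / tot else rep(0, length(sv))
  structure(list(singular_values = sv, variance_explained = ve),
            class = "factor_diagnostics")
}

#' Choose the number of standardization factors
#'
#' Returns the smallest number of factors whose cumulative squared
#' singular values reach the variance threshold. With the default
#' threshold of 0.995, two-factor structure (one solute and one solvent
#' direction) yields K = 2.
#'
#' @param diag A [factor_diagnostics()] object (or a numeric vector of
#'   singular values).
#' @param variance_threshold Fraction in (0, 1].
#' @return Integer number of factors.
#' @export
select_n_components <- function(diag, variance_threshold = 0.995) {
  if (!inherits(diag, "factor_diagnostics")) {
    diag <- factor_diagnostics(diag)
  }
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  ve <- diag$variance_explained
  k <- which(ve >= variance_threshold - 1e-15)
  if (length(k) == 0L) length(ve) else k[1]
}

# assemble per-temperature matrices with consistent row ordering:
# composition-major, replicate-minor, truncated to the dataset-wide
# minimum replicate count per (composition, temperature) cell
lss_stack <- function(dataset) {
  meta <- dataset$meta
  temps <- sort(unique(meta$temperature))
  comps <- sort(unique(meta$concentration))
  if (anyNA(comps)) {
    stop("all spectra must have known concentrations", call. = FALSE)
  }
  counts <- table(factor(meta$concentration, levels = comps),
                  factor(meta$temperature, levels = temps))
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "design error: composition %g g/100 g has no spectra at %g degC",
      comps[bad[1]], temps[bad[2]]), call. = FALSE)
  }
  r_min <- min(counts)
  idx_mats <- lapply(temps, function(tm) {
    rows <- unlist(lapply(comps, function(cc) {
      i <- which(meta$concentration == cc & meta$temperature == tm)
      i[order(meta$replicate[i], meta$time[i])][seq_len(r_min)]
    }))
    dataset$intensities[rows, , drop = FALSE]
  })
  list(temps = temps, comps = comps, r_min = r_min, X = idx_mats)
}

#' Fit a loading space standardization model
#'
#' Models the temperature dependence of spectra so that a spectrum
#' measured at one temperature can be transformed to appear measured at
#' another. The committed formulation is:
#'
#' 1. For each temperature `t_m` in the calibration input, assemble the
#'    matrix `X_m` of spectra with a common row ordering
#'    (composition-major, replicate-minor; replicate counts truncated to
#'    the dataset-wide minimum per cell so rows pair across temperatures).
#' 2. Take the SVD of the reference-temperature matrix,
#'    `X_ref = U S V'`; the temperature-independent composition scores
#'    are `T_ref = U_K S_K`. Factor signs are fixed by making each
#'    loading vector's largest-magnitude element positive, and factors
#'    are ordered by singular value.
#' 3. For every temperature, regress `X_m` on the reference scores:
#'    `P_m = X_m' T_ref (T_ref' T_ref)^{-1}`, a p x K loading matrix.
#' 4. Entrywise, fit each loading trajectory `p_jk` as a second-order
#'    polynomial in the standardized temperature
#'    `(t - mean(temps)) / sd(temps)` by ordinary least squares.
#'
#' On noise-free data that are exactly rank-K with loadings exactly
#' quadratic in temperature (the generator's `"linearized"` mode), the
#' resulting transform is exact to numerical precision.
#'
#' @param dataset A [spectral_dataset()] in which every included
#'   composition is measured at every temperature (at least 3 distinct
#'   temperatures, so the quadratic is identifiable).
#' @param k Number of factors (see [select_n_components()]); 2 for
#'   one-solute/one-solvent structure.
#' @param t_ref Reference temperature for the SVD; must be one of the
#'   dataset temperatures. Defaults to `t_target`.
#' @param t_target Default target temperature for [apply_lss()] /
#'   [predict.lss()]; conventionally the lowest temperature at which all
#'   concentrations were measured (50 degC in the bundled design).
#' @return An object of class `lss` with elements `k`, `temps_used`,
#'   `t_ref`, `t_target`, `ref_scores`, `coeffs` (p x K x 3 array of
#'   `(a0, a1, a2)`), `temp_standardization`, `axis`, `unit`,
#'   `diagnostics` (a [factor_diagnostics()]), `fitted_loadings`
#'   (p x K x M array of step-3 loadings, for diagnostics) and
#'   `compositions`.
#' @seealso [apply_lss()], [apply_lss_dataset()], [loading_matrix_at()]
#' @export
lss <- function(dataset, k = 2L, t_ref = NULL, t_target = 50) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (is.null(t_ref)) t_ref <- t_target
  st <- lss_stack(dataset)
  M <- length(st$temps)
  if (M < 3L) {
    stop("identifiability error: need at least 3 distinct temperatures",
         call. = FALSE)
  }
  m_ref <- match(TRUE, abs(st$temps - t_ref) < 1e-9)
  if (is.na(m_ref)) {
    stop(sprintf("t_ref = %g degC is not a dataset temperature", t_ref),
         call. = FALSE)
  }
  X_ref <- st$X[[m_ref]]
  if (k > min(dim(X_ref))) {
    stop("rank error: k exceeds the reference matrix dimensions",
         call. = FALSE)
  }
  sv <- svd(X_ref)
  # sign convention: largest-magnitude element of each loading positive
  for (j in seq_len(ncol(sv$v))) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  if (sv$d[k] <= max(dim(X_ref)) * .Machine$double.eps * sv$d[1]) {
    stop("rank error: reference scores are rank deficient at the requested k",
         call. = FALSE)
  }
  ref_scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  gram_inv <- solve(crossprod(ref_scores))
  p <- ncol(X_ref)
  loadings <- array(NA_real_, c(p, k, M))
  for (m in seq_len(M)) {
    loadings[, , m] <- crossprod(st$X[[m]], ref_scores) %*% gram_inv
  }
  ts_mean <- mean(st$temps)
  ts_sd <- stats::sd(st$temps)
  tt <- (st$temps - ts_mean) / ts_sd
  Tm <- cbind(1, tt, tt^2)
  # solve all p*K quadratic fits at once
  L <- t(apply(loadings, 3L, identity))      # M x (p*k), vec column-major
  beta <- solve(crossprod(Tm), crossprod(Tm, L))  # 3 x (p*k)
  coeffs <- array(t(beta), c(p, k, 3L))
  structure(list(k = k, temps_used = st$temps, t_ref = t_ref,
                 t_target = t_target, ref_scores = ref_scores,
                 coeffs = coeffs,
                 temp_standardization = c(mean = ts_mean, sd = ts_sd),
                 axis = dataset$axis, unit = dataset$unit,
                 diagnostics = factor_diagnostics(sv$d),
                 fitted_loadings = loadings,
                 compositions = st$comps,
                 n_replicates_used = st$r_min),
            class = "lss")
}

#' @export
print.lss <- function(x, ...) {
  cat(sprintf("<lss> %d factor(s) on %d axis points (%s)\n", x$k,
              length(x$axis$values), x$unit))
  cat(sprintf("  fitted at %d temperatures (%g to %g degC), t_ref = %g, t_target = %g\n",
              length(x$temps_used), min(x$temps_used), max(x$temps_used),
              x$t_ref, x$t_target))
  cat(sprintf("  variance explained by %d factor(s): %.4f%%\n", x$k,
              100 * x$diagnostics$variance_explained[x$k]))
  invisible(x)
}

#' @export
coef.lss <- function(object, ...) object$coeffs

#' Loading matrix at a temperature
#'
#' Evaluates the fitted quadratic loading polynomials entrywise at one
#' temperature (standardized internally). Extrapolation outside the
#' fitted temperature range is allowed but flagged with a warning.
#'
#' @param model An [lss()] model.
#' @param temperature Temperature in degrees Celsius.
#' @return Loading matrix, `p x K`.
#' @export
loading_matrix_at <- function(model, temperature) {
  rng <- range(model$temps_used)
  if (temperature < rng[1] - 1e-9 || temperature > rng[2] + 1e-9) {
    warning(sprintf(
      "extrapolating loadings to %g degC outside the fitted range [%g, %g]",
      temperature, rng[1], rng[2]), call. = FALSE)
  }
  tt <- (temperature - model$temp_standardization[["mean"]]) /
    model$temp_standardization[["sd"]]
  model$coeffs[, , 1L] + model$coeffs[, , 2L] * tt +
    model$coeffs[, , 3L] * tt^2
}

#' Transform one spectrum between temperatures
#'
#' Projects the spectrum onto the loading space at its measured
#' temperature to obtain temperature-independent composition scores,
#' reconstructs with the loadings at the target temperature, and carries
#' the out-of-space residual over unchanged:
#' `s = x P_m (P_m' P_m)^{-1}`, `e = x - s P_m'`,
#' `x_out = s P_t' + e`. When `measured_t == target_t` the output equals
#' the input exactly.
#'
#' @param model An [lss()] model.
#' @param spectrum Numeric vector of length `p`, in the unit the model
#'   was fitted on.
#' @param measured_t Temperature at which the spectrum was measured, degC.
#' @param target_t Temperature to standardize to; defaults to the model's
#'   `t_target`.
#' @param keep_residual Carry the out-of-space residual into the output
#'   (default `TRUE`); `FALSE` returns the pure K-factor reconstruction.
#' @return The transformed intensity vector.
#' @export
apply_lss <- function(model, spectrum, measured_t,
                      target_t = model$t_target, keep_residual = TRUE) {
  spectrum <- as.numeric(spectrum)
  p <- dim(model$coeffs)[1]
  if (length(spectrum) != p) {
    stop(sprintf("spectrum has %d points but model expects %d",
                 length(spectrum), p), call. = FALSE)
  }
  if (isTRUE(measured_t == target_t) && keep_residual) {
    return(spectrum)
  }
  P_m <- loading_matrix_at(model, measured_t)
  G <- crossprod(P_m)
  if (kappa(G, exact = TRUE) > 1e12) {
    stop(sprintf("conditioning error: loading matrix at %g degC is near singular",
                 measured_t), call. = FALSE)
  }
  s <- solve(G, crossprod(P_m, spectrum))
  recon <- drop(P_m %*% s)
  out <- drop(loading_matrix_at(model, target_t) %*% s)
  if (keep_residual) out <- out + (spectrum - recon)
  out
}

#' Transform every spectrum of a dataset to one temperature
#'
#' Vectorized [apply_lss()] using each spectrum's own metadata
#' temperature; metadata is unchanged. Loading matrices are computed once
#' per distinct temperature.
#'
#' @param model An [lss()] model.
#' @param dataset A [spectral_dataset()] on the model's axis and unit.
#' @param target_t Target temperature, degC; defaults to the model's
#'   `t_target`.
#' @param keep_residual See [apply_lss()].
#' @return A [spectral_dataset()] of standardized spectra.
#' @export
apply_lss_dataset <- function(model, dataset, target_t = model$t_target,
                              keep_residual = TRUE) {
  if (!identical(dataset$unit, model$unit)) {
    stop(sprintf("pipeline error: dataset unit '%s' does not match model unit '%s'",
                 dataset$unit, model$unit), call. = FALSE)
  }
  if (length(dataset$axis$values) != dim(model$coeffs)[1] ||
      max(abs(dataset$axis$values - model$axis$values)) > 1e-9) {
    stop("pipeline error: dataset axis does not match the model axis",
         call. = FALSE)
  }
  X <- dataset$intensities
  if (nrow(X) == 0L) return(dataset)
  P_t <- loading_matrix_at(model, target_t)
  out <- X
  for (tm in unique(dataset$meta$temperature)) {
    rows <- which(dataset$meta$temperature == tm)
    if (isTRUE(tm == target_t) && keep_residual) next
    P_m <- loading_matrix_at(model, tm)
    G <- crossprod(P_m)
    if (kappa(G, exact = TRUE) > 1e12) {
      stop(sprintf("conditioning error: loading matrix at %g degC is near singular",
                   tm), call. = FALSE)
    }
    S <- t(solve(G, crossprod(P_m, t(X[rows, , drop = FALSE]))))  # n_t x K
    recon_t <- S %*% t(P_t)
    if (keep_residual) {
      recon_m <- S %*% t(P_m)
      out[rows, ] <- recon_t + (X[rows, , drop = FALSE] - recon_m)
    } else {
      out[rows, ] <- recon_t
    }
  }
  structure(list(axis = dataset$axis, intensities = out,
                 meta = dataset$meta, unit = dataset$unit),
            class = "spectral_dataset")
}

#' @export
predict.lss <- function(object, newdata, target_t = object$t_target, ...) {
  apply_lss_dataset(object, newdata, target_t = target_t)
}

#' Serialize / restore an LSS model as JSON
#'
#' Arrays are written row-major with explicit dimensions, so the file is
#' portable across tools.
#'
#' @param model An [lss()] model.
#' @param path File path.
#' @return `write_lss_json`: invisibly, `path`. `read_lss_json`: the
#'   restored `lss` model (without `fitted_loadings`, which are a fitting
#'   diagnostic only).
#' @export
write_lss_json <- function(model, path) {
  obj <- list(
    class = "lss", k = model$k, temps_used = model$temps_used,
    t_ref = model$t_ref, t_target = model$t_target,
    ref_scores = list(dim = dim(model$ref_scores),
                      data = as.numeric(t(model$ref_scores))),
    coeffs = list(dim = dim(model$coeffs),
                  data = as.numeric(aperm(model$coeffs, c(3, 2, 1)))),
    temp_standardization = as.list(model$temp_standardization),
    axis = list(kind = model$axis$kind, values = model$axis$values),
    unit = model$unit,
    singular_values = model$diagnostics$singular_values,
    compositions = model$compositions,
    n_replicates_used = model$n_replicates_used)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lss_json
#' @export
read_lss_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$class, "lss")) {
    stop("not an lss model file", call. = FALSE)
  }
  rs_dim <- as.integer(obj$ref_scores$dim)
  coeff_dim <- as.integer(obj$coeffs$dim)
  structure(list(
    k = as.integer(obj$k), temps_used = as.numeric(obj$temps_used),
    t_ref = obj$t_ref, t_target = obj$t_target,
    ref_scores = matrix(obj$ref_scores$data, rs_dim[1], rs_dim[2],
                        byrow = TRUE),
    coeffs = aperm(array(obj$coeffs$data, rev(coeff_dim)), c(3, 2, 1)),
    temp_standardization = c(mean = obj$temp_standardization$mean,
                             sd = obj$temp_standardization$sd),
    axis = spectral_axis(obj$axis$kind, obj$axis$values),
    unit = obj$unit,
    diagnostics = factor_diagnostics(obj$singular_values),
    fitted_loadings = NULL,
    compositions = as.numeric(obj$compositions),
    n_replicates_used = as.integer(obj$n_replicates_used)),
    class = "lss")
}
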