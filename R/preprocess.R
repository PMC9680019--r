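#' Preprocessing specification
#'
#' The per-technique preprocessing recipe applied before regression: crop
#' to a working spectral range, optionally take a Savitzky-Golay first
#' derivative (second-order local polynomial), and mean-center inside the
#' regression step. The mid-IR pipeline conventionally uses a 7-point
#' window on a 1831-709 cm-1 range; the UV pipeline a 15-point window (in
#' its derivative variant) on 218-285 nm.
#'
#' @param range_lo,range_hi Closed crop interval in axis units,
#'   `range_lo < range_hi`.
#' @param sg_window Odd integer window >= 5 for the first-derivative
#'   filter, or `NULL` for no derivative.
#' @param center Logical; mean-center spectra in the regression step
#'   (always recommended and on by default).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(range_lo, range_hi, sg_window = NULL,
                            center = TRUE) {
  stopifnot(is.numeric(range_lo), is.numeric(range_hi), range_lo < range_hi)
  if (!is.null(sg_window)) {
    sg_window <- as.integer(sg_window)
    if (sg_window < 5L || sg_window %% 2L == 0L) {
      stop("sg_window must be an odd integer >= 5", call. = FALSE)
    }
  }
  structure(list(range_lo = range_lo, range_hi = range_hi,
                 sg_window = sg_window, sg_polyorder = 2L,
                 center = isTRUE(center)),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat(sprintf("<preprocess_spec> crop [%g, %g]%s%s\n", x$range_lo,
              x$range_hi,
              if (is.null(x$sg_window)) ""
              else sprintf(", SG first derivative (%d-point, order 2)",
                           x$sg_window),
              if (x$center) ", mean centering" else ""))
  invisible(x)
}

#' Crop a dataset to an axis range
#'
#' Retains axis points `v` with `lo <= v <= hi` (closed interval);
#' metadata and units are unchanged.
#'
#' @param dataset A [spectral_dataset()].
#' @param lo,hi Range bounds in axis units.
#' @return The cropped [spectral_dataset()].
#' @export
crop_range <- function(dataset, lo, hi) {
  keep <- dataset$axis$values >= lo & dataset$axis$values <= hi
  if (!any(keep)) {
    stop(sprintf("range error: no axis points in [%g, %g]", lo, hi),
         call. = FALSE)
  }
  structure(list(axis = spectral_axis(dataset$axis$kind,
                                      dataset$axis$values[keep]),
                 intensities = dataset$intensities[, keep, drop = FALSE],
                 meta = dataset$meta, unit = dataset$unit),
            class = "spectral_dataset")
}

# Savitzky-Golay first-derivative convolution weights for a local
# second-order polynomial fit over `window` points at unit spacing
sg_deriv_weights <- function(window, polyorder = 2L) {
  half <- (window - 1L) / 2L
  offs <- seq(-half, half)
  A <- outer(offs, 0:polyorder, `^`)
  # row of the pseudoinverse picking the linear coefficient of the fit
  solve(crossprod(A), t(A))[2L, ]
}

#' Savitzky-Golay first derivative
#'
#' At each interior axis point, fits a second-order polynomial by least
#' squares over a sliding window and reports its first derivative at the
#' window center, divided by the axis spacing (units: absorbance per axis
#' unit, so results are invariant to grid resampling). The `(window-1)/2`
#' edge points on each side, where the window does not fit, are dropped
#' and the axis cropped to match. Requires a uniformly spaced axis
#' (relative tolerance 1e-6).
#'
#' The filter is linear, annihilates constant spectra, maps straight
#' lines to their exact slope, and is exact for quadratics (which lie in
#' the local model space).
#'
#' @param dataset A [spectral_dataset()] with `unit = "absorbance"`.
#' @param window Odd integer >= 5, the filter width in points (7 is
#'   conventional for mid-IR at 4 cm-1 spacing, 15 for UV at 1 nm).
#' @return A [spectral_dataset()] with `unit = "absorbance_deriv"` and
#'   `window - 1` fewer axis points.
#' @export
sg_first_derivative <- function(dataset, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 5L) {
    stop("parameter error: window must be an odd integer >= 5",
         call. = FALSE)
  }
  if (!axis_is_uniform(dataset$axis)) {
    stop("precondition error: axis must be uniformly spaced for derivative filtering",
         call. = FALSE)
  }
  p <- length(dataset$axis$values)
  if (window > p) {
    stop("parameter error: window exceeds axis length", call. = FALSE)
  }
  h <- axis_spacing(dataset$axis)
  w <- sg_deriv_weights(window)
  half <- (window - 1L) / 2L
  idx <- (half + 1L):(p - half)
  X <- dataset$intensities
  D <- matrix(0, nrow(X), length(idx))
  for (k in seq_len(window)) {
    D <- D + w[k] * X[, idx + k - 1L - half, drop = FALSE]
  }
  D <- D / h
  structure(list(axis = spectral_axis(dataset$axis$kind,
                                      dataset$axis$values[idx]),
                 intensities = D, meta = dataset$meta,
                 unit = "absorbance_deriv"),
            class = "spectral_dataset")
}

#' Apply a preprocessing specification
#'
#' Crop, then (if configured) Savitzky-Golay first derivative. Mean
#' centering is not applied here: it belongs to the regression step,
#' where the calibration-set column means are stored for reuse on new
#' spectra.
#'
#' @param dataset A [spectral_dataset()].
#' @param spec A [preprocess_spec()].
#' @return The preprocessed [spectral_dataset()].
#' @export
apply_preprocess <- function(dataset, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  d <- crop_range(dataset, spec$range_lo, spec$range_hi)
  if (!is.null(spec$sg_window)) {
    d <- sg_first_derivative(d, spec$sg_window)
  }
  d
}

#' Fit and apply mean centering
#'
#' `fit_center` computes calibration-set column means; `apply_center`
#' subtracts a stored mean vector from each row. New spectra must be
#' centered with the calibration mean, never their own.
#'
#' @param X Numeric matrix with >= 1 row.
#' @return `fit_center`: the column-mean vector. `apply_center`: the
#'   centered matrix.
#' @export
fit_center <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("need at least one row", call. = FALSE)
  colMeans(X)
}

#' @rdname fit_center
#' @param center Mean vector as returned by `fit_center`.
#' @export
apply_center <- function(X, center) {
  X <- as.matrix(X)
  if (ncol(X) != length(center)) {
    stop(sprintf("shape error: %d columns vs %d mean entries", ncol(X),
                 length(center)), call. = FALSE)
  }
  sweep(X, 2L, center, `-`)
}
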