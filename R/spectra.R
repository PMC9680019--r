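#' Spectral axis
#'
#' An axis is the common abscissa shared by every spectrum in a dataset:
#' either a wavelength grid in nm (UV/vis) or a wavenumber grid in cm-1
#' (mid-IR). Values are stored strictly increasing regardless of the
#' instrument's plotting convention, so that downstream code never has to
#' reason about direction.
#'
#' @param kind One of `"wavelength_nm"` or `"wavenumber_cm-1"`.
#' @param values Numeric vector of strictly increasing, finite axis values.
#' @return An object of class `spectral_axis`: a list with elements `kind`
#'   and `values`.
#' @examples
#' ax <- spectral_axis("wavelength_nm", 218:285)
#' length(ax$values)
#' @export
spectral_axis <- function(kind = c("wavelength_nm", "wavenumber_cm-1"),
                          values) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("axis values must be a non-empty vector of finite numbers",
         call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("axis values must be strictly increasing", call. = FALSE)
  }
  structure(list(kind = kind, values = values), class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %s: %d points, %g to %g\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

axis_spacing <- function(axis) {
  d <- diff(axis$values)
  if (length(d) == 0L) return(NA_real_)
  mean(d)
}

axis_is_uniform <- function(axis, rel_tol = 1e-6) {
  d <- diff(axis$values)
  if (length(d) < 2L) return(TRUE)
  max(abs(d - mean(d))) <= rel_tol * abs(mean(d))
}

# canonical metadata column order of the CSV dialect
.meta_cols <- c("sample_id", "concentration", "temperature", "time",
                "replicate", "role")
.valid_roles <- c("calibration", "validation", "slurry")

empty_meta <- function() {
  data.frame(sample_id = character(), concentration = numeric(),
             temperature = numeric(), time = numeric(),
             replicate = integer(), role = character(),
             stringsAsFactors = FALSE)
}

#' Spectrum metadata table
#'
#' Build the per-spectrum metadata data frame used by
#' [spectral_dataset()]. Concentration is in g solute per 100 g solvent and
#' may be `NA` when unknown (e.g. a slurry supernatant after nucleation);
#' an unknown concentration is never encoded as 0.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param concentration Numeric, g/100 g solvent; `NA` = unknown.
#' @param temperature Numeric, degrees Celsius.
#' @param time Numeric, seconds since experiment start (>= 0).
#' @param replicate Integer replicate index (>= 1).
#' @param role One of `"calibration"`, `"validation"`, `"slurry"` per row.
#' @return A data frame with the six canonical columns.
#' @export
spectrum_meta <- function(sample_id, concentration, temperature, time = 0,
                          replicate = 1L, role = "calibration") {
  n <- max(length(sample_id), length(concentration), length(temperature),
           length(time), length(replicate), length(role))
  data.frame(sample_id = rep_len(as.character(sample_id), n),
             concentration = rep_len(as.numeric(concentration), n),
             temperature = rep_len(as.numeric(temperature), n),
             time = rep_len(as.numeric(time), n),
             replicate = rep_len(as.integer(replicate), n),
             role = rep_len(as.character(role), n),
             stringsAsFactors = FALSE)
}

#' Spectral dataset
#'
#' The universal currency of the pipeline: a matrix of spectra (rows) on a
#' shared axis (columns) plus one metadata row per spectrum. The `unit` tag
#' records whether intensities are raw absorbance or a first derivative per
#' axis unit, so that derivative and raw spectra are never mixed in one
#' model.
#'
#' @param axis A [spectral_axis()].
#' @param intensities Numeric matrix, `n_spectra x length(axis$values)`,
#'   all finite.
#' @param meta Data frame as returned by [spectrum_meta()], one row per
#'   spectrum.
#' @param unit `"absorbance"` or `"absorbance_deriv"` (first derivative per
#'   axis unit).
#' @return An object of class `spectral_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [validate_dataset()]
#' @export
spectral_dataset <- function(axis, intensities, meta,
                             unit = c("absorbance", "absorbance_deriv")) {
  unit <- match.arg(unit)
  stopifnot(inherits(axis, "spectral_axis"))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) == 0L) {
    intensities <- matrix(numeric(), 0L, length(axis$values))
  }
  if (ncol(intensities) != length(axis$values)) {
    stop(sprintf("intensity matrix has %d columns but axis has %d points",
                 ncol(intensities), length(axis$values)), call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(intensities)) {
    stop(sprintf("metadata has %d rows but intensity matrix has %d",
                 nrow(meta), nrow(intensities)), call. = FALSE)
  }
  if (!all(.meta_cols %in% names(meta))) {
    stop("metadata must contain columns: ",
         paste(.meta_cols, collapse = ", "), call. = FALSE)
  }
  meta <- meta[, .meta_cols, drop = FALSE]
  rownames(meta) <- NULL
  dimnames(intensities) <- NULL
  obj <- structure(list(axis = axis, intensities = intensities,
                        meta = meta, unit = unit),
                   class = "spectral_dataset")
  v <- validate_dataset(obj)
  if (length(v)) {
    stop("invalid spectral dataset:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  obj
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points (%s, %s)\n",
              nrow(x$intensities), length(x$axis$values), x$axis$kind,
              x$unit))
  if (nrow(x$meta)) {
    cat(sprintf("  roles: %s\n",
                paste(sprintf("%s=%d", names(table(x$meta$role)),
                              as.integer(table(x$meta$role))),
                      collapse = ", ")))
    tr <- range(x$meta$temperature)
    cat(sprintf("  temperature %g to %g degC; concentration %s g/100 g\n",
                tr[1], tr[2],
                if (all(is.na(x$meta$concentration))) "unknown"
                else paste(signif(range(x$meta$concentration, na.rm = TRUE), 4),
                           collapse = " to ")))
  }
  invisible(x)
}

#' Number of spectra in a dataset
#' @param dataset A [spectral_dataset()].
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(dataset) nrow(dataset$intensities)

#' Subset a spectral dataset by spectrum index
#'
#' @param dataset A [spectral_dataset()].
#' @param i Row (spectrum) indices, any form accepted by matrix indexing.
#' @return A new `spectral_dataset` containing the selected spectra.
#' @export
subset_spectra <- function(dataset, i) {
  structure(list(axis = dataset$axis,
                 intensities = dataset$intensities[i, , drop = FALSE],
                 meta = {
                   m <- dataset$meta[i, , drop = FALSE]
                   rownames(m) <- NULL
                   m
                 },
                 unit = dataset$unit),
            class = "spectral_dataset")
}

#' Validate a spectral dataset
#'
#' Checks every dataset invariant and reports violations rather than
#' throwing: axis monotone, matrix/axis dimension agreement, finite
#' intensities (naming row and column), metadata shape, valid roles,
#' temperature within -50 to 150 degC, non-negative time and concentration,
#' replicate >= 1, and uniqueness of (sample_id, replicate, time).
#'
#' @param dataset A `spectral_dataset` (or a structurally similar list).
#' @return Character vector of human-readable violation descriptions;
#'   empty if the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  v <- character()
  ax <- dataset$axis
  X <- dataset$intensities
  meta <- dataset$meta
  if (any(diff(ax$values) <= 0)) {
    v <- c(v, "axis values are not strictly increasing")
  }
  if (ncol(X) != length(ax$values)) {
    v <- c(v, sprintf("intensity matrix has %d columns but axis has %d points",
                      ncol(X), length(ax$values)))
  }
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    for (r in seq_len(min(nrow(bad), 10L))) {
      v <- c(v, sprintf("non-finite intensity at spectrum %d, column %d",
                        bad[r, 1], bad[r, 2]))
    }
  }
  if (nrow(meta) != nrow(X)) {
    v <- c(v, sprintf("metadata has %d rows but intensity matrix has %d",
                      nrow(meta), nrow(X)))
  }
  if (nrow(meta)) {
    bad_role <- which(!meta$role %in% .valid_roles)
    for (r in bad_role) {
      v <- c(v, sprintf("spectrum %d has invalid role '%s'", r, meta$role[r]))
    }
    bad_t <- which(meta$temperature < -50 | meta$temperature > 150)
    for (r in bad_t) {
      v <- c(v, sprintf("spectrum %d temperature %g degC outside [-50, 150]",
                        r, meta$temperature[r]))
    }
    bad_c <- which(!is.na(meta$concentration) & meta$concentration < 0)
    for (r in bad_c) {
      v <- c(v, sprintf("spectrum %d has negative concentration", r))
    }
    bad_time <- which(meta$time < 0)
    for (r in bad_time) {
      v <- c(v, sprintf("spectrum %d has negative time", r))
    }
    bad_rep <- which(meta$replicate < 1)
    for (r in bad_rep) {
      v <- c(v, sprintf("spectrum %d has replicate index < 1", r))
    }
    key <- paste(meta$sample_id, meta$replicate, meta$time, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      for (r in which(dup)) {
        v <- c(v, sprintf(
          "spectrum %d duplicates (sample_id, replicate, time) = (%s, %d, %g)",
          r, meta$sample_id[r], meta$replicate[r], meta$time[r]))
      }
    }
  }
  v
}

#' Write a spectral dataset to the package CSV dialect
#'
#' Line 1 is a comment `# axis_kind=<kind> unit=<unit>`; line 2 is the
#' header `sample_id,concentration,temperature,time,replicate,role`
#' followed by the axis values in increasing order; each subsequent line is
#' one spectrum. Numbers are serialized with 17 significant digits so that
#' write-then-read is the exact identity; an empty concentration field
#' encodes an unknown concentration.
#'
#' @param dataset A valid [spectral_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  v <- validate_dataset(dataset)
  if (length(v)) {
    stop("refusing to write invalid dataset:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# axis_kind=%s unit=%s", dataset$axis$kind,
                     dataset$unit), con)
  writeLines(paste(c(.meta_cols, num(dataset$axis$values)), collapse = ","),
             con)
  meta <- dataset$meta
  if (nrow(meta)) {
    if (any(grepl(",", meta$sample_id, fixed = TRUE))) {
      stop("sample_id must not contain commas", call. = FALSE)
    }
    rows <- vapply(seq_len(nrow(meta)), function(i) {
      paste(c(meta$sample_id[i], num(meta$concentration[i]),
              num(meta$temperature[i]), num(meta$time[i]),
              sprintf("%d", meta$replicate[i]), meta$role[i],
              num(dataset$intensities[i, ])), collapse = ",")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a spectral dataset from the package CSV dialect
#'
#' Inverse of [write_dataset()]. Malformed headers and ragged rows raise
#' format errors; a non-monotone axis raises a validation error. A file
#' read successfully always yields a dataset for which
#' [validate_dataset()] returns no violations.
#'
#' @param path Path to a CSV file in the dialect written by
#'   [write_dataset()].
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    stop("malformed file: expected a comment line and a header line",
         call. = FALSE)
  }
  m <- regmatches(lines[1],
                  regexec("^#\\s*axis_kind=(\\S+)(?:\\s+unit=(\\S+))?\\s*$",
                          lines[1]))[[1]]
  if (length(m) == 0L) {
    stop("malformed header: line 1 must be '# axis_kind=<kind>'",
         call. = FALSE)
  }
  kind <- m[2]
  unit <- if (is.na(m[3]) || m[3] == "") "absorbance" else m[3]
  if (!kind %in% c("wavelength_nm", "wavenumber_cm-1")) {
    stop(sprintf("malformed header: unknown axis_kind '%s'", kind),
         call. = FALSE)
  }
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(header) < length(.meta_cols) ||
      !identical(header[seq_along(.meta_cols)], .meta_cols)) {
    stop("malformed header: expected columns ",
         paste(.meta_cols, collapse = ","), ",<axis values...>",
         call. = FALSE)
  }
  axis_vals <- suppressWarnings(
    as.numeric(header[-seq_along(.meta_cols)]))
  if (any(is.na(axis_vals))) {
    stop("malformed header: non-numeric axis value", call. = FALSE)
  }
  if (length(axis_vals) < 1L) {
    stop("malformed header: no axis columns", call. = FALSE)
  }
  if (any(diff(axis_vals) <= 0)) {
    stop("validation error: axis values must be strictly increasing",
         call. = FALSE)
  }
  axis <- spectral_axis(kind, axis_vals)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  p <- length(axis_vals)
  ncols <- length(.meta_cols) + p
  n <- length(body)
  X <- matrix(NA_real_, n, p)
  meta <- empty_meta()
  if (n) {
    parts <- strsplit(body, ",", fixed = TRUE)
    lens <- lengths(parts)
    # a trailing empty field is dropped by strsplit; only possible for the
    # concentration column via a final comma, which cannot be last here
    if (any(lens != ncols)) {
      stop(sprintf("format error: row %d has %d fields, expected %d",
                   which(lens != ncols)[1], lens[lens != ncols][1], ncols),
           call. = FALSE)
    }
    tab <- matrix(unlist(parts), nrow = n, byrow = TRUE)
    numfield <- function(j, what) {
      x <- tab[, j]
      out <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(out) & nzchar(x))
      if (length(bad)) {
        stop(sprintf("format error: row %d has non-numeric %s '%s'",
                     bad[1], what, x[bad[1]]), call. = FALSE)
      }
      out
    }
    conc <- numfield(2L, "concentration")
    meta <- data.frame(sample_id = tab[, 1L],
                       concentration = conc,
                       temperature = numfield(3L, "temperature"),
                       time = numfield(4L, "time"),
                       replicate = as.integer(numfield(5L, "replicate")),
                       role = tab[, 6L],
                       stringsAsFactors = FALSE)
    for (j in seq_len(p)) {
      X[, j] <- numfield(length(.meta_cols) + j, "intensity")
    }
  }
  spectral_dataset(axis, X, meta, unit = unit)
}
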