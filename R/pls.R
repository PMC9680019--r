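#' Fit a single-response PLS regression (NIPALS)
#'
#' Partial least squares regression of one response (solute
#' concentration) on spectra, by the NIPALS recursion for a univariate y:
#' center `X` and `y`; then for each latent variable
#' `w = X'y / ||X'y||`, `t = X w`, `p = X't / t't`, `q = y't / t't`,
#' deflate `X <- X - t p'` and `y <- y - q t`. The regression vector is
#' assembled as `b = W (P'W)^{-1} q`, so prediction is
#' `(X - x_mean) b + y_mean`. Score vectors are mutually orthogonal, and
#' at `n_lv = rank(X_centered)` the fit reproduces the minimum-norm
#' least-squares solution.
#'
#' @param x Calibration spectra: a numeric matrix (rows = spectra) or a
#'   [spectral_dataset()] (in which case `y` defaults to the metadata
#'   concentrations).
#' @param y Response vector, g/100 g solvent.
#' @param n_lv Number of latent variables, `<= min(nrow - 1, ncol)`.
#' @return An object of class `pls1` with elements `n_lv`, `x_mean`,
#'   `y_mean`, `weights` (p x A), `x_loadings` (p x A), `y_loadings`
#'   (length A), `coef_path` (p x A matrix whose column k is the
#'   regression vector using k latent variables), `b` (the `n_lv`-LV
#'   regression vector), `scores`, `fitted.values`, `residuals` and
#'   `unit` (the preprocessing tag of the training data).
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(12, sd = 0.01)
#' fit <- pls1(X, y, n_lv = 2)
#' summary(fit)
#' @export
pls1 <- function(x, y = NULL, n_lv) {
  unit <- NA_character_
  if (inherits(x, "spectral_dataset")) {
    if (is.null(y)) y <- x$meta$concentration
    unit <- x$unit
    x <- x$intensities
  }
  X <- as.matrix(x)
  y <- as.numeric(y)
  n_lv <- as.integer(n_lv)
  if (nrow(X) != length(y)) {
    stop("shape error: nrow(x) must equal length(y)", call. = FALSE)
  }
  if (nrow(X) < 2L) stop("need at least 2 calibration rows", call. = FALSE)
  if (anyNA(y)) stop("y must not contain missing values", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("degenerate-target error: y has zero variance", call. = FALSE)
  }
  if (n_lv < 1L || n_lv > min(nrow(X) - 1L, ncol(X))) {
    stop(sprintf("rank error: n_lv must be in [1, %d]",
                 min(nrow(X) - 1L, ncol(X))), call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean, `-`)
  yc <- y - y_mean
  p <- ncol(X)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, nrow(X), n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      stop(sprintf("rank error: no covariance left at latent variable %d", a),
           call. = FALSE)
    }
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps^2) {
      stop(sprintf("rank error: degenerate score at latent variable %d", a),
           call. = FALSE)
    }
    p_ <- crossprod(Xc, t_) / tt
    q[a] <- sum(yc * t_) / tt
    Xc <- Xc - t_ %*% t(p_)
    yc <- yc - q[a] * t_
    W[, a] <- w
    P[, a] <- p_
    Tm[, a] <- t_
  }
  # R = W (P'W)^{-1}; b using k LVs is R[, 1:k] %*% q[1:k]
  R <- W %*% solve(t(P) %*% W)
  coef_path <- sapply(seq_len(n_lv), function(k) {
    R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)]
  })
  coef_path <- matrix(coef_path, p, n_lv)
  b <- coef_path[, n_lv]
  fitted <- drop(sweep(X, 2L, x_mean, `-`) %*% b) + y_mean
  structure(list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, coef_path = coef_path, b = b,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, unit = unit),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d latent variable(s), %d wavelengths/wavenumbers\n",
              x$n_lv, length(x$x_mean)))
  m <- regression_metrics(x$y, x$fitted.values)
  cat(sprintf("  RMSEC = %.4g g/100 g, R2 = %.6f\n", m$rmse, m$r2))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  m <- regression_metrics(object$y, object$fitted.values)
  out <- list(n_lv = object$n_lv, n = length(object$y),
              p = length(object$x_mean), rmsec = m$rmse, r2 = m$r2)
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, ...) {
  cat(sprintf("Single-response PLS fit: %d spectra x %d points, %d LVs\n",
              x$n, x$p, x$n_lv))
  cat(sprintf("  calibration RMSE %.4g g/100 g solvent, R2 %.6f\n",
              x$rmsec, x$r2))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, n_lv = object$n_lv, ...) {
  object$coef_path[, n_lv]
}

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' Predict concentrations from spectra
#'
#' `(X - x_mean) b + y_mean`, using the stored calibration means (new
#' spectra are never centered with their own mean).
#'
#' @param object A [pls1()] model.
#' @param newdata Numeric matrix, a single spectrum vector, or a
#'   [spectral_dataset()] whose unit matches the training data.
#' @param n_lv Number of latent variables to use (defaults to the fitted
#'   number; any value up to it is valid).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations, g/100 g solvent.
#' @export
predict.pls1 <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (inherits(newdata, "spectral_dataset")) {
    if (!is.na(object$unit) && !identical(newdata$unit, object$unit)) {
      stop(sprintf("pipeline error: dataset unit '%s' does not match model unit '%s'",
                   newdata$unit, object$unit), call. = FALSE)
    }
    newdata <- newdata$intensities
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop(sprintf("shape error: %d columns vs %d in the calibration data",
                 ncol(newdata), length(object$x_mean)), call. = FALSE)
  }
  b <- object$coef_path[, n_lv]
  drop(sweep(newdata, 2L, object$x_mean, `-`) %*% b) + object$y_mean
}

#' Cross-validation configuration
#'
#' Random-subset cross-validation: in each iteration the grouping units
#' are randomly partitioned into `n_splits` folds and every fold is held
#' out once; squared errors are pooled over all folds and iterations.
#' Grouping `"by_sample"` moves a (concentration, temperature) sample
#' with all its replicate spectra as one unit, so replicates of a
#' held-out sample never leak into training.
#'
#' @param n_splits Number of folds per iteration (>= 2).
#' @param n_iterations Number of random repartitions.
#' @param max_lv Largest number of latent variables scanned; `NA` means
#'   `min(15, n_train - 1, p)` decided at run time.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param grouping `"by_sample"` or `"by_spectrum"`.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_splits = 3L, n_iterations = 20L, max_lv = NA,
                      seed = 1L, grouping = c("by_sample", "by_spectrum")) {
  grouping <- match.arg(grouping)
  stopifnot(n_splits >= 2L, n_iterations >= 1L)
  structure(list(n_splits = as.integer(n_splits),
                 n_iterations = as.integer(n_iterations),
                 max_lv = if (is.na(max_lv)) NA_integer_
                          else as.integer(max_lv),
                 seed = as.integer(seed), grouping = grouping),
            class = "cv_config")
}

#' Random-subset cross-validation for PLS
#'
#' For each of `cfg$n_iterations` iterations, randomly partitions the
#' grouping units into `cfg$n_splits` folds; each fold is held out once
#' and the model refit (including re-centering) on the remainder for
#' every latent-variable count from 1 to `max_lv`; held-out squared
#' errors are pooled across folds and iterations into
#' `RMSECV(k) = sqrt(pooled mean)`. Deterministic given `cfg$seed`.
#'
#' @param x Spectra matrix or [spectral_dataset()].
#' @param y Response vector (defaults to dataset concentrations).
#' @param meta Metadata data frame supplying `sample_id` for
#'   `grouping = "by_sample"` (defaults to the dataset's metadata).
#' @param cfg A [cv_config()].
#' @return An object of class `cv_result`: `rmsecv` (vector over
#'   1..max_lv), `r2cv`, `chosen_lv` (via [select_latent_variables()]
#'   at the default tolerance), `per_iteration` (n_iterations x max_lv
#'   matrix of per-iteration RMSECV), `folds` (n_iterations x n_units
#'   fold assignments, for leakage audits), `n_units`, `n_residuals`,
#'   and the `cfg` used.
#' @export
random_subset_cv <- function(x, y = NULL, meta = NULL, cfg = cv_config()) {
  if (inherits(x, "spectral_dataset")) {
    if (is.null(y)) y <- x$meta$concentration
    if (is.null(meta)) meta <- x$meta
    x <- x$intensities
  }
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  units <- if (cfg$grouping == "by_sample") {
    if (is.null(meta)) {
      stop("grouping by_sample requires metadata with sample_id",
           call. = FALSE)
    }
    as.character(meta$sample_id)
  } else {
    as.character(seq_len(n))
  }
  u_levels <- unique(units)
  n_units <- length(u_levels)
  if (n_units < cfg$n_splits) {
    stop(sprintf("design error: %d grouping units but %d splits requested",
                 n_units, cfg$n_splits), call. = FALSE)
  }
  n_train_min <- n - max(table(factor(units, levels = u_levels))) *
    ceiling(n_units / cfg$n_splits)
  max_lv <- if (is.na(cfg$max_lv)) {
    max(1L, min(15L, n_train_min - 1L, ncol(X)))
  } else cfg$max_lv
  sse <- numeric(max_lv)
  n_res <- 0L
  per_iter <- matrix(NA_real_, cfg$n_iterations, max_lv)
  folds <- matrix(NA_integer_, cfg$n_iterations, n_units,
                  dimnames = list(NULL, u_levels))
  ss_tot <- 0
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_iterations)) {
      perm <- sample(u_levels)
      # fold id per original unit level: assign along the permuted order
      fold_of_unit <- integer(n_units)
      fold_of_unit[match(perm, u_levels)] <-
        rep(seq_len(cfg$n_splits), length.out = n_units)
      fold <- fold_of_unit[match(units, u_levels)]
      folds[it, ] <- fold_of_unit
      it_sse <- numeric(max_lv)
      it_n <- 0L
      for (f in seq_len(cfg$n_splits)) {
        test <- which(fold == f)
        train <- which(fold != f)
        k_max <- min(max_lv, length(train) - 1L, ncol(X))
        fit <- NULL
        while (is.null(fit) && k_max >= 1L) {
          # exactly low-rank training folds cannot support deep models;
          # fall back to the deepest extractable fit
          fit <- tryCatch(pls1(X[train, , drop = FALSE], y[train],
                               n_lv = k_max),
                          error = function(e) NULL)
          if (is.null(fit)) k_max <- k_max - 1L
        }
        if (is.null(fit)) {
          stop("design error: a CV training fold admits no PLS model",
               call. = FALSE)
        }
        Xc <- sweep(X[test, , drop = FALSE], 2L, fit$x_mean, `-`)
        pred <- Xc %*% fit$coef_path + fit$y_mean   # n_test x k_max
        err2 <- (pred - y[test])^2
        add <- colSums(err2)
        if (k_max < max_lv) {
          # deeper models unavailable on this fold: carry the deepest fit
          add <- c(add, rep(add[k_max], max_lv - k_max))
        }
        it_sse <- it_sse + add
        it_n <- it_n + length(test)
        ss_tot <- ss_tot + sum((y[test] - mean(y[train]))^2)
      }
      sse <- sse + it_sse
      n_res <- n_res + it_n
      per_iter[it, ] <- sqrt(it_sse / it_n)
    }
  })
  rmsecv <- sqrt(sse / n_res)
  r2cv <- 1 - sse / ss_tot
  out <- structure(list(rmsecv = rmsecv, r2cv = r2cv,
                        chosen_lv = NA_integer_,
                        per_iteration = per_iter, folds = folds,
                        n_units = n_units,
                        n_residuals = n_res, max_lv = max_lv, cfg = cfg),
                   class = "cv_result")
  out$chosen_lv <- select_latent_variables(out)
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d splits x %d iterations over %d units\n",
              x$cfg$n_splits, x$cfg$n_iterations, x$n_units))
  cat("  RMSECV:", paste(sprintf("%.4g", x$rmsecv), collapse = " "), "\n")
  cat(sprintf("  chosen LVs: %d (RMSECV %.4g g/100 g)\n", x$chosen_lv,
              x$rmsecv[x$chosen_lv]))
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  graphics::plot(seq_along(x$rmsecv), x$rmsecv, type = "b",
                 xlab = "latent variables", ylab = "RMSECV (g/100 g)", ...)
  graphics::abline(v = x$chosen_lv, lty = 2)
  invisible(x)
}

#' Parsimonious latent-variable selection
#'
#' Returns the smallest number of latent variables whose RMSECV is within
#' `tolerance_fraction` of the minimum over the scanned range — the
#' operational form of "the minimal number of latent variables providing
#' suitable accuracy".
#'
#' @param result A `cv_result` or a numeric RMSECV vector.
#' @param tolerance_fraction Relative slack above the minimum RMSECV
#'   (default 0.10).
#' @return Integer number of latent variables.
#' @export
select_latent_variables <- function(result, tolerance_fraction = 0.10) {
  rmsecv <- if (inherits(result, "cv_result")) result$rmsecv
            else as.numeric(result)
  if (length(rmsecv) == 0L) stop("empty RMSECV vector", call. = FALSE)
  thr <- (1 + tolerance_fraction) * min(rmsecv)
  which(rmsecv <= thr)[1]
}

#' Root mean square error and coefficient of determination
#'
#' `rmse = sqrt(mean((y_true - y_pred)^2))`;
#' `r2 = 1 - SS_res / SS_tot`.
#'
#' @param y_true,y_pred Equal-length numeric vectors, length >= 2.
#' @return List with elements `rmse` and `r2`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("r2 undefined: y_true has zero variance", call. = FALSE)
  }
  ss_res <- sum((y_true - y_pred)^2)
  list(rmse = sqrt(mean((y_true - y_pred)^2)), r2 = 1 - ss_res / ss_tot)
}

#' Summary of repeated predictions of one known sample
#'
#' The validation-block statistics: RMSE of the predictions against the
#' known concentration, their mean, min and max, and the relative
#' standard deviation `rsd = 100 * sd / mean` (sample sd, n - 1) as the
#' precision metric.
#'
#' @param y_pred Predicted concentrations for replicate spectra of one
#'   sample.
#' @param y_true_scalar The sample's known concentration, g/100 g.
#' @return An object of class `prediction_summary` with fields `rmse`,
#'   `mean`, `min`, `max`, `rsd`, `n`, `truth`.
#' @export
prediction_summary <- function(y_pred, y_true_scalar) {
  y_pred <- as.numeric(y_pred)
  stopifnot(length(y_pred) >= 1L, length(y_true_scalar) == 1L)
  m <- mean(y_pred)
  if (m == 0) stop("rsd undefined: mean prediction is zero", call. = FALSE)
  s <- if (length(y_pred) > 1L) stats::sd(y_pred) else 0
  structure(list(rmse = sqrt(mean((y_pred - y_true_scalar)^2)),
                 mean = m, min = min(y_pred), max = max(y_pred),
                 rsd = 100 * s / m, n = length(y_pred),
                 truth = y_true_scalar),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat(sprintf(
    "<prediction_summary> truth %.4g: RMSE %.4g, mean %.4g [%.4g, %.4g], RSD %.2f%% (n=%d)\n",
    x$truth, x$rmse, x$mean, x$min, x$max, x$rsd, x$n))
  invisible(x)
}
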