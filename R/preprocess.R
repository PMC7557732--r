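#' Standard normal variate transform
#'
#' Centers a spectrum to zero mean and scales it to unit sample standard
#' deviation (the `n - 1` convention), removing multiplicative scatter and
#' global intensity fluctuations.
#'
#' @param x Numeric intensity vector (length >= 2, non-constant).
#' @return Transformed vector with mean 0 and sample sd 1.
#' @export
snv <- function(x) {
  if (length(x) < 2L) stop("spectrum must have length >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate spectrum: zero variance, SNV undefined", call. = FALSE)
  }
  (x - mean(x)) / s
}

snv_matrix <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  if (any(s == 0)) {
    stop("degenerate spectrum: zero variance, SNV undefined", call. = FALSE)
  }
  (X - mu) / s
}

#' SNV-transform every spectrum of a series
#' @param series A [spectral_series()].
#' @return A [spectral_series()] of SNV spectra.
#' @export
snv_series <- function(series) {
  stopifnot(inherits(series, "spectral_series"))
  spectral_series(series$axis, snv_matrix(series$spectra), series$info,
                  series$metadata)
}

#' Savitzky-Golay derivative of a spectrum
#'
#' Local least-squares polynomial convolution (via [signal::sgolay()]);
#' edge points use the asymmetric fits over the available window rather than
#' padding. The derivative is returned in index units (per channel); for a
#' uniform axis this differs from per-cm^-1 only by a constant factor, which
#' is immaterial downstream of centering.
#'
#' @param x Numeric intensity vector.
#' @param window Odd window length in points (default 21).
#' @param polyorder Fitted polynomial degree (default 2).
#' @param deriv Derivative order (default 2; `0` = smoothing).
#' @return Numeric vector, same length as `x`.
#' @export
savgol_derivative <- function(x, window = 21L, polyorder = 2L, deriv = 2L) {
  check_sg(length(x), window, polyorder, deriv)
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window, m = deriv,
                                ts = 1))
}

check_sg <- function(len, window, polyorder, deriv) {
  if (window %% 2L != 1L || window <= polyorder) {
    stop("invalid window: `window` must be odd and > `polyorder`",
         call. = FALSE)
  }
  if (deriv > polyorder) {
    stop("`deriv` must be <= `polyorder`", call. = FALSE)
  }
  if (len < window) {
    stop("invalid window: spectrum shorter than the filter window",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Matrix form of the Savitzky-Golay derivative: interior by shifted-column
# accumulation with the central projection row, edges by the asymmetric rows
# of the sgolay matrix. Identical to savgol_derivative() row by row.
savgol_matrix <- function(X, window = 21L, polyorder = 2L, deriv = 2L) {
  check_sg(ncol(X), window, polyorder, deriv)
  FF <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = 1)
  FF <- unclass(FF)
  k <- (window - 1L) %/% 2L
  L <- ncol(X)
  Y <- matrix(0, nrow(X), L)
  w_mid <- FF[k + 1L, ]
  for (j in seq_len(window)) {
    Y[, (k + 1L):(L - k)] <- Y[, (k + 1L):(L - k)] +
      w_mid[j] * X[, j:(L - window + j), drop = FALSE]
  }
  Y[, 1:k] <- X[, 1:window, drop = FALSE] %*% t(FF[1:k, , drop = FALSE])
  Y[, (L - k + 1L):L] <- X[, (L - window + 1L):L, drop = FALSE] %*%
    t(FF[(window - k + 1L):window, , drop = FALSE])
  Y
}

#' Savitzky-Golay derivative of every spectrum in a series
#' @inheritParams savgol_derivative
#' @param series A [spectral_series()].
#' @return A [spectral_series()].
#' @export
savgol_series <- function(series, window = 21L, polyorder = 2L, deriv = 2L) {
  stopifnot(inherits(series, "spectral_series"))
  spectral_series(series$axis,
                  savgol_matrix(series$spectra, window, polyorder, deriv),
                  series$info, series$metadata)
}

#' Trailing moving average over time
#'
#' Replaces spectrum *t* by the mean of spectra `max(1, t - window + 1) ... t`
#' (causal window, so a real-time prediction never uses future spectra; the
#' first `window - 1` spectra average over the shorter available prefix).
#' The applied-mass label of the output spectrum stays that of spectrum *t*.
#'
#' @param series A [spectral_series()].
#' @param window Number of spectra to average (>= 1; default 6, i.e. 60 s of
#'   process time at a 10 s cadence).
#' @return A [spectral_series()].
#' @export
moving_average_series <- function(series, window = 6L) {
  stopifnot(inherits(series, "spectral_series"))
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  n <- nrow(series$spectra)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (window == 1L) return(series)
  cs <- apply(series$spectra, 2L, cumsum)
  if (n == 1L) cs <- matrix(cs, nrow = 1L)
  lag <- rbind(matrix(0, min(window, n), ncol(cs)),
               cs[seq_len(max(0L, n - window)), , drop = FALSE])
  denom <- pmin(seq_len(n), window)
  spectral_series(series$axis, (cs - lag) / denom, series$info,
                  series$metadata)
}

#' Mean core spectrum from the warm-up phase
#'
#' Takes the last `n` warm-up spectra, SNV-transforms each, and averages
#' them channel-wise. The result is the subtrahend used to form differential
#' spectra that isolate the growing coating signal.
#'
#' @param series A raw [spectral_series()] with a warm-up phase.
#' @param n Number of trailing warm-up spectra to use (default 8).
#' @return A `core_reference` object: list with `axis`, `mean_spectrum`,
#'   `n_source_spectra` and `source_run` (core name if known).
#' @export
compute_core_reference <- function(series, n = 8L) {
  stopifnot(inherits(series, "spectral_series"))
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  warm <- which(series$info$phase == "warmup")
  if (length(warm) < n) {
    stop("insufficient warm-up spectra: need ", n, ", have ", length(warm),
         call. = FALSE)
  }
  idx <- utils::tail(warm, n)
  ref <- colMeans(snv_matrix(series$spectra[idx, , drop = FALSE]))
  structure(list(axis = series$axis, mean_spectrum = ref,
                 n_source_spectra = n,
                 source_run = series$metadata$core %||% NA_character_),
            class = "core_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential spectrum: subtract the mean core spectrum
#'
#' @param x An SNV-treated intensity vector on the reference's axis.
#' @param core_ref A [compute_core_reference()] result.
#' @return The channel-wise difference `x - core_ref$mean_spectrum`.
#' @export
differential_spectrum <- function(x, core_ref) {
  stopifnot(inherits(core_ref, "core_reference"))
  if (length(x) != length(core_ref$mean_spectrum)) {
    stop("incompatible axes: spectrum has ", length(x),
         " channels, core reference ", length(core_ref$mean_spectrum),
         call. = FALSE)
  }
  x - core_ref$mean_spectrum
}

#' Differential spectra for a whole (already SNV-treated) series
#' @param series A [spectral_series()] of SNV spectra.
#' @param core_ref A [compute_core_reference()] result on the same axis.
#' @return A [spectral_series()] of differential spectra.
#' @export
differential_series <- function(series, core_ref) {
  stopifnot(inherits(series, "spectral_series"),
            inherits(core_ref, "core_reference"))
  if (length(series$axis) != length(core_ref$axis) ||
      any(series$axis != core_ref$axis)) {
    stop("incompatible axes between series and core reference", call. = FALSE)
  }
  spectral_series(series$axis,
                  series$spectra - matrix(core_ref$mean_spectrum,
                                          nrow(series$spectra),
                                          length(series$axis), byrow = TRUE),
                  series$info, series$metadata)
}

#' Crop a series or spectrum to a wavenumber range
#'
#' Retains channels with `lo <= wavenumber <= hi` (inclusive).
#'
#' @param x A [spectral_series()], or a numeric vector with `axis` given.
#' @param lo,hi Range bounds in cm^-1, `lo < hi`.
#' @param axis Wavenumber axis, required when `x` is a bare vector.
#' @return Same kind as `x`, restricted to the range.
#' @export
crop_range <- function(x, lo, hi, axis = NULL) {
  if (lo >= hi) stop("`lo` must be < `hi`", call. = FALSE)
  if (inherits(x, "spectral_series")) {
    keep <- x$axis >= lo & x$axis <= hi
    if (!any(keep)) {
      stop("empty range: [", lo, ", ", hi, "] does not overlap the axis",
           call. = FALSE)
    }
    return(spectral_series(x$axis[keep], x$spectra[, keep, drop = FALSE],
                           x$info, x$metadata))
  }
  if (is.null(axis)) stop("`axis` required for a bare spectrum", call. = FALSE)
  keep <- axis >= lo & axis <= hi
  if (!any(keep)) {
    stop("empty range: [", lo, ", ", hi, "] does not overlap the axis",
         call. = FALSE)
  }
  x[keep]
}

#' Preprocessing configuration
#'
#' The default chain is: SNV -> core-spectrum subtraction (differential) ->
#' trailing moving average -> end-point normalization -> Savitzky-Golay
#' 2nd derivative -> range crop. Subtraction acts on SNV-filtered spectra
#' and normalization on differential spectra; the moving average precedes
#' normalization so the end-point reference is read off a 60 s-averaged
#' spectrum instead of one noisy acquisition, and the derivative follows
#' normalization because a derivative does not commute with division by a
#' raw end-point maximum.
#'
#' @param snv Apply SNV? (default `TRUE`).
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay settings
#'   (defaults 21 / 2 / 2). `sg_deriv = NA` skips the derivative.
#' @param moving_avg_window Trailing moving-average span in spectra
#'   (default 6).
#' @param range_lo,range_hi Retained wavenumber range (cm^-1); `NA` keeps the
#'   full axis.
#' @param n_core_spectra Warm-up spectra used for the core reference
#'   (default 8).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(snv = TRUE, sg_window = 21L, sg_polyorder = 2L,
                              sg_deriv = 2L, moving_avg_window = 6L,
                              range_lo = NA_real_, range_hi = NA_real_,
                              n_core_spectra = 8L) {
  if (!is.na(sg_deriv)) check_sg(Inf, sg_window, sg_polyorder, sg_deriv)
  if (moving_avg_window < 1L) stop("`moving_avg_window` must be >= 1",
                                   call. = FALSE)
  if (!is.na(range_lo) && !is.na(range_hi) && range_lo >= range_hi) {
    stop("`range_lo` must be < `range_hi`", call. = FALSE)
  }
  structure(list(snv = snv, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = if (is.na(sg_deriv)) NA_integer_ else
                   as.integer(sg_deriv),
                 moving_avg_window = as.integer(moving_avg_window),
                 range_lo = range_lo, range_hi = range_hi,
                 n_core_spectra = as.integer(n_core_spectra)),
            class = "preprocess_config")
}

#' Differential SNV spectra of a run
#'
#' Convenience for the first half of the chain: SNV every spectrum, build
#' (or accept) the mean core reference, and subtract it. Normalization
#' references are extracted from the result of this step.
#'
#' @param series A raw [spectral_series()].
#' @param config A [preprocess_config()].
#' @param core_ref Optional pre-computed [compute_core_reference()]; by
#'   default the run's own warm-up tail is used.
#' @return List with `series` (differential [spectral_series()]) and
#'   `core_ref`.
#' @export
differential_snv_series <- function(series, config = preprocess_config(),
                                    core_ref = NULL) {
  if (is.null(core_ref)) {
    core_ref <- compute_core_reference(series, config$n_core_spectra)
  }
  list(series = differential_series(snv_series(series), core_ref),
       core_ref = core_ref)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: SNV, core-spectrum subtraction, trailing moving
#' average, optional end-point normalization, Savitzky-Golay derivative,
#' range crop (see [preprocess_config()] for the rationale of the order).
#'
#' @inheritParams differential_snv_series
#' @param norm_ref Optional [normalization_reference()]; when supplied the
#'   averaged differential spectra are divided by its value before the
#'   derivative. When `NULL`, no normalization is applied.
#' @return List with `series` (fully preprocessed [spectral_series()]),
#'   `core_ref` and `norm_ref` (possibly `NULL`).
#' @export
preprocess_series <- function(series, config = preprocess_config(),
                              core_ref = NULL, norm_ref = NULL) {
  diff <- differential_snv_series(series, config, core_ref)
  out <- moving_average_series(diff$series, config$moving_avg_window)
  if (!is.null(norm_ref)) out <- apply_normalization(out, norm_ref)
  if (!is.na(config$sg_deriv)) {
    out <- savgol_series(out, config$sg_window, config$sg_polyorder,
                         config$sg_deriv)
  }
  if (!is.na(config$range_lo) && !is.na(config$range_hi)) {
    out <- crop_range(out, config$range_lo, config$range_hi)
  }
  list(series = out, core_ref = diff$core_ref, norm_ref = norm_ref)
}
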