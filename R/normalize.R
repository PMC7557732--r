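#' Normalization reference
#'
#' The scalar used to put differential spectra of runs with very different
#' core intensities on a common scale, together with its provenance. Two
#' schemes exist: `"max"` divides by the maximum of the final differential
#' spectrum of a run; `"max3"` divides by the mean end-point intensity at the
#' three anatase TiO2 marker bands (398, 516, 640 cm^-1 by default). The
#' reference may come from the run being normalized (`own_run_endpoint`,
#' only possible retrospectively) or from the final spectra of a calibration
#' run (`calibration_run`, the real-time variant).
#'
#' @param method `"max"` or `"max3"`.
#' @param value Positive scalar intensity.
#' @param marker_bands Wavenumbers (cm^-1) used by `"max3"`.
#' @param source `"own_run_endpoint"` or `"calibration_run"`.
#' @return A `normalization_reference` object.
#' @export
normalization_reference <- function(method, value,
                                    marker_bands = NULL,
                                    source = "own_run_endpoint") {
  method <- match.arg(method, c("max", "max3"))
  source <- match.arg(source, c("own_run_endpoint", "calibration_run"))
  if (!is.finite(value) || value <= 0) {
    stop("non-positive reference: normalization value must be > 0",
         call. = FALSE)
  }
  if (method == "max3" && length(marker_bands) < 1L) {
    stop("`max3` requires at least one marker band", call. = FALSE)
  }
  structure(list(method = method, value = as.numeric(value),
                 marker_bands = marker_bands, source = source),
            class = "normalization_reference")
}

#' End-point "max" normalization reference of a run
#'
#' The maximum intensity over channels of the final differential spectrum of
#' the series (the largest peak of a normalized run then reaches exactly 1
#' at the end of the process).
#'
#' @param series A differential [spectral_series()] (time-ordered).
#' @param source Provenance tag, see [normalization_reference()].
#' @return A `normalization_reference` with `method = "max"`.
#' @export
compute_max_reference <- function(series, source = "own_run_endpoint") {
  stopifnot(inherits(series, "spectral_series"))
  if (nrow(series$spectra) < 1L) stop("empty series", call. = FALSE)
  v <- max(series$spectra[nrow(series$spectra), ])
  if (v <= 0) {
    stop("non-positive reference: final-spectrum maximum is <= 0",
         call. = FALSE)
  }
  normalization_reference("max", v, source = source)
}

#' End-point "max3" normalization reference of a run
#'
#' The mean of the final differential spectrum's intensities at the marker
#' bands, each looked up at the single nearest axis channel (no peak search,
#' no interpolation). At the process end the marker bands are at their
#' maximum, so this is the mean of the three peak maxima.
#'
#' @param series A differential [spectral_series()].
#' @param marker_bands Wavenumbers (cm^-1); default the three anatase TiO2
#'   bands 398, 516, 640.
#' @param source Provenance tag, see [normalization_reference()].
#' @param tolerance Maximum |band - nearest channel| allowed (cm^-1);
#'   default half the axis range so any on-axis band passes.
#' @return A `normalization_reference` with `method = "max3"`.
#' @export
compute_max3_reference <- function(series,
                                   marker_bands = c(398, 516, 640),
                                   source = "own_run_endpoint",
                                   tolerance = NULL) {
  stopifnot(inherits(series, "spectral_series"))
  if (nrow(series$spectra) < 1L) stop("empty series", call. = FALSE)
  idx <- marker_channels(series$axis, marker_bands, tolerance)
  v <- mean(series$spectra[nrow(series$spectra), idx])
  if (v <= 0) {
    stop("non-positive reference: mean marker intensity is <= 0",
         call. = FALSE)
  }
  normalization_reference("max3", v, marker_bands = marker_bands,
                          source = source)
}

# Nearest-channel lookup of marker bands; bands are matched by wavenumber so
# references transfer across axes (calibration axis -> test axis).
marker_channels <- function(axis, bands, tolerance = NULL) {
  if (is.null(tolerance)) {
    tolerance <- max(diff(axis))  # one grid step: band must lie on the axis
  }
  vapply(bands, function(b) {
    i <- which.min(abs(axis - b))
    if (abs(axis[i] - b) > tolerance) {
      stop("band not on axis: ", b, " cm-1 (nearest channel ", axis[i], ")",
           call. = FALSE)
    }
    i
  }, integer(1))
}

#' Normalize a differential series by a reference value
#'
#' Divides every spectrum channel-wise by `ref$value`. With an own-run
#' end-point `"max"` reference the final spectrum's maximum becomes exactly 1.
#'
#' @param series A differential [spectral_series()].
#' @param ref A [normalization_reference()].
#' @return A [spectral_series()] of normalized spectra.
#' @export
apply_normalization <- function(series, ref) {
  stopifnot(inherits(series, "spectral_series"),
            inherits(ref, "normalization_reference"))
  if (ref$value <= 0) {
    stop("non-positive reference", call. = FALSE)
  }
  spectral_series(series$axis, series$spectra / ref$value, series$info,
                  series$metadata)
}

#' Compute a normalization reference by method name
#'
#' @param series A differential [spectral_series()].
#' @param method `"max"` or `"max3"`.
#' @param marker_bands Bands for `"max3"`.
#' @param source Provenance tag.
#' @return A [normalization_reference()].
#' @export
compute_norm_reference <- function(series, method = c("max", "max3"),
                                   marker_bands = c(398, 516, 640),
                                   source = "own_run_endpoint") {
  method <- match.arg(method)
  if (method == "max") {
    compute_max_reference(series, source = source)
  } else {
    compute_max3_reference(series, marker_bands = marker_bands,
                           source = source)
  }
}
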