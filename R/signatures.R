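#' Spectral peak specification
#'
#' A single Raman band used by the synthetic-run generator.
#'
#' @param center Band position in cm^-1.
#' @param amplitude Peak height in arbitrary intensity units (>= 0).
#' @param width Width parameter in cm^-1 (> 0): Gaussian standard deviation
#'   or Lorentzian half-width at half-maximum.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row tibble describing the band.
#' @export
peak_spec <- function(center, amplitude, width, shape = "gaussian") {
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  tibble::tibble(center = center, amplitude = amplitude,
                 width = width, shape = shape)
}

peak_table <- function(centers, amplitudes, widths,
                       shape = "gaussian") {
  purrr::pmap_dfr(list(centers, amplitudes, widths),
                  function(c, a, w) peak_spec(c, a, w, shape))
}

#' Built-in tablet-core spectral signatures
#'
#' Returns the Raman signature of one of the three study cores. The
#' acetylsalicylic-acid (ASA) core carries the strongest scattering with its
#' characteristic double band near 1605 cm^-1 and a cluster of bands between
#' 990 and 1340 cm^-1; the diclofenac core shows bands at 441, 1046, 1578 and
#' 1605 cm^-1 at lower overall intensity; the dicalcium-phosphate placebo core
#' has only a few weak bands (dominated by the phosphate stretch near
#' 985 cm^-1). Base intensities are ordered asa > diclofenac > placebo.
#'
#' @param name One of `"asa"`, `"diclofenac"`, `"placebo"`.
#' @return A `core_signature` object: list with `name`, `peaks` (tibble of
#'   [peak_spec()] rows with absolute amplitudes), `base_intensity` and
#'   `baseline` (polynomial coefficients of a smooth fluorescence-like
#'   background over the normalized axis).
#' @export
core_signature <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("asa", "diclofenac", "placebo")) {
    stop("unsupported core: ", deparse(substitute(name)),
         " (built-ins: asa, diclofenac, placebo)", call. = FALSE)
  }
  sig <- switch(name,
    asa = list(
      base_intensity = 100,
      peaks = peak_table(
        centers    = c(1605, 1622, 1045, 1190, 1290, 750, 550),
        amplitudes = c(1.00, 0.70, 0.50, 0.35, 0.40, 0.20, 0.15),
        widths     = c(6, 6, 7, 8, 8, 9, 9)),
      baseline = c(8, 4, -3)),
    diclofenac = list(
      base_intensity = 40,
      peaks = peak_table(
        centers    = c(441, 1046, 1578, 1605, 880, 1250),
        amplitudes = c(0.60, 0.50, 0.80, 0.70, 0.30, 0.30),
        widths     = c(7, 7, 6, 6, 9, 9)),
      baseline = c(6, 3, -2)),
    placebo = list(
      base_intensity = 15,
      peaks = peak_table(
        centers    = c(475, 590, 985, 1090),
        amplitudes = c(0.50, 0.30, 0.60, 0.30),
        widths     = c(10, 10, 8, 10)),
      baseline = c(5, 2, -1))
  )
  sig$peaks$amplitude <- sig$peaks$amplitude * sig$base_intensity
  structure(list(name = name, peaks = sig$peaks,
                 base_intensity = sig$base_intensity,
                 baseline = sig$baseline),
            class = "core_signature")
}

#' Built-in coating spectral signatures
#'
#' The enteric coating (`"tio2_enteric"`) contains anatase TiO2 whose three
#' characteristic bands at 398, 516 and 640 cm^-1 serve both as growth markers
#' and as the "max3" normalization bands. The immediate-release coating
#' (`"caco3_ir"`) is TiO2-free, with CaCO3 bands at 280, 712 and 1086 cm^-1;
#' its dominant 1086 cm^-1 band grows to roughly 1/2.7 of the TiO2 dominant
#' band at matched conditions, which is what makes it the harder coating to
#' track.
#'
#' @param name One of `"tio2_enteric"`, `"caco3_ir"`.
#' @return A `coating_signature` object: list with `name`, `peaks` (tibble of
#'   [peak_spec()] rows, absolute amplitudes at full applied mass),
#'   `marker_bands` (cm^-1), `solids_fraction` of the sprayed suspension and
#'   `film_density` (g/cm^3) of the dried film.
#' @export
coating_signature <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("tio2_enteric", "caco3_ir")) {
    stop("unsupported coating: ", deparse(substitute(name)),
         " (built-ins: tio2_enteric, caco3_ir)", call. = FALSE)
  }
  sig <- switch(name,
    tio2_enteric = list(
      peaks = peak_table(
        centers    = c(398, 516, 640, 810, 1450),
        amplitudes = c(2.00, 1.20, 1.50, 0.30, 0.50),
        widths     = c(7, 7, 7, 10, 12)),
      marker_bands = c(398, 516, 640),
      solids_fraction = 0.22,
      film_density = 1.35),
    caco3_ir = list(
      peaks = peak_table(
        centers    = c(280, 712, 1086, 1450),
        amplitudes = c(0.41, 0.33, 0.74, 0.22),
        widths     = c(8, 7, 7, 12)),
      marker_bands = 1086,
      solids_fraction = 0.15,
      film_density = 1.45)
  )
  structure(c(list(name = name), sig), class = "coating_signature")
}

#' Evaluate a signature's spectrum on a wavenumber axis
#'
#' Sums the signature's bands (and, for cores, the polynomial baseline) over
#' the axis. Coating spectra are returned at full applied mass; the simulator
#' scales them by the applied-mass fraction.
#'
#' @param signature A `core_signature` or `coating_signature`.
#' @param axis Wavenumber grid (cm^-1).
#' @param baseline Include the signature's baseline term (cores only)?
#' @return Numeric intensity vector of `length(axis)`.
#' @export
signature_spectrum <- function(signature, axis, baseline = TRUE) {
  y <- numeric(length(axis))
  pk <- signature$peaks
  for (i in seq_len(nrow(pk))) {
    if (pk$shape[i] == "gaussian") {
      y <- y + pk$amplitude[i] * exp(-((axis - pk$center[i])^2) /
                                       (2 * pk$width[i]^2))
    } else {
      y <- y + pk$amplitude[i] * pk$width[i]^2 /
        ((axis - pk$center[i])^2 + pk$width[i]^2)
    }
  }
  if (baseline && !is.null(signature$baseline)) {
    u <- (axis - min(axis)) / (max(axis) - min(axis))
    y <- y + drop(outer(u, seq_along(signature$baseline) - 1, `^`) %*%
                    signature$baseline)
  }
  y
}
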