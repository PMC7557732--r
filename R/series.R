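#' Time-ordered inline Raman spectra on a shared wavenumber axis
#'
#' `spectral_series()` bundles a wavenumber axis, one intensity vector per
#' acquisition, and a per-spectrum info table (time, process phase, applied
#' coating mass). It is the common currency of the whole pipeline: the
#' simulator emits it, every preprocessing step maps it to a new one, and
#' calibration consumes it.
#'
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param spectra Numeric matrix, one row per spectrum, `length(axis)` columns.
#' @param info Tibble with one row per spectrum and columns `spectrum_id`,
#'   `time_s`, `phase` (`"warmup"` or `"spray"`) and `applied_mass_g`
#'   (0 during warm-up, non-decreasing over time; may be `NA` for externally
#'   read data without labels).
#' @param metadata Named list of free-form run descriptors (core, coating,
#'   spray rate, ...).
#'
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(axis, spectra, info, metadata = list()) {
  axis <- as.numeric(axis)
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1L)
  spectra <- unname(as.matrix(spectra))
  storage.mode(spectra) <- "double"
  if (length(axis) < 2L || any(diff(axis) <= 0)) {
    stop("`axis` must be strictly increasing with at least two channels",
         call. = FALSE)
  }
  if (ncol(spectra) != length(axis)) {
    stop("each spectrum must have one intensity per axis channel (",
         ncol(spectra), " columns vs ", length(axis), " channels)",
         call. = FALSE)
  }
  info <- tibble::as_tibble(info)
  required <- c("spectrum_id", "time_s", "phase", "applied_mass_g")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols) > 0L) {
    stop("`info` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(info) != nrow(spectra)) {
    stop("`info` must have one row per spectrum", call. = FALSE)
  }
  m <- info$applied_mass_g
  if (!anyNA(m)) {
    if (any(diff(m) < 0)) {
      stop("`applied_mass_g` must be non-decreasing over time", call. = FALSE)
    }
    if (any(m[info$phase == "warmup"] != 0)) {
      stop("warm-up spectra must carry zero applied mass", call. = FALSE)
    }
  }
  structure(
    list(axis = axis, spectra = spectra, info = info, metadata = metadata),
    class = "spectral_series"
  )
}

#' @export
print.spectral_series <- function(x, ...) {
  n <- nrow(x$spectra)
  cat("<spectral_series> ", n, " spectra x ", length(x$axis),
      " channels (", min(x$axis), "-", max(x$axis), " cm-1)\n", sep = "")
  ph <- table(x$info$phase)
  cat("  phases: ", paste(names(ph), ph, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!anyNA(x$info$applied_mass_g)) {
    cat("  applied mass: 0-", max(x$info$applied_mass_g), " g\n", sep = "")
  }
  if (!is.null(x$metadata$core)) {
    cat("  core: ", x$metadata$core,
        if (!is.null(x$metadata$coating)) paste0(", coating: ", x$metadata$coating),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of spectra in a series
#' @param series A [spectral_series()].
#' @return Integer count.
#' @export
n_spectra <- function(series) {
  stopifnot(inherits(series, "spectral_series"))
  nrow(series$spectra)
}

#' Subset the spectra of a series by row index
#'
#' Keeps axis and metadata, subsets the intensity matrix and the info table
#' in lock-step.
#'
#' @param series A [spectral_series()].
#' @param idx Integer or logical index over spectra.
#' @return A [spectral_series()].
#' @export
subset_spectra <- function(series, idx) {
  stopifnot(inherits(series, "spectral_series"))
  spectral_series(series$axis,
                  series$spectra[idx, , drop = FALSE],
                  series$info[idx, , drop = FALSE],
                  series$metadata)
}

#' Tidy a spectral series into a long tibble
#'
#' One row per (spectrum, channel), suitable for dplyr/ggplot2 work.
#'
#' @param x A [spectral_series()].
#' @param ... Unused.
#' @return A tibble with columns `spectrum_id`, `time_s`, `phase`,
#'   `applied_mass_g`, `wavenumber`, `intensity`.
#' @export
tidy.spectral_series <- function(x, ...) {
  long <- tibble::tibble(
    spectrum_id = rep(x$info$spectrum_id, each = length(x$axis)),
    wavenumber = rep(x$axis, times = nrow(x$spectra)),
    intensity = as.vector(t(x$spectra))
  )
  dplyr::left_join(long, x$info, by = "spectrum_id")[,
    c("spectrum_id", "time_s", "phase", "applied_mass_g",
      "wavenumber", "intensity")]
}

#' @export
autoplot.spectral_series <- function(object, every = 25L, ...) {
  keep <- unique(c(seq(1L, n_spectra(object), by = every), n_spectra(object)))
  df <- tidy(subset_spectra(object, keep))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wavenumber, y = .data$intensity,
    group = .data$spectrum_id, colour = .data$applied_mass_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "applied mass (g)") +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "intensity (a.u.)")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
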