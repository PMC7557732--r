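#' Model performance statistics
#'
#' Computes the coefficient of determination (squared correlation of
#' observed and predicted mass), the root-mean-square error and the
#' bias-corrected standard error, with errors expressed as a percentage of
#' the total applied coating mass of the run (a single fixed denominator:
#' per-time-point relative errors would diverge near zero applied mass at
#' the process start).
#'
#' \deqn{RMSE = \sqrt{\tfrac1n \sum (\hat y_i - y_i)^2}, \qquad
#'       SE = \sqrt{\tfrac{1}{n-1} \sum (\hat y_i - y_i - \overline{d})^2}}
#' with \eqn{\overline{d}} the mean prediction bias. In a calibration
#' context the RMSE is the RMSEC and the SE the SEC; in a prediction context
#' the RMSE is the RMSEP.
#'
#' @param observed,predicted Mass vectors (g), equal length.
#' @param total_applied_mass Total sprayed coating mass of the run (g), the
#'   percentage denominator.
#' @param context `"calibration"` or `"prediction"` (bookkeeping label).
#' @param n_excluded Number of outliers excluded before fitting (optional).
#' @return One-row tibble: `context`, `n_samples`, `n_excluded`, `r2`,
#'   `rmse_pct`, `se_pct`.
#' @export
performance <- function(observed, predicted, total_applied_mass,
                        context = c("calibration", "prediction"),
                        n_excluded = 0L) {
  context <- match.arg(context)
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (total_applied_mass <= 0) {
    stop("`total_applied_mass` must be > 0", call. = FALSE)
  }
  d <- predicted - observed
  rmse <- sqrt(mean(d^2))
  se <- if (length(d) > 1L) sqrt(sum((d - mean(d))^2) / (length(d) - 1L))
        else 0
  r2 <- if (stats::var(observed) > 0 && stats::var(predicted) > 0) {
    stats::cor(observed, predicted)^2
  } else if (all(d == 0)) 1 else NA_real_
  tibble::tibble(context = context,
                 n_samples = length(observed),
                 n_excluded = as.integer(n_excluded),
                 r2 = r2,
                 rmse_pct = rmse / total_applied_mass * 100,
                 se_pct = se / total_applied_mass * 100)
}

#' Biconvex tablet geometry
#'
#' @param diameter Tablet diameter (mm).
#' @param total_height Total tablet height including both caps (mm).
#' @param band_height Height of the cylindrical band (mm),
#'   `<= total_height`.
#' @param mean_mass Mean tablet mass (mg).
#' @return A `tablet_geometry` object. Built-in study geometries are
#'   available via [core_tablet_geometry()].
#' @export
tablet_geometry <- function(diameter, total_height, band_height, mean_mass) {
  if (diameter <= 0 || band_height <= 0) {
    stop("invalid geometry: diameter and band height must be > 0",
         call. = FALSE)
  }
  if (band_height > total_height) {
    stop("invalid geometry: band height exceeds total height", call. = FALSE)
  }
  structure(list(diameter = diameter, total_height = total_height,
                 band_height = band_height, mean_mass = mean_mass),
            class = "tablet_geometry")
}

#' Built-in tablet geometries of the three study cores
#'
#' ASA: 8.0 mm diameter, 4.2 mm height, 2.8 mm band, 239.6 mg.
#' Diclofenac: 8.0 mm, 4.02 mm, 2.02 mm, 205.6 mg.
#' Placebo: 8.1 mm, 3.42 mm, 2.05 mm, 252.4 mg.
#'
#' @param core `"asa"`, `"diclofenac"` or `"placebo"`.
#' @return A [tablet_geometry()].
#' @export
core_tablet_geometry <- function(core) {
  switch(match.arg(core, c("asa", "diclofenac", "placebo")),
         asa = tablet_geometry(8.0, 4.2, 2.8, 239.6),
         diclofenac = tablet_geometry(8.0, 4.02, 2.02, 205.6),
         placebo = tablet_geometry(8.1, 3.42, 2.05, 252.4))
}

#' Surface area of a biconvex tablet
#'
#' Models the tablet as a cylindrical band plus two spherical caps: band
#' area \eqn{\pi d h_b}; each cap of height
#' \eqn{h = (H - h_b)/2} has lateral area \eqn{2 \pi R h} with cap radius
#' \eqn{R = ((d/2)^2 + h^2) / (2h)}. With \eqn{h = 0} the faces are flat and
#' contribute \eqn{\pi (d/2)^2} each; in the limit of a vanishing band with
#' \eqn{H = d} the total tends to the sphere surface \eqn{4\pi r^2}.
#'
#' @param geometry A [tablet_geometry()].
#' @return Total surface area in mm^2.
#' @export
tablet_surface_area <- function(geometry) {
  stopifnot(inherits(geometry, "tablet_geometry"))
  d <- geometry$diameter
  h <- (geometry$total_height - geometry$band_height) / 2
  band <- pi * d * geometry$band_height
  cap <- if (h == 0) {
    pi * (d / 2)^2
  } else {
    R <- ((d / 2)^2 + h^2) / (2 * h)
    2 * pi * R * h
  }
  band + 2 * cap
}

#' Film properties of a coating
#'
#' @param solids_fraction Mass fraction of the sprayed suspension that ends
#'   up as dry film, in (0, 1].
#' @param film_density Density of the dried film (g/cm^3), e.g. from gas
#'   pycnometry of cast films.
#' @return A `film_properties` object.
#' @export
film_properties <- function(solids_fraction, film_density) {
  if (solids_fraction <= 0 || solids_fraction > 1) {
    stop("`solids_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (film_density <= 0) stop("`film_density` must be > 0", call. = FALSE)
  structure(list(solids_fraction = solids_fraction,
                 film_density = film_density),
            class = "film_properties")
}

#' End-point coating thickness from predicted sprayed mass
#'
#' Converts the predicted sprayed suspension mass into a per-tablet dry film
#' volume and divides by the tablet surface area:
#' tablets in the batch \eqn{N =} batch mass / mean tablet mass; dry film
#' mass per tablet = predicted mass x solids fraction / \eqn{N}; film volume
#' = mass / density; thickness = volume / surface area.
#'
#' @param predicted_sprayed_mass Predicted sprayed suspension mass (g).
#' @param film A [film_properties()].
#' @param geometry A [tablet_geometry()].
#' @param batch_mass Tablet batch mass (g).
#' @return Film thickness in micrometers.
#' @export
endpoint_thickness <- function(predicted_sprayed_mass, film, geometry,
                               batch_mass) {
  stopifnot(inherits(film, "film_properties"),
            inherits(geometry, "tablet_geometry"))
  if (predicted_sprayed_mass <= 0 || batch_mass <= 0) {
    stop("invalid input: masses must be > 0", call. = FALSE)
  }
  area <- tablet_surface_area(geometry)
  if (area <= 0) stop("invalid input: non-positive surface area",
                      call. = FALSE)
  n_tablets <- batch_mass / (geometry$mean_mass / 1000)  # mean mass in mg
  dry_mass <- predicted_sprayed_mass * film$solids_fraction / n_tablets  # g
  volume_mm3 <- dry_mass / film$film_density * 1000       # cm^3 -> mm^3
  volume_mm3 / area * 1000                                # mm -> um
}
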