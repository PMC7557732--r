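#' Configuration of a simulated coating run
#'
#' Collects the process and noise parameters of one inline-monitored coating
#' run. Defaults mirror the study conditions of the pan-coating process the
#' generator emulates: one spectrum every 10 s, an 8-spectrum warm-up tail
#' used for the mean core spectrum, a spray rate of 11.5 g/min (middle of the
#' 11-12 g/min operating band) and a total sprayed suspension mass of 1373 g
#' for the enteric coating or 1330 g for the immediate-release coating.
#'
#' @param core A [core_signature()] or built-in core name.
#' @param coating A [coating_signature()] or built-in coating name.
#' @param axis Wavenumber grid (cm^-1), ascending; default 200-1800 at
#'   1 cm^-1, covering every band of the built-in signatures.
#' @param spray_rate Suspension spray rate in g/min (> 0).
#' @param total_spray_mass Total sprayed suspension mass in g (> 0). `NULL`
#'   picks the coating-specific default (1373 g TiO2 enteric, 1330 g CaCO3).
#' @param spectrum_interval Acquisition cadence in s.
#' @param n_warmup_spectra Number of core-only spectra before spraying
#'   (>= 8 so a mean core spectrum can be formed from the last eight).
#' @param noise_sd Additive Gaussian channel noise, intensity units.
#' @param intensity_jitter_sd Log-normal sigma of the per-spectrum
#'   multiplicative intensity fluctuation (dimensionless).
#' @param core_attenuation Rate at which the core signal decays with the
#'   applied-mass fraction (core is masked by the growing film); 0 disables.
#' @param batch_mass Tablet batch mass in g (used downstream for thickness).
#' @param seed Integer seed; the run is fully deterministic given the config.
#' @return A `coating_run_config` object (named list).
#' @export
coating_run_config <- function(core = "placebo",
                               coating = "tio2_enteric",
                               axis = seq(200, 1800, by = 1),
                               spray_rate = 11.5,
                               total_spray_mass = NULL,
                               spectrum_interval = 10,
                               n_warmup_spectra = 8L,
                               noise_sd = 0.02,
                               intensity_jitter_sd = 0.01,
                               core_attenuation = 0.3,
                               batch_mass = 3800,
                               seed = 1L) {
  if (is.character(core)) core <- core_signature(core)
  if (is.character(coating)) coating <- coating_signature(coating)
  stopifnot(inherits(core, "core_signature"),
            inherits(coating, "coating_signature"))
  if (is.null(total_spray_mass)) {
    total_spray_mass <- switch(coating$name, caco3_ir = 1330, 1373)
  }
  if (spray_rate <= 0 || total_spray_mass <= 0) {
    stop("invalid config: `spray_rate` and `total_spray_mass` must be > 0",
         call. = FALSE)
  }
  if (spectrum_interval <= 0) {
    stop("invalid config: `spectrum_interval` must be > 0", call. = FALSE)
  }
  if (any(diff(axis) <= 0)) {
    stop("invalid config: `axis` must be strictly increasing", call. = FALSE)
  }
  if (noise_sd < 0 || intensity_jitter_sd < 0 || core_attenuation < 0) {
    stop("invalid config: noise, jitter and attenuation must be >= 0",
         call. = FALSE)
  }
  structure(list(core = core, coating = coating, axis = as.numeric(axis),
                 spray_rate = spray_rate,
                 total_spray_mass = total_spray_mass,
                 spectrum_interval = spectrum_interval,
                 n_warmup_spectra = as.integer(n_warmup_spectra),
                 noise_sd = noise_sd,
                 intensity_jitter_sd = intensity_jitter_sd,
                 core_attenuation = core_attenuation,
                 batch_mass = batch_mass,
                 seed = as.integer(seed)),
            class = "coating_run_config")
}

#' Simulate an inline-monitored coating run
#'
#' Generates a [spectral_series()] with the structure the calibration chain
#' assumes: `n_warmup_spectra` core-only spectra followed by spray-phase
#' spectra at the configured cadence until the applied suspension mass
#' reaches `total_spray_mass`. Each spectrum is
#'
#' \deqn{s_t = j_t [\,c(\nu) e^{-\alpha m_t/M} + g(\nu)\, m_t/M\,] + b(\nu) + \epsilon_t}
#'
#' with core spectrum \eqn{c}, coating spectrum at full mass \eqn{g},
#' baseline \eqn{b}, applied mass \eqn{m_t = } spray rate x elapsed spray
#' time (clipped at \eqn{M}), log-normal per-spectrum jitter \eqn{j_t} and
#' additive Gaussian channel noise \eqn{\epsilon_t}. The coating signal grows
#' linearly with the applied-mass fraction; the core is attenuated
#' exponentially as the film masks it.
#'
#' @param config A [coating_run_config()].
#' @return A [spectral_series()]; `metadata` records the generating
#'   parameters (core, coating, spray rate, total mass, batch mass, seed).
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "coating_run_config"))
  axis <- config$axis
  core_spec <- signature_spectrum(config$core, axis, baseline = FALSE)
  u <- (axis - min(axis)) / (max(axis) - min(axis))
  baseline <- drop(outer(u, seq_along(config$core$baseline) - 1, `^`) %*%
                     config$core$baseline)
  coat_spec <- signature_spectrum(config$coating, axis)

  n_warm <- config$n_warmup_spectra
  M <- config$total_spray_mass
  dm <- config$spray_rate * config$spectrum_interval / 60
  n_spray <- ceiling(M / dm)
  mass <- c(rep(0, n_warm), pmin(seq_len(n_spray) * dm, M))
  phase <- c(rep("warmup", n_warm), rep("spray", n_spray))
  n_tot <- n_warm + n_spray
  frac <- mass / M

  pure <- outer(exp(-config$core_attenuation * frac), core_spec) +
    outer(frac, coat_spec)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  jitter <- if (config$intensity_jitter_sd > 0) {
    exp(stats::rnorm(n_tot, 0, config$intensity_jitter_sd))
  } else rep(1, n_tot)
  noise <- if (config$noise_sd > 0) {
    matrix(stats::rnorm(n_tot * length(axis), 0, config$noise_sd),
           nrow = n_tot)
  } else 0

  spectra <- pure * jitter +
    matrix(baseline, n_tot, length(axis), byrow = TRUE) + noise

  info <- tibble::tibble(
    spectrum_id = sprintf("s%04d", seq_len(n_tot)),
    time_s = (seq_len(n_tot) - 1) * config$spectrum_interval,
    phase = phase,
    applied_mass_g = mass
  )
  spectral_series(axis, spectra, info, metadata = list(
    core = config$core$name, coating = config$coating$name,
    spray_rate = config$spray_rate, total_spray_mass = M,
    batch_mass = config$batch_mass,
    solids_fraction = config$coating$solids_fraction,
    film_density = config$coating$film_density,
    marker_bands = config$coating$marker_bands,
    n_warmup_spectra = n_warm, seed = config$seed
  ))
}
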