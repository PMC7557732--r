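#' Serialize a coating model to JSON
#'
#' Writes everything a later prediction needs — centering vectors,
#' regression vector, weights and loadings, chosen range and channels,
#' preprocessing configuration and the per-core normalization references —
#' so that `read_model(path)` plus a spectra CSV is a self-contained
#' real-time prediction setup.
#'
#' @param model A `coating_model` from [calibrate_run()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "coating_model"))
  fit <- model$fit
  payload <- list(
    format = "ramancoat_model",
    version = 1L,
    range = model$range,
    n_factors = model$n_factors,
    channels = model$channels,
    normalization = model$normalization,
    source = model$source,
    marker_bands = model$marker_bands,
    norm_refs = unname(purrr::imap(model$norm_refs, function(r, core) {
      if (is.null(core) || is.na(core) || !nzchar(core)) core <- "unknown"
      list(core = core, method = r$method, value = r$value,
           marker_bands = r$marker_bands)
    })),
    config = unclass(model$config),
    total_spray_mass = model$total_spray_mass,
    training = model$training,
    fit = list(x_mean = fit$x_mean, y_mean = fit$y_mean,
               coefficients = fit$coefficients,
               weights = fit$weights, x_loadings = fit$x_loadings,
               y_loadings = fit$y_loadings,
               score_var = apply(fit$scores, 2L, stats::var),
               n_samples = fit$n_samples)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a coating model written by [write_model()]
#'
#' @param path `.json` path.
#' @return A `coating_model` usable with [predict.coating_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "ramancoat_model") {
    stop("parse error in ", path, ": not a ramancoat model file",
         call. = FALSE)
  }
  fit <- structure(list(
    x_mean = p$fit$x_mean, y_mean = p$fit$y_mean,
    coefficients = p$fit$coefficients,
    weights = as.matrix(p$fit$weights),
    x_loadings = as.matrix(p$fit$x_loadings),
    y_loadings = p$fit$y_loadings,
    scores = matrix(numeric(0), 0, length(p$fit$y_loadings)),
    n_factors = p$n_factors,
    n_samples = p$fit$n_samples,
    fitted = NULL, y = NULL
  ), class = "pls_fit")
  norm_refs <- list()
  refs <- p$norm_refs
  n_refs <- if (is.data.frame(refs)) nrow(refs) else length(refs)
  for (i in seq_len(n_refs)) {
    r <- if (is.data.frame(refs)) refs[i, ] else refs[[i]]
    core <- r$core
    if (is.null(core) || is.na(core) || !nzchar(core)) core <- "unknown"
    norm_refs[[core]] <- normalization_reference(
      r$method, r$value,
      marker_bands = unlist(r$marker_bands),
      source = "calibration_run")
  }
  cfg_in <- p$config
  cfg <- preprocess_config(
    snv = cfg_in$snv %||% TRUE,
    sg_window = cfg_in$sg_window %||% 21L,
    sg_polyorder = cfg_in$sg_polyorder %||% 2L,
    sg_deriv = cfg_in$sg_deriv %||% NA_integer_,
    moving_avg_window = cfg_in$moving_avg_window %||% 6L,
    range_lo = cfg_in$range_lo %||% NA_real_,
    range_hi = cfg_in$range_hi %||% NA_real_,
    n_core_spectra = cfg_in$n_core_spectra %||% 8L)
  structure(list(
    fit = fit, range = p$range, n_factors = p$n_factors,
    channels = p$channels, config = cfg,
    normalization = p$normalization, source = p$source,
    marker_bands = p$marker_bands, norm_refs = norm_refs,
    outliers = NULL, grid = NULL,
    calibration_performance = NULL,
    total_spray_mass = p$total_spray_mass,
    confidence = NA_real_,
    training = p$training
  ), class = "coating_model")
}
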