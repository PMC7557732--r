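#' Calibrate a coating-mass PLS model on one or more runs
#'
#' Runs the full chain on the calibration run(s): SNV, subtraction of each
#' run's own mean core spectrum, end-point normalization (each calibration
#' run is normalized by its own end-point reference), Savitzky-Golay
#' derivative, trailing moving average; then a spectral-range x factor-count
#' grid search with single-pass Hotelling outlier exclusion, evaluated by
#' RMSEP on the evaluation run(s). Pooled (multi-core) models concatenate
#' the preprocessed calibration samples across runs before fitting.
#'
#' @param calibration A [spectral_series()] or list of them.
#' @param evaluation A [spectral_series()] or list of them, used as the
#'   grid-search evaluation set. Using the test batch here mirrors the
#'   original optimize-on-the-test-batch protocol (leaky by modern
#'   standards); pass an independent run for a leak-free search.
#' @param normalization `"max"` or `"max3"`.
#' @param source Where prediction-time normalization references come from:
#'   `"own_run_endpoint"` (retrospective) or `"calibration_run"` (real-time:
#'   the calibration run's end-point values are reused, matched by core).
#' @param marker_bands Bands for `"max3"` (default 398, 516, 640 cm^-1).
#' @param config A [preprocess_config()]; its range fields are ignored in
#'   favour of the searched `ranges`.
#' @param ranges List of candidate `c(lo, hi)` windows (cm^-1).
#' @param factors Candidate factor counts (default 1:3).
#' @param confidence Hotelling confidence (default 0.99).
#' @return A `coating_model`: the chosen [fit_pls()] fit, range, factor
#'   count, preprocessing config, normalization policy and per-core
#'   references, outlier report, grid-search table and training metadata.
#' @export
calibrate_run <- function(calibration, evaluation,
                          normalization = c("max", "max3"),
                          source = c("own_run_endpoint", "calibration_run"),
                          marker_bands = c(398, 516, 640),
                          config = preprocess_config(),
                          ranges = list(c(340, 1400)),
                          factors = 1:3,
                          confidence = 0.99) {
  normalization <- match.arg(normalization)
  source <- match.arg(source)
  cal_runs <- as_run_list(calibration)
  eval_runs <- as_run_list(evaluation)

  cal_pre <- lapply(cal_runs, preprocess_for_model, config = config,
                    normalization = normalization,
                    marker_bands = marker_bands)
  norm_refs <- lapply(cal_pre, `[[`, "norm_ref")
  names(norm_refs) <- vapply(cal_runs, run_core, character(1))

  eval_pre <- lapply(eval_runs, function(run) {
    ref <- if (source == "calibration_run") {
      lookup_norm_ref(norm_refs, run_core(run))
    } else NULL
    preprocess_for_model(run, config, normalization, marker_bands,
                         norm_ref = ref)
  })

  axis <- cal_pre[[1]]$series$axis
  X_cal <- do.call(rbind, lapply(cal_pre, function(p) p$series$spectra))
  y_cal <- unlist(lapply(cal_pre,
                         function(p) p$series$info$applied_mass_g))
  X_eval <- do.call(rbind, lapply(eval_pre, function(p) p$series$spectra))
  y_eval <- unlist(lapply(eval_pre,
                          function(p) p$series$info$applied_mass_g))
  total_mass <- cal_runs[[1]]$metadata$total_spray_mass %||%
    max(y_cal)

  gs <- grid_search(X_cal, y_cal, X_eval, y_eval, axis, ranges, factors,
                    total_mass, confidence)
  keep <- axis >= gs$best$range[1] & axis <= gs$best$range[2]
  cal_perf <- performance(y_cal[gs$best$retained], gs$best$fit$fitted,
                          total_mass, "calibration",
                          n_excluded = length(gs$best$report$excluded))
  structure(list(
    fit = gs$best$fit,
    range = gs$best$range,
    n_factors = gs$best$n_factors,
    channels = axis[keep],
    config = config,
    normalization = normalization,
    source = source,
    marker_bands = marker_bands,
    norm_refs = norm_refs,
    outliers = gs$best$report,
    grid = gs$results,
    calibration_performance = cal_perf,
    total_spray_mass = total_mass,
    confidence = confidence,
    training = list(cores = vapply(cal_runs, run_core, character(1)),
                    coating = cal_runs[[1]]$metadata$coating %||% NA_character_)
  ), class = "coating_model")
}

as_run_list <- function(x) {
  if (inherits(x, "spectral_series")) list(x) else x
}

run_core <- function(run) {
  run$metadata$core %||% NA_character_
}

lookup_norm_ref <- function(norm_refs, core) {
  if (length(norm_refs) == 1L) return(norm_refs[[1]])
  if (is.na(core) || is.null(norm_refs[[core]])) {
    stop("no calibration normalization reference for core `", core, "`",
         call. = FALSE)
  }
  norm_refs[[core]]
}

# Full chain minus the range crop (the grid search crops per candidate).
# The moving average runs before reference extraction so that the end-point
# normalization value is read off the 60 s-averaged final spectrum rather
# than a single noisy acquisition.
preprocess_for_model <- function(run, config, normalization, marker_bands,
                                 norm_ref = NULL) {
  diff <- differential_snv_series(run, config)
  avg <- moving_average_series(diff$series, config$moving_avg_window)
  if (is.null(norm_ref)) {
    norm_ref <- compute_norm_reference(avg, normalization,
                                       marker_bands = marker_bands)
  } else {
    norm_ref <- normalization_reference(norm_ref$method, norm_ref$value,
                                        marker_bands = norm_ref$marker_bands,
                                        source = "calibration_run")
  }
  out <- apply_normalization(avg, norm_ref)
  if (!is.na(config$sg_deriv)) {
    out <- savgol_series(out, config$sg_window, config$sg_polyorder,
                         config$sg_deriv)
  }
  list(series = out, core_ref = diff$core_ref, norm_ref = norm_ref)
}

#' @export
print.coating_model <- function(x, ...) {
  cat("<coating_model> ", x$normalization, " normalization (refs: ",
      x$source, "), range ", x$range[1], "-", x$range[2], " cm-1, ",
      x$n_factors, " factor(s)\n", sep = "")
  cat("  trained on core(s): ", paste(x$training$cores, collapse = ", "),
      "; coating: ", x$training$coating, "\n", sep = "")
  cat("  RMSEC ", signif(x$calibration_performance$rmse_pct, 3),
      "% of ", x$total_spray_mass, " g (",
      length(x$outliers$excluded), " outlier(s) excluded)\n", sep = "")
  invisible(x)
}

#' @export
glance.coating_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(normalization = x$normalization, source = x$source,
                   range_lo = x$range[1], range_hi = x$range[2],
                   n_factors = x$n_factors),
    x$calibration_performance[, c("r2", "rmse_pct", "se_pct",
                                  "n_samples", "n_excluded")]
  )
}

#' @export
tidy.coating_model <- function(x, ...) {
  tibble::tibble(wavenumber = x$channels, estimate = x$fit$coefficients)
}

#' Predict applied coating mass for a new run
#'
#' Applies the model's stored preprocessing chain to the run and evaluates
#' the regression vector. The run's own warm-up tail provides the mean core
#' spectrum; the normalization reference follows the model's `source`
#' policy (own end-point, or the stored calibration value matched by core).
#'
#' @param object A `coating_model` from [calibrate_run()].
#' @param newdata A raw [spectral_series()].
#' @param ... Unused.
#' @return Tibble with `spectrum_id`, `time_s`, `phase`, `observed_mass_g`
#'   and `predicted_mass_g`.
#' @export
predict.coating_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectral_series"))
  ref <- if (object$source == "calibration_run") {
    lookup_norm_ref(object$norm_refs, run_core(newdata))
  } else NULL
  pre <- preprocess_for_model(newdata, object$config, object$normalization,
                              object$marker_bands, norm_ref = ref)
  cropped <- crop_range(pre$series, object$range[1], object$range[2])
  if (length(cropped$axis) != length(object$channels) ||
      any(cropped$axis != object$channels)) {
    stop("incompatible axes: run channels do not match the model's range",
         call. = FALSE)
  }
  pred <- predict(object$fit, cropped$spectra)
  tibble::tibble(spectrum_id = newdata$info$spectrum_id,
                 time_s = newdata$info$time_s,
                 phase = newdata$info$phase,
                 observed_mass_g = newdata$info$applied_mass_g,
                 predicted_mass_g = pred)
}

#' @export
autoplot.coating_model <- function(object, predictions = NULL, ...) {
  df <- if (is.null(predictions)) {
    tibble::tibble(observed_mass_g = object$fit$y,
                   predicted_mass_g = object$fit$fitted,
                   set = "calibration")
  } else {
    dplyr::bind_rows(
      tibble::tibble(observed_mass_g = object$fit$y,
                     predicted_mass_g = object$fit$fitted,
                     set = "calibration"),
      dplyr::mutate(predictions[, c("observed_mass_g", "predicted_mass_g")],
                    set = "prediction"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed_mass_g,
                                   y = .data$predicted_mass_g,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "observed applied mass (g)",
                  y = "predicted applied mass (g)")
}

#' Experiment plan: calibration runs, test runs, normalization policy
#'
#' @param model_id Label for the plan (e.g. `"A1.2"`, `"APD1"`).
#' @param calibration_runs,test_runs Character vectors of run names (keys
#'   into the `runs` list, or file paths), disjoint, at least one each.
#' @param normalization `"max"` or `"max3"`.
#' @param source Normalization-reference source policy.
#' @param ranges,factors Grid-search candidates.
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(model_id, calibration_runs, test_runs,
                            normalization = "max",
                            source = "own_run_endpoint",
                            ranges = list(c(340, 1400)),
                            factors = 1:3) {
  if (length(calibration_runs) < 1L || length(test_runs) < 1L) {
    stop("need at least one calibration and one test run", call. = FALSE)
  }
  if (length(intersect(calibration_runs, test_runs)) > 0L) {
    stop("calibration and test runs must be disjoint", call. = FALSE)
  }
  structure(list(model_id = model_id,
                 calibration_runs = calibration_runs,
                 test_runs = test_runs,
                 normalization = match.arg(normalization, c("max", "max3")),
                 source = match.arg(source, c("own_run_endpoint",
                                              "calibration_run")),
                 ranges = ranges, factors = factors),
            class = "experiment_plan")
}

resolve_run <- function(name, runs) {
  if (!is.null(runs) && !is.null(runs[[name]])) return(runs[[name]])
  if (file.exists(name)) return(read_series(name))
  stop("run `", name, "` not found (not in the run list, no such file)",
       call. = FALSE)
}

#' Execute an experiment plan
#'
#' Preprocesses, calibrates (grid search + outlier exclusion), predicts
#' every test run, and computes calibration and prediction performance.
#' Optionally writes a JSON report and per-run prediction CSVs.
#'
#' @param plan An [experiment_plan()].
#' @param runs Named list of [spectral_series()] (run names are looked up
#'   here first, then treated as file paths).
#' @param config A [preprocess_config()].
#' @param confidence Hotelling confidence level.
#' @param out_dir Optional output directory for `report_<id>.json` and
#'   `predictions_<id>_<run>.csv`.
#' @return List with `model_id`, `model` (a `coating_model`),
#'   `performance` (tibble: calibration row plus one prediction row per
#'   test run) and `predictions` (named list of tibbles).
#' @export
run_experiment <- function(plan, runs = NULL, config = preprocess_config(),
                           confidence = 0.99, out_dir = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  cal <- lapply(plan$calibration_runs, resolve_run, runs = runs)
  test <- lapply(plan$test_runs, resolve_run, runs = runs)
  names(test) <- plan$test_runs

  model <- calibrate_run(cal, test,
                         normalization = plan$normalization,
                         source = plan$source,
                         config = config,
                         ranges = plan$ranges, factors = plan$factors,
                         confidence = confidence)

  preds <- lapply(test, function(run) predict(model, run))
  perf_rows <- list(
    dplyr::mutate(model$calibration_performance,
                  model_id = plan$model_id, test_run = NA_character_,
                  .before = 1))
  for (nm in names(preds)) {
    p <- preds[[nm]]
    if (!anyNA(p$observed_mass_g)) {
      tm <- test[[nm]]$metadata$total_spray_mass %||% model$total_spray_mass
      perf_rows[[length(perf_rows) + 1L]] <- dplyr::mutate(
        performance(p$observed_mass_g, p$predicted_mass_g, tm, "prediction"),
        model_id = plan$model_id, test_run = nm, .before = 1)
    }
  }
  out <- list(model_id = plan$model_id, model = model,
              performance = dplyr::bind_rows(perf_rows),
              predictions = preds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(model_id = plan$model_id,
           normalization = model$normalization, source = model$source,
           range = model$range, n_factors = model$n_factors,
           norm_refs = lapply(model$norm_refs, function(r) r$value),
           n_excluded = length(model$outliers$excluded),
           performance = out$performance),
      file.path(out_dir, paste0("report_", plan$model_id, ".json")),
      auto_unbox = TRUE, digits = NA)
    for (nm in names(preds)) {
      utils::write.csv(
        preds[[nm]][, c("time_s", "observed_mass_g", "predicted_mass_g")],
        file.path(out_dir, paste0("predictions_", plan$model_id, "_", nm,
                                  ".csv")),
        row.names = FALSE)
    }
  }
  out
}

#' Reproduce the full calibration/test design grid on simulated runs
#'
#' Simulates two batches of each of the three cores with the requested
#' coating, then runs the complete cross-core design: for the TiO2 enteric
#' coating, every (calibration core) x (normalization in max, max3) x
#' (test core) combination (18 single-core models) plus two pooled
#' three-core models with real-time calibration-run references (APD1 max,
#' APD2 max3), 20 models in all; for the TiO2-free CaCO3 coating, the nine
#' max-normalized single-core models.
#'
#' @param coating `"tio2_enteric"` or `"caco3_ir"`.
#' @param seed Base integer seed; each batch derives its own sub-seed.
#' @param ranges Candidate range list (defaults depend on the coating:
#'   marker-centred windows for TiO2, high-wavenumber windows for CaCO3).
#' @param factors Candidate factor counts (default 1:3).
#' @param config A [preprocess_config()].
#' @param run_config Optional function `(core, batch_seed)` returning a
#'   [coating_run_config()], to override simulation settings.
#' @return List with `grid` (summary tibble: one row per model x test run,
#'   with chosen range, factors, R2, RMSEC, SEC and RMSEP as % of applied
#'   mass), `reports` (per-model [run_experiment()] results) and `runs`.
#' @export
reproduce_design <- function(coating = c("tio2_enteric", "caco3_ir"),
                             seed = 1L,
                             ranges = NULL, factors = 1:3,
                             config = preprocess_config(),
                             run_config = NULL) {
  coating <- match.arg(coating)
  if (is.null(ranges)) {
    ranges <- if (coating == "tio2_enteric") {
      list(c(340, 1400), c(340, 900))
    } else {
      list(c(900, 1560), c(770, 1200))
    }
  }
  cores <- c(asa = "A", placebo = "P", diclofenac = "D")
  batches <- c(1L, 2L)
  if (is.null(run_config)) {
    run_config <- function(core, batch_seed) {
      coating_run_config(core = core, coating = coating, seed = batch_seed)
    }
  }
  runs <- list()
  i <- 0L
  for (core in names(cores)) {
    for (b in batches) {
      i <- i + 1L
      runs[[paste0(core, "_batch", b)]] <-
        simulate_run(run_config(core, as.integer(seed) * 100L + i))
    }
  }

  norm_idx <- if (coating == "tio2_enteric") {
    c(max = 1L, max3 = 2L)
  } else {
    c(max = 3L)
  }
  test_idx <- c(asa = 1L, placebo = 2L, diclofenac = 3L)

  plans <- list()
  for (cal_core in names(cores)) {
    for (norm in names(norm_idx)) {
      for (test_core in names(test_idx)) {
        id <- paste0(cores[[cal_core]], norm_idx[[norm]], ".",
                     test_idx[[test_core]])
        plans[[id]] <- experiment_plan(
          id,
          calibration_runs = paste0(cal_core, "_batch1"),
          test_runs = paste0(test_core, "_batch2"),
          normalization = norm, source = "own_run_endpoint",
          ranges = ranges, factors = factors)
      }
    }
  }
  if (coating == "tio2_enteric") {
    for (norm in c("max", "max3")) {
      id <- paste0("APD", if (norm == "max") 1L else 2L)
      plans[[id]] <- experiment_plan(
        id,
        calibration_runs = paste0(names(cores), "_batch1"),
        test_runs = paste0(names(cores), "_batch2"),
        normalization = norm, source = "calibration_run",
        ranges = ranges, factors = factors)
    }
  }

  reports <- lapply(plans, run_experiment, runs = runs, config = config)
  grid <- purrr::map_dfr(reports, function(rep) {
    perf <- rep$performance
    cal <- perf[perf$context == "calibration", ]
    prd <- perf[perf$context == "prediction", ]
    tibble::tibble(
      model_id = rep$model_id,
      coating = coating,
      calibration = paste(rep$model$training$cores, collapse = "+"),
      test_run = prd$test_run,
      normalization = rep$model$normalization,
      source = rep$model$source,
      range_lo = rep$model$range[1], range_hi = rep$model$range[2],
      n_factors = rep$model$n_factors,
      r2 = cal$r2,
      rmsec_pct = cal$rmse_pct,
      sec_pct = cal$se_pct,
      rmsep_pct = prd$rmse_pct,
      n_excluded = cal$n_excluded)
  })
  list(grid = grid, reports = reports, runs = runs)
}
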