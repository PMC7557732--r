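# Small, fast run configurations used across the unit tests. The full-scale
# defaults (1373 g at 11.5 g/min, 10 s cadence) are exercised in the
# end-to-end acceptance tests; unit tests use shorter runs on a narrower
# axis so each file stays in the seconds range.

quick_config <- function(core = "placebo", coating = "tio2_enteric",
                         total_spray_mass = 200, seed = 1L, ...) {
  axis_hi <- if (coating == "caco3_ir") 1200 else 800
  coating_run_config(core = core, coating = coating,
                     axis = seq(200, axis_hi, by = 2),
                     total_spray_mass = total_spray_mass,
                     seed = seed, ...)
}

quick_run <- function(...) simulate_run(quick_config(...))

# noise-free, jitter-free variant
clean_run <- function(...) {
  simulate_run(quick_config(noise_sd = 0, intensity_jitter_sd = 0, ...))
}

marker_channel <- function(series, band = 398) {
  which.min(abs(series$axis - band))
}
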