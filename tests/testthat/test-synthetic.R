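test_that("built-in core signatures carry their characteristic bands", {
  asa <- core_signature("asa")
  expect_true(1605 %in% asa$peaks$center)
  expect_true(any(asa$peaks$center >= 990 & asa$peaks$center <= 1340))

  dic <- core_signature("diclofenac")
  expect_true(all(c(441, 1046, 1578, 1605) %in% dic$peaks$center))

  plc <- core_signature("placebo")
  expect_lt(nrow(plc$peaks), nrow(asa$peaks))
  expect_lt(plc$base_intensity, dic$base_intensity)
  expect_lt(dic$base_intensity, asa$base_intensity)

  expect_error(core_signature("aspirin"), "unsupported core")
})

test_that("built-in coating signatures expose marker bands and amplitudes", {
  tio2 <- coating_signature("tio2_enteric")
  expect_identical(tio2$marker_bands, c(398, 516, 640))
  expect_true(all(tio2$marker_bands %in% tio2$peaks$center))

  caco3 <- coating_signature("caco3_ir")
  expect_identical(caco3$marker_bands, 1086)
  expect_true(all(c(280, 712, 1086) %in% caco3$peaks$center))

  # end-of-run dominant-peak amplitude contrast at matched conditions
  ratio <- max(tio2$peaks$amplitude) / max(caco3$peaks$amplitude)
  expect_equal(ratio, 2.7, tolerance = 0.02)
  expect_true(all(purrr::map2_lgl(
    tio2$peaks$amplitude[match(c(398, 516, 640), tio2$peaks$center)],
    caco3$peaks$amplitude[match(c(280, 712, 1086), caco3$peaks$center)],
    `>`)))

  expect_error(coating_signature("opadry"), "unsupported coating")
})

test_that("core spectra preserve the intensity ordering asa > diclofenac > placebo", {
  axis <- seq(200, 1800, by = 1)
  means <- vapply(c("asa", "diclofenac", "placebo"), function(nm) {
    mean(signature_spectrum(core_signature(nm), axis))
  }, numeric(1))
  expect_true(means["asa"] > means["diclofenac"])
  expect_true(means["diclofenac"] > means["placebo"])
})

test_that("simulated runs have the configured phase structure and cadence", {
  run <- quick_run()
  info <- run$info
  expect_identical(sum(info$phase == "warmup"), 8L)
  expect_true(all(info$applied_mass_g[info$phase == "warmup"] == 0))
  expect_true(all(diff(info$applied_mass_g) >= 0))
  expect_equal(max(info$applied_mass_g), 200)
  expect_equal(unique(diff(info$time_s)), 10)

  # spray-phase spectrum count follows from rate, mass and cadence
  cfg <- coating_run_config(spray_rate = 11.5, total_spray_mass = 1373,
                            spectrum_interval = 10)
  run_full <- simulate_run(cfg)
  expect_identical(sum(run_full$info$phase == "spray"),
                   as.integer(ceiling(1373 / 11.5 * 60 / 10)))  # = 717
  expect_identical(sum(run_full$info$phase == "spray"), 717L)
})

test_that("simulation is deterministic given the seed", {
  r1 <- quick_run(seed = 42)
  r2 <- quick_run(seed = 42)
  expect_identical(r1$spectra, r2$spectra)
  expect_identical(r1$info, r2$info)
  r3 <- quick_run(seed = 43)
  expect_false(identical(r1$spectra, r3$spectra))
})

test_that("simulate_run does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(quick_run(seed = 99))
  expect_identical(before, .Random.seed)
})

test_that("marker growth is linear in applied mass in the noise-free limit", {
  run <- clean_run(core_attenuation = 0)
  core_only <- run$spectra[1, ]
  ch <- marker_channel(run, 398)
  net <- run$spectra[, ch] - core_only[ch]
  # exactly proportional to applied mass
  expect_equal(net, max(net) * run$info$applied_mass_g / 200,
               tolerance = 1e-12)
})

test_that("coating contribution is exactly zero during warm-up", {
  run <- clean_run()
  warm <- run$spectra[run$info$phase == "warmup", , drop = FALSE]
  expect_true(all(abs(sweep(warm, 2, warm[1, ])) < 1e-12))
  # warm-up equals the pure core + baseline spectrum
  core_axis <- signature_spectrum(core_signature("placebo"), run$axis)
  expect_equal(unname(warm[1, ]), core_axis, tolerance = 1e-12)
})

test_that("invalid run configurations are rejected", {
  expect_error(coating_run_config(spray_rate = 0), "invalid config")
  expect_error(coating_run_config(total_spray_mass = -5), "invalid config")
  expect_error(coating_run_config(axis = c(1, 1, 2)), "invalid config")
})

test_that("tidy() flattens a series with aligned labels", {
  run <- clean_run()
  td <- tidy(run)
  expect_identical(nrow(td), n_spectra(run) * length(run$axis))
  one <- dplyr::filter(td, spectrum_id == run$info$spectrum_id[3])
  expect_equal(one$intensity, unname(run$spectra[3, ]))
  expect_equal(unique(one$applied_mass_g), run$info$applied_mass_g[3])
})
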