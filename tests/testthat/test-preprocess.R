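test_that("snv centers and scales to the sample convention", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "degenerate")
  expect_error(snv(3), "length")

  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(100, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    z <- snv(x)
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
  }
})

test_that("snv is idempotent and affine-invariant", {
  set.seed(12)
  x <- rnorm(200)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-10)
  for (i in 1:5) {
    a <- runif(1, 0.01, 100); b <- runif(1, -50, 50)
    expect_equal(snv(a * x + b), snv(x), tolerance = 1e-10)
  }
})

test_that("snv_series matches per-spectrum snv", {
  run <- quick_run(total_spray_mass = 30)
  out <- snv_series(run)
  expect_equal(out$spectra[4, ], snv(run$spectra[4, ]))
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
  i <- 1:100
  d2 <- savgol_derivative(i^2, window = 21, polyorder = 2, deriv = 2)
  expect_equal(d2[11:90], rep(2, 80), tolerance = 1e-10)

  lin <- savgol_derivative(3 * i + 7, window = 21, polyorder = 2, deriv = 2)
  expect_lt(max(abs(lin[11:90])), 1e-10)
})

test_that("Savitzky-Golay derivative agrees with finite differences on sin", {
  h <- 0.01
  x <- seq(0, 2 * pi, by = h)
  y <- sin(x)
  d2 <- savgol_derivative(y, window = 21, polyorder = 2, deriv = 2) / h^2
  fd <- (y[1:(length(y) - 2)] - 2 * y[2:(length(y) - 1)] +
           y[3:length(y)]) / h^2
  interior <- 11:(length(y) - 10)
  expect_lt(max(abs(d2[interior] - fd[interior - 1])), 1e-3)
})

test_that("Savitzky-Golay filtering is linear", {
  set.seed(13)
  x <- rnorm(150); y <- rnorm(150)
  a <- 2.5; b <- -1.3
  expect_equal(savgol_derivative(a * x + b * y),
               a * savgol_derivative(x) + b * savgol_derivative(y),
               tolerance = 1e-10)
})

test_that("savgol matrix path equals the per-spectrum filter", {
  run <- quick_run(total_spray_mass = 30)
  out <- savgol_series(run)
  for (i in c(1, 7, n_spectra(run))) {
    expect_equal(out$spectra[i, ], savgol_derivative(run$spectra[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("savgol rejects invalid windows", {
  expect_error(savgol_derivative(1:10, window = 21), "shorter")
  expect_error(savgol_derivative(1:100, window = 20), "odd")
  expect_error(savgol_derivative(1:100, window = 21, polyorder = 2,
                                 deriv = 3), "deriv")
})

test_that("trailing moving average has the documented window semantics", {
  # scalar series: two-channel spectra so the series constructor accepts it
  vals <- 1:10
  info <- tibble::tibble(spectrum_id = sprintf("s%02d", 1:10),
                         time_s = 0:9, phase = "spray",
                         applied_mass_g = as.numeric(1:10))
  s <- spectral_series(c(100, 101), cbind(vals, vals), info)
  out <- moving_average_series(s, 6)
  expect_equal(out$spectra[10, 1], mean(5:10))  # = 7.5
  expect_equal(out$spectra[3, 1], mean(1:3))    # shorter prefix window
  expect_equal(out$info$applied_mass_g, info$applied_mass_g)

  expect_identical(moving_average_series(s, 1)$spectra, s$spectra)

  const <- spectral_series(c(100, 101), cbind(rep(4, 10), rep(4, 10)), info)
  expect_equal(moving_average_series(const, 6)$spectra, const$spectra)
})

test_that("full-window moving average conserves the channel-wise mean", {
  run <- quick_run(total_spray_mass = 30)
  w <- 6L
  out <- moving_average_series(run, w)
  n <- n_spectra(run)
  # mean of outputs with complete windows equals mean over their inputs
  expect_equal(colMeans(out$spectra[w:n, , drop = FALSE]),
               colMeans(sapply(seq_len(ncol(run$spectra)), function(j) {
                 vapply(w:n, function(t) mean(run$spectra[(t - w + 1):t, j]),
                        numeric(1))
               })), tolerance = 1e-12)
})

test_that("core reference averages the SNV of the last n warm-up spectra", {
  run <- clean_run()
  ref <- compute_core_reference(run, 8)
  expect_identical(length(ref$mean_spectrum), length(run$axis))
  # noise-free warm-up spectra are identical: reference = SNV of any one
  expect_equal(ref$mean_spectrum, snv(run$spectra[1, ]), tolerance = 1e-12)
  expect_identical(ref$n_source_spectra, 8L)

  expect_error(compute_core_reference(run, 9), "insufficient warm-up")
})

test_that("antisymmetric SNV warm-up pair averages to a zero reference", {
  v <- snv(sin(seq_len(50)))
  s1 <- v * 2 + 5           # SNV(s1) = v
  s2 <- -v * 0.5 + 1        # SNV(s2) = -v
  info <- tibble::tibble(spectrum_id = c("a", "b"), time_s = c(0, 10),
                         phase = "warmup", applied_mass_g = c(0, 0))
  s <- spectral_series(seq_len(50), rbind(s1, s2), info)
  ref <- compute_core_reference(s, 2)
  expect_lt(max(abs(ref$mean_spectrum)), 1e-10)
})

test_that("differential of noise-free warm-up spectra is zero", {
  run <- clean_run()
  ref <- compute_core_reference(run, 8)
  d <- differential_spectrum(snv(run$spectra[3, ]), ref)
  expect_lt(max(abs(d)), 1e-10)

  expect_error(differential_spectrum(rnorm(10), ref), "incompatible axes")
})

test_that("differential marker intensity is non-decreasing without noise", {
  run <- clean_run()
  d <- differential_snv_series(run)$series
  ch <- marker_channel(d, 398)
  expect_true(all(diff(d$spectra[d$info$phase == "spray", ch]) > -1e-12))
})

test_that("crop_range keeps inclusive bounds and rejects empty overlap", {
  run <- quick_run(total_spray_mass = 30)
  cr <- crop_range(run, 340, 700)
  expect_true(all(cr$axis >= 340 & cr$axis <= 700))
  expect_true(340 %in% cr$axis && 700 %in% cr$axis)

  full <- crop_range(run, min(run$axis), max(run$axis))
  expect_identical(full$spectra, run$spectra)

  expect_error(crop_range(run, 2000, 2100), "empty range")
  expect_error(crop_range(run, 700, 340), "`lo` must be <")

  v <- crop_range(run$spectra[1, ], 340, 700, axis = run$axis)
  expect_identical(v, unname(run$spectra[1, run$axis >= 340 &
                                              run$axis <= 700]))
})

test_that("the full preprocessing chain composes its stages in order", {
  run <- clean_run()
  cfg <- preprocess_config(range_lo = 340, range_hi = 700,
                           moving_avg_window = 6)
  diff <- differential_snv_series(run, cfg)
  avg <- moving_average_series(diff$series, 6)
  ref <- compute_max_reference(avg)
  out <- preprocess_series(run, cfg, norm_ref = ref)

  manual <- apply_normalization(avg, ref)
  manual <- savgol_series(manual, cfg$sg_window, cfg$sg_polyorder,
                          cfg$sg_deriv)
  manual <- crop_range(manual, 340, 700)
  expect_equal(out$series$spectra, manual$spectra, tolerance = 1e-12)
  expect_identical(out$series$axis, manual$axis)
})
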