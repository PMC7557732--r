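test_that("a single latent variable is recovered exactly", {
  set.seed(21)
  t_true <- rnorm(30)
  p_true <- rnorm(12)
  X <- outer(t_true, p_true)
  y <- 3 * t_true + 5
  fit <- fit_pls(X, y, 1)
  expect_lt(max(abs(fit$fitted - y)), 1e-10)
  expect_equal(glance(fit)$r2, 1, tolerance = 1e-10)
})

test_that("full-rank PLS training predictions equal the OLS oracle", {
  set.seed(22)
  for (i in 1:4) {
    n <- 25; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_pls(X, y, p)
    # normal-equation oracle on centered data
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    beta <- solve(crossprod(Xc), crossprod(Xc, yc))
    ols <- drop(Xc %*% beta) + mean(y)
    expect_equal(fit$fitted, ols, tolerance = 1e-8)
  }
})

test_that("a constant response yields a zero regression vector", {
  set.seed(23)
  X <- matrix(rnorm(60), 12, 5)
  fit <- fit_pls(X, rep(4.2, 12), 3)
  expect_equal(fit$coefficients, rep(0, 5))
  expect_equal(fit$fitted, rep(4.2, 12))
})

test_that("score vectors are mutually orthogonal", {
  set.seed(24)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- rnorm(40)
  fit <- fit_pls(X, y, 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("training RMSEC is monotone non-increasing in the factor count", {
  set.seed(25)
  X <- matrix(rnorm(35 * 10), 35, 10)
  y <- rnorm(35)
  rmse <- vapply(1:8, function(a) {
    glance(fit_pls(X, y, a))$rmsec_g
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("predictions are invariant to a channel pattern removed by centering", {
  set.seed(26)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  offset <- rnorm(8)
  fit1 <- fit_pls(X, y, 3)
  Xs <- sweep(X, 2, offset, `+`)
  fit2 <- fit_pls(Xs, y, 3)
  newx <- rnorm(8)
  expect_equal(predict(fit1, newx), predict(fit2, newx + offset),
               tolerance = 1e-8)
})

test_that("predict reproduces fitted values and handles degenerate input", {
  set.seed(27)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 2)
  expect_equal(predict(fit, X), fit$fitted, tolerance = 1e-12)
  expect_equal(predict(fit, fit$x_mean), fit$y_mean, tolerance = 1e-12)
  expect_error(predict(fit, rnorm(5)), "incompatible axes")
})

test_that("rank and sample preconditions are enforced", {
  set.seed(28)
  expect_error(fit_pls(matrix(rnorm(30), 10, 3), rnorm(10), 4),
               "rank-deficient")
  expect_error(fit_pls(matrix(rnorm(12), 4, 3), rnorm(4), 0), ">= 1")
  expect_error(fit_pls(matrix(rnorm(6), 2, 3), rnorm(2), 2), "samples")
  expect_error(fit_pls(matrix(2, 10, 3), rnorm(10), 1), "rank-deficient")
  # requesting more factors than the matrix rank exhausts X
  X1 <- outer(rnorm(10), rnorm(5))
  expect_error(fit_pls(X1, drop(X1[, 1]) + rnorm(10, sd = 1e-9), 3),
               "rank-deficient")
})

test_that("NIPALS agrees with an independent PLS implementation", {
  set.seed(29)
  X <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(NULL, paste0("ch", 1:12)))
  y <- rnorm(40)
  fit <- fit_pls(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  ref_pred <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(fit$fitted), unname(ref_pred), tolerance = 1e-6)
})

test_that("Hotelling T2 vanishes at the score origin and ties for identical samples", {
  set.seed(30)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 2)
  # the training mean projects to the score-space origin: T2 = 0
  rep_mean <- hotelling_t2(fit, newdata = matrix(fit$x_mean, 1))
  expect_lt(rep_mean$t2$t2, 1e-20)
  # identical samples share a score vector, hence a single T2 value
  dup <- X[3, , drop = FALSE][rep(1, 5), ]
  rep_dup <- hotelling_t2(fit, newdata = dup)
  expect_lt(diff(range(rep_dup$t2$t2)), 1e-12)
  expect_true(all(rep_dup$t2$t2 >= 0))
})

test_that("the mean training T2 equals A(n-1)/n", {
  set.seed(31)
  for (A in c(2, 4)) {
    n <- 30
    X <- matrix(rnorm(n * 10), n, 10)
    y <- rnorm(n)
    fit <- fit_pls(X, y, A)
    rep <- hotelling_t2(fit)
    expect_equal(mean(rep$t2$t2), A * (n - 1) / n, tolerance = 1e-10)
  }
})

test_that("a constructed 10-sd outlier is flagged at 99% confidence", {
  set.seed(32)
  n <- 40
  t1 <- rnorm(n); t2v <- rnorm(n)
  X <- outer(t1, rnorm(10)) + outer(t2v, rnorm(10)) +
    matrix(rnorm(n * 10, sd = 0.01), n, 10)
  y <- t1 + 0.5 * t2v
  fit <- fit_pls(X, y, 2)
  # displace one sample 10 score-sd along factor 1
  s1 <- sd(fit$scores[, 1])
  w1 <- fit$weights[, 1]
  Xout <- rbind(X, X[1, ] + 10 * s1 * w1)
  yout <- c(y, y[1])
  fit2 <- fit_pls(Xout, yout, 2)
  rep2 <- hotelling_t2(fit2, confidence = 0.99)
  expect_true((n + 1) %in% rep2$excluded)

  # threshold -> infinity: nothing flagged
  rep_inf <- hotelling_t2(fit2, confidence = 1)
  expect_identical(rep_inf$excluded, integer(0))
  expect_identical(rep_inf$threshold, Inf)
})

test_that("outlier exclusion refits once and is a no-op without outliers", {
  set.seed(33)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  res <- fit_with_outlier_exclusion(X, y, 2, confidence = 1)
  expect_identical(res$retained, 1:30)
  expect_equal(res$fit$coefficients, fit_pls(X, y, 2)$coefficients)

  # corrupt 5 early samples far outside the score cloud
  t1 <- rnorm(60)
  Xc <- outer(t1, rnorm(8)) + matrix(rnorm(60 * 8, sd = 0.05), 60, 8)
  yc <- 2 * t1
  Xc[1:5, ] <- Xc[1:5, ] + outer(rep(12, 5), rnorm(8))
  res2 <- fit_with_outlier_exclusion(Xc, yc, 2, confidence = 0.99)
  expect_gte(length(intersect(res2$report$excluded, 1:5)), 4L)
  expect_false(any(res2$report$excluded %in% res2$retained))
})

test_that("grid search selects the informative spectral region", {
  run_cal <- quick_run(core_attenuation = 0, seed = 1)
  run_eval <- quick_run(core_attenuation = 0, seed = 2)
  pre <- function(run) {
    d <- differential_snv_series(run)$series
    nd <- apply_normalization(d, compute_max_reference(d))
    moving_average_series(savgol_series(nd), 6)
  }
  cal <- pre(run_cal); ev <- pre(run_eval)
  # markers live at 398/516/640; 200-330 cm-1 holds no core or coating band
  gs <- grid_search(cal$spectra, cal$info$applied_mass_g,
                    ev$spectra, ev$info$applied_mass_g, cal$axis,
                    ranges = list(c(340, 700), c(200, 330)),
                    factors = 2, total_mass = 200)
  expect_identical(gs$best$range, c(340, 700))
  expect_identical(nrow(gs$results), 2L)

  single <- grid_search(cal$spectra, cal$info$applied_mass_g,
                        ev$spectra, ev$info$applied_mass_g, cal$axis,
                        ranges = list(c(200, 330)), factors = 2,
                        total_mass = 200)
  expect_identical(single$best$range, c(200, 330))

  both <- grid_search(cal$spectra, cal$info$applied_mass_g,
                      ev$spectra, ev$info$applied_mass_g, cal$axis,
                      ranges = list(c(340, 700)), factors = c(2, 3),
                      total_mass = 200)
  expect_true(both$best$n_factors %in% c(2L, 3L))
})

test_that("grid search reports a structured failure when no candidate fits", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(
    grid_search(X, rnorm(10), X, rnorm(10), c(100, 200),
                ranges = list(c(300, 400)), factors = 2, total_mass = 1),
    "no valid model")
})
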