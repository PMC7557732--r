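#' Partial least squares regression by NIPALS
#'
#' Univariate-response PLS1 fitted from first principles. X columns are
#' centered (not variance-scaled: SNV already equalizes spectra row-wise,
#' and channel autoscaling would amplify noise channels); y is centered.
#' Each factor takes its weight vector as the X'y covariance direction,
#' which for a single response makes NIPALS fully deterministic (no random
#' initialization, no iteration needed), then deflates X by the extracted
#' score/loading pair.
#'
#' @param X Numeric matrix of preprocessed spectra (rows = samples).
#' @param y Numeric response (applied coating mass, g).
#' @param n_factors Number of latent factors (>= 1).
#' @return A `pls_fit` object: centering vectors, per-factor `weights`,
#'   `x_loadings`, `y_loadings`, training `scores`, the overall regression
#'   vector `coefficients`, `fitted` values and bookkeeping.
#' @export
fit_pls <- function(X, y, n_factors) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  n_factors <- as.integer(n_factors)
  if (length(y) != n) stop("rows(X) must equal length(y)", call. = FALSE)
  if (n_factors < 1L) stop("`n_factors` must be >= 1", call. = FALSE)
  if (n < n_factors + 1L) {
    stop("need at least n_factors + 1 samples (", n_factors + 1L,
         "), have ", n, call. = FALSE)
  }
  if (n_factors > p) {
    stop("rank-deficient: n_factors exceeds the number of channels",
         call. = FALSE)
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  x_scale <- sqrt(sum(Xc^2))
  if (x_scale == 0) {
    stop("rank-deficient: X has no variance after centering", call. = FALSE)
  }

  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  Xa <- Xc; ya <- yc
  a_used <- 0L
  for (a in seq_len(n_factors)) {
    if (sqrt(sum(Xa^2)) < 1e-12 * x_scale) {
      stop("rank-deficient: X exhausted after ", a_used, " factor(s)",
           call. = FALSE)
    }
    w <- drop(crossprod(Xa, ya))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14 * x_scale * max(1, sqrt(sum(yc^2)))) {
      break  # no covariance left with y (e.g. constant response)
    }
    w <- w / wn
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-24 * x_scale^2) break
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    a_used <- a
  }

  if (a_used == 0L) {
    B <- numeric(p)
  } else {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    B <- drop(W %*% solve(crossprod(P, W), q))
  }
  fitted <- drop(Xc %*% B) + y_mean
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 weights = if (a_used) W else matrix(0, p, 0L),
                 x_loadings = if (a_used) P else matrix(0, p, 0L),
                 y_loadings = q[seq_len(a_used)],
                 scores = if (a_used) Tm else matrix(0, n, 0L),
                 coefficients = B, n_factors = a_used,
                 n_factors_requested = n_factors,
                 fitted = fitted, y = y, n_samples = n),
            class = "pls_fit")
}

#' Predict applied mass from preprocessed spectra
#'
#' @param object A [fit_pls()] model.
#' @param newdata Matrix of preprocessed spectra with the model's channels
#'   (a single spectrum may be given as a vector).
#' @param ... Unused.
#' @return Numeric vector of predicted masses (g):
#'   \eqn{\hat y = (x - \bar x) b + \bar y}.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("incompatible axes: model has ", length(object$x_mean),
         " channels, new spectra have ", ncol(newdata), call. = FALSE)
  }
  drop(sweep(newdata, 2L, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$n_factors, " factor(s), ", length(x$x_mean),
      " channels, ", x$n_samples, " training spectra\n", sep = "")
  res <- x$y - x$fitted
  cat("  training RMSE: ", signif(sqrt(mean(res^2)), 4), " g\n", sep = "")
  invisible(x)
}

#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$coefficients),
                 estimate = x$coefficients)
}

#' @export
glance.pls_fit <- function(x, ...) {
  res <- x$y - x$fitted
  tibble::tibble(
    n_factors = x$n_factors,
    n_samples = x$n_samples,
    r2 = if (stats::var(x$y) > 0) stats::cor(x$y, x$fitted)^2 else NA_real_,
    rmsec_g = sqrt(mean(res^2))
  )
}

#' Hotelling T-squared statistics on PLS scores
#'
#' For each sample, \eqn{T^2_i = \sum_a t_{ia}^2 / s_a^2} over the model's
#' factors, with \eqn{s_a^2} the sample variance of the training scores of
#' factor *a*. The critical value at confidence level \eqn{1-\alpha} with
#' *A* factors and *n* training samples is
#' \deqn{T^2_{crit} = \frac{A (n-1)(n+1)}{n (n-A)} F_{1-\alpha}(A, n-A).}
#' Samples above the threshold are flagged as strong outliers.
#'
#' @param fit A [fit_pls()] model.
#' @param newdata Optional matrix of preprocessed spectra to score; by
#'   default the training samples are assessed.
#' @param confidence Confidence level of the F-based threshold (default
#'   0.99; `1` disables flagging).
#' @return An `outlier_report`: list with `t2` (tibble `sample`, `t2`),
#'   `threshold`, `excluded` (indices above threshold) and `confidence`.
#' @export
hotelling_t2 <- function(fit, newdata = NULL, confidence = 0.99) {
  stopifnot(inherits(fit, "pls_fit"))
  A <- fit$n_factors
  n <- fit$n_samples
  if (A < 1L) stop("model has no factors", call. = FALSE)
  if (n < A + 2L) stop("need at least n_factors + 2 samples", call. = FALSE)
  s2 <- apply(fit$scores, 2L, stats::var)
  scores <- if (is.null(newdata)) {
    fit$scores
  } else {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
    R <- fit$weights %*% solve(crossprod(fit$x_loadings, fit$weights))
    sweep(as.matrix(newdata), 2L, fit$x_mean) %*% R
  }
  if (all(s2 == 0)) {
    # all training samples identical in score space: every T2 is zero
    t2 <- rep(0, nrow(scores))
  } else if (any(s2 == 0)) {
    stop("degenerate scores: zero variance in a factor", call. = FALSE)
  } else {
    t2 <- drop(scores^2 %*% (1 / s2))
  }
  threshold <- if (confidence >= 1) {
    Inf
  } else {
    A * (n - 1) * (n + 1) / (n * (n - A)) * stats::qf(confidence, A, n - A)
  }
  structure(list(t2 = tibble::tibble(sample = seq_along(t2), t2 = t2),
                 threshold = threshold,
                 excluded = which(t2 > threshold),
                 confidence = confidence),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", nrow(x$t2), " samples, threshold ",
      signif(x$threshold, 4), " (", x$confidence * 100, "% confidence), ",
      length(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Fit PLS with single-pass Hotelling outlier exclusion
#'
#' Fits, flags training samples whose T-squared exceeds the threshold, and
#' refits once on the retained samples (one pass, not iterated; strong
#' outliers typically sit at the unstable start of the process).
#'
#' @inheritParams fit_pls
#' @param confidence Hotelling confidence level (default 0.99).
#' @return List with `fit` (final [fit_pls()] model), `report` (the
#'   [hotelling_t2()] report of the initial fit) and `retained` indices.
#' @export
fit_with_outlier_exclusion <- function(X, y, n_factors, confidence = 0.99) {
  X <- as.matrix(X)
  fit0 <- fit_pls(X, y, n_factors)
  report <- hotelling_t2(fit0, confidence = confidence)
  if (length(report$excluded) == 0L) {
    return(list(fit = fit0, report = report, retained = seq_len(nrow(X))))
  }
  keep <- setdiff(seq_len(nrow(X)), report$excluded)
  if (length(keep) < n_factors + 1L) {
    stop("too few samples: outlier exclusion would leave ", length(keep),
         " < ", n_factors + 1L, call. = FALSE)
  }
  list(fit = fit_pls(X[keep, , drop = FALSE], y[keep], n_factors),
       report = report, retained = keep)
}

#' Spectral-range and factor-count grid search
#'
#' Exhaustively fits every candidate (range, factor count) pair on the
#' calibration spectra and evaluates the root-mean-square error of
#' prediction on the evaluation spectra, returning the argmin. Ties are
#' broken by fewer factors, then by the narrower range. Note that when the
#' evaluation set is the test batch this reproduces the original
#' optimize-on-the-test-batch protocol, which leaks test information into
#' model selection; pass an independent held-out run for a leak-free search.
#'
#' @param cal,eval Matrices of fully preprocessed (uncropped) spectra for
#'   calibration and evaluation, on `axis`.
#' @param y_cal,y_eval Applied-mass responses (g).
#' @param axis Wavenumber axis of the matrices.
#' @param ranges List of `c(lo, hi)` wavenumber windows.
#' @param factors Integer vector of candidate factor counts.
#' @param total_mass Total applied mass (g), the denominator of the
#'   percentage errors.
#' @param confidence Hotelling confidence for outlier exclusion.
#' @return List with `best` (list `range`, `n_factors`, `fit`, `report`,
#'   `rmsep_pct`) and `results` (tibble of all candidates).
#' @export
grid_search <- function(cal, y_cal, eval, y_eval, axis, ranges, factors,
                        total_mass, confidence = 0.99) {
  stopifnot(length(ranges) >= 1L, length(factors) >= 1L)
  rows <- list(); fits <- list(); errs <- character()
  k <- 0L
  for (rg in ranges) {
    keep <- axis >= rg[1] & axis <= rg[2]
    for (A in factors) {
      k <- k + 1L
      res <- tryCatch({
        fr <- fit_with_outlier_exclusion(cal[, keep, drop = FALSE], y_cal,
                                         A, confidence)
        pred <- predict(fr$fit, eval[, keep, drop = FALSE])
        rmsep <- sqrt(mean((pred - y_eval)^2)) / total_mass * 100
        list(ok = TRUE, fr = fr, rmsep = rmsep)
      }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
      if (res$ok) {
        fits[[k]] <- res$fr
        rows[[k]] <- tibble::tibble(
          range_lo = rg[1], range_hi = rg[2], n_factors = A,
          rmsep_pct = res$rmsep,
          n_excluded = length(res$fr$report$excluded))
      } else {
        errs <- c(errs, res$msg)
        rows[[k]] <- tibble::tibble(
          range_lo = rg[1], range_hi = rg[2], n_factors = A,
          rmsep_pct = NA_real_, n_excluded = NA_integer_)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  if (all(is.na(results$rmsep_pct))) {
    stop("no valid model: every candidate failed (first error: ",
         errs[1], ")", call. = FALSE)
  }
  ord <- order(results$rmsep_pct, results$n_factors,
               results$range_hi - results$range_lo)
  best_i <- ord[1]
  list(best = list(range = c(results$range_lo[best_i],
                             results$range_hi[best_i]),
                   n_factors = results$n_factors[best_i],
                   fit = fits[[best_i]]$fit,
                   report = fits[[best_i]]$report,
                   retained = fits[[best_i]]$retained,
                   rmsep_pct = results$rmsep_pct[best_i]),
       results = results)
}
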