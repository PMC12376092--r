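#' Configuration for Whittaker smoothing and airPLS baseline estimation
#'
#' @param lam Smoothness penalty weight (dimensionless, > 0).  The default
#'   `1e5` suits amide-I'-width spectra sampled on a ~1 cm^-1 grid; stiffer
#'   baselines need larger values.
#' @param max_iter Iteration cap for the airPLS reweighting loop (>= 1).
#' @param tol Relative termination threshold in (0, 1): the loop stops when
#'   the absolute mass of negative residuals falls below `tol * sum(|y|)`.
#' @param diff_order Order of the finite-difference roughness penalty
#'   (1, 2 or 3).  Order 2 leaves straight lines unpenalized.
#'
#' @return An object of class `airpls_config`.
#' @export
#' @examples
#' airpls_config()
#' airpls_config(lam = 1e6, diff_order = 2)
airpls_config <- function(lam = 1e5, max_iter = 50L, tol = 1e-3,
                          diff_order = 2L) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("`lam` must be a single positive number")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1")
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0 || tol >= 1)
    stop("`tol` must lie in (0, 1)")
  diff_order <- as.integer(diff_order)
  if (!(diff_order %in% 1:3)) stop("`diff_order` must be 1, 2 or 3")
  structure(list(lam = lam, max_iter = max_iter, tol = tol,
                 diff_order = diff_order), class = "airpls_config")
}

#' @export
print.airpls_config <- function(x, ...) {
  cat(sprintf("<airpls_config lam=%g, max_iter=%d, tol=%g, diff_order=%d>\n",
              x$lam, x$max_iter, x$tol, x$diff_order))
  invisible(x)
}

# Sparse d-th order difference penalty D'D for n points.
difference_penalty <- function(n, d) {
  D <- Matrix::Matrix(diff(diag(n), differences = d), sparse = TRUE)
  Matrix::crossprod(D)
}

#' Weighted Whittaker smoother
#'
#' Returns the vector `z` minimizing
#' `sum_i w_i (y_i - z_i)^2 + lam * sum_j (diff(z, d)_j)^2`,
#' obtained from the banded normal equations `(W + lam D'D) z = W y` with `W`
#' the diagonal weight matrix and `D` the d-th order difference operator.
#' This is the smoothing primitive inside the airPLS baseline estimator.
#'
#' @param values Numeric vector `y`, length n >= `diff_order + 1`.
#' @param weights Non-negative weights of the same length; must not be all
#'   zero.
#' @param config An [airpls_config()]; only `lam` and `diff_order` are used.
#' @return Numeric vector `z` of length n.
#' @export
#' @examples
#' y <- sin(seq(0, pi, length.out = 50)) + rnorm(50, sd = 0.05)
#' z <- whittaker_smooth(y, rep(1, 50), airpls_config(lam = 100))
whittaker_smooth <- function(values, weights, config = airpls_config()) {
  n <- length(values)
  if (length(weights) != n)
    stop("`values` and `weights` must have equal length")
  if (any(weights < 0)) stop("`weights` must be non-negative")
  if (all(weights == 0))
    stop("all-zero weights: the smoothing system is singular")
  if (n < config$diff_order + 1L)
    stop("need at least diff_order + 1 = ", config$diff_order + 1L, " points")
  A <- Matrix::Diagonal(x = weights) +
    config$lam * difference_penalty(n, config$diff_order)
  as.numeric(Matrix::solve(A, weights * values))
}

#' Adaptive iteratively reweighted penalized least-squares (airPLS) baseline
#'
#' Estimates a smooth baseline that hugs the lower envelope of a spectrum with
#' positive peaks.  Starting from uniform weights, each iteration `t` smooths
#' the data with [whittaker_smooth()], then down-weights points lying above
#' the current baseline (weight 0) and re-weights points below it by
#' `exp(t * |residual| / m)`, where `m` is the total mass of negative
#' residuals; the first and last points are pinned to the maximum weight so
#' the baseline cannot droop at cropped spectrum edges.  Iteration stops when
#' `m < tol * sum(|y|)` or at `max_iter`.
#'
#' On noisy spectra the exponential reweighting can degenerate: the weight
#' mass concentrates on the few most negative noise excursions and the
#' baseline runs away below the data.  The loop therefore also stops, with
#' the baseline of the previous iteration, once fewer than `max(4, 5%)` of
#' the points retain a negative residual -- at that stage the baseline
#' already hugs the lower envelope and further iterations only chase extreme
#' noise points (`meta$stop_reason = "envelope"`).
#'
#' Hitting the iteration cap is not an error: the current baseline is returned
#' with `meta$converged = FALSE` and `meta$stop_reason = "max_iter"`.
#'
#' @param spectrum An [axis_spectrum()] with role `linear_od`.
#' @param config An [airpls_config()].
#' @return An [axis_spectrum()] (role `linear_od`) holding the baseline on the
#'   same axis, with `meta` recording `lam`, `diff_order`, `iterations` and
#'   `converged`.
#' @export
airpls_baseline <- function(spectrum, config = airpls_config()) {
  stopifnot_spectrum(spectrum, "linear_od")
  y <- spectrum$values
  n <- length(y)
  if (n < config$diff_order + 2L)
    stop("spectrum too short for airPLS with diff_order ", config$diff_order)
  w <- rep(1, n)
  abs_y <- sum(abs(y))
  z_prev <- z <- y
  converged <- FALSE
  stop_reason <- "max_iter"
  iterations <- 0L
  min_neg <- max(4L, ceiling(0.05 * n))
  for (t in seq_len(config$max_iter)) {
    z_prev <- z
    z <- whittaker_smooth(y, w, config)
    iterations <- t
    d <- y - z
    neg <- d < 0
    m <- sum(abs(d[neg]))
    if (m < config$tol * abs_y) {
      converged <- TRUE
      stop_reason <- "residual_mass"
      break
    }
    if (t > 1L && sum(neg) < min_neg) {   # weight-concentration stall guard
      z <- z_prev
      iterations <- t - 1L
      converged <- TRUE
      stop_reason <- "envelope"
      break
    }
    if (t == config$max_iter) break
    w[!neg] <- 0
    w[neg] <- exp(pmin(t * abs(d[neg]) / m, 500))
    w[c(1L, n)] <- max(w)
  }
  axis_spectrum(spectrum$axis, z, role = "linear_od",
                meta = list(lam = config$lam, diff_order = config$diff_order,
                            iterations = iterations, converged = converged,
                            stop_reason = stop_reason))
}

#' Baseline-correct a linear OD spectrum
#'
#' Subtracts the [airpls_baseline()] estimate from the spectrum; the axis is
#' unchanged (no resampling happens inside baseline correction).
#'
#' @inheritParams airpls_baseline
#' @return An [axis_spectrum()] of the corrected values, with baseline
#'   diagnostics (`lam`, `iterations`, `converged`) in `meta` and the baseline
#'   itself in `meta$baseline`.
#' @export
correct_baseline <- function(spectrum, config = airpls_config()) {
  bl <- airpls_baseline(spectrum, config)
  meta <- bl$meta
  meta$baseline <- bl$values
  axis_spectrum(spectrum$axis, spectrum$values - bl$values,
                role = spectrum$role, meta = meta)
}
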