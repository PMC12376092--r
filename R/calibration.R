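#' Built-in alpha-helix calibration points from the [EK]_N model peptides
#'
#' The de novo [EK]_N peptide series (N repeats of the EAAAK motif, chain
#' lengths 8, 13, 18 and 23 residues for N = 1..4) provides the standard
#' alpha-helix TDS calibration: CD-derived helical residue counts of 0, 5.9,
#' 13.2 and 20.2 paired with measured transition dipole strengths of 0.13,
#' 0.15, 0.21 and 0.26 D^2 (replicate standard deviations 0.005, 0.01, 0.02,
#' 0.03 D^2).
#'
#' @return A data frame with columns `label`, `helical_residues`, `tds_D2`,
#'   `tds_sd_D2`.
#' @export
#' @examples
#' fit_calibration(ek_calibration_points())
ek_calibration_points <- function() {
  data.frame(
    label = c("EK1", "EK2", "EK3", "EK4"),
    helical_residues = c(0, 5.9, 13.2, 20.2),
    tds_D2 = c(0.13, 0.15, 0.21, 0.26),
    tds_sd_D2 = c(0.005, 0.01, 0.02, 0.03),
    stringsAsFactors = FALSE
  )
}

#' Read a calibration-points file
#'
#' CSV with header `label,helical_residues,tds_D2,tds_sd_D2` (the `tds_sd_D2`
#' column may be omitted).
#'
#' @param path Path to the CSV file.
#' @return A data frame in the format of [ek_calibration_points()].
#' @export
read_calibration_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("label", "helical_residues", "tds_D2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing calibration column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$tds_sd_D2)) df$tds_sd_D2 <- 0
  validate_calibration_points(df)
  df
}

validate_calibration_points <- function(points) {
  if (!is.data.frame(points))
    stop("calibration points must be a data frame")
  if (any(points$tds_D2 <= 0)) stop("calibration TDS values must be positive")
  if (any(points$helical_residues < 0))
    stop("helical residue counts must be non-negative")
  if (!is.null(points$tds_sd_D2) && any(points$tds_sd_D2 < 0))
    stop("TDS standard deviations must be non-negative")
  invisible(points)
}

#' Fit the linear TDS-vs-helical-length calibration
#'
#' Ordinary least squares of TDS (D^2) on the number of helical residues.
#' Unweighted by default; with `weighted = TRUE` each point is weighted by
#' `1/sd^2` (points with sd = 0 are rejected in that case).  A positive slope
#' is required of a valid alpha-helix calibration: vibrational delocalization
#' grows with continuous helix length, so TDS must increase with it.
#'
#' @param points Data frame with columns `helical_residues`, `tds_D2` and
#'   optionally `tds_sd_D2`, `label`; at least 3 points with at least 2
#'   distinct `helical_residues` values.
#' @param weighted Use `1/sd^2` weights? Default `FALSE`.
#' @return An object of class `helix_calibration` with fields `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `coef_cov` (2x2 covariance of
#'   intercept and slope), `r_squared`, `residual_sd`, `points`, `weighted`.
#' @export
#' @examples
#' cal <- fit_calibration(ek_calibration_points())
#' cal
fit_calibration <- function(points, weighted = FALSE) {
  validate_calibration_points(points)
  if (nrow(points) < 3L)
    stop("need at least 3 calibration points, got ", nrow(points))
  if (length(unique(points$helical_residues)) < 2L)
    stop("calibration points have no spread in helical_residues ",
         "(degenerate x variance)")
  w <- NULL
  if (weighted) {
    if (is.null(points$tds_sd_D2) || any(points$tds_sd_D2 <= 0))
      stop("weighted fit requires positive tds_sd_D2 for every point")
    w <- 1 / points$tds_sd_D2^2
  }
  fit <- stats::lm(tds_D2 ~ helical_residues, data = points, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    slope = unname(co["helical_residues", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["helical_residues", "Std. Error"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    coef_cov = unname(stats::vcov(fit)),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    points = points,
    weighted = isTRUE(weighted)
  ), class = "helix_calibration")
}

#' @export
print.helix_calibration <- function(x, ...) {
  cat(sprintf(
    "<helix_calibration TDS = %.4g + %.4g * residues (D^2); r^2 = %.3f, n = %d%s>\n",
    x$intercept, x$slope, x$r_squared, nrow(x$points),
    if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Predict maximum alpha-helix length from a measured TDS
#'
#' Inverts the calibration line: `length = (tds - intercept) / slope`.
#' Because vibrational delocalization is limited to regions of continuous
#' structure, the apparent TDS of an unresolved multi-helix protein reports
#' the longest helix present, so the prediction is of the maximum
#' alpha-helix length, not an average.
#'
#' First-order (delta-method) uncertainty combines the measurement
#' uncertainty `tds_sd` with the coefficient covariance of the fit.
#' Predictions below zero are reported as 0 with a `below_range` flag;
#' predictions beyond the largest calibration abscissa are flagged
#' `extrapolated` (not refused -- extrapolation beyond the calibration
#' peptides is often exactly the point).
#'
#' @param tds Measured TDS in D^2.
#' @param model A [helix_calibration()] with positive slope.
#' @param tds_sd Optional standard deviation of `tds` (D^2).
#' @return An object of class `helix_prediction` with fields `length`
#'   (residues), `se`, `tds`, `flags` (character vector, possibly empty).
#' @export
#' @examples
#' cal <- fit_calibration(ek_calibration_points())
#' predict_helix_length(0.21, cal, tds_sd = 0.006)
predict_helix_length <- function(tds, model, tds_sd = NULL) {
  if (!inherits(model, "helix_calibration"))
    stop("`model` must be a helix_calibration")
  if (model$slope <= 0)
    stop("calibration slope must be positive to invert for helix length")
  if (!is.numeric(tds) || length(tds) != 1L || tds <= 0)
    stop("`tds` must be a single positive number (D^2)")
  len <- (tds - model$intercept) / model$slope
  # delta method: gradient of (tds - b)/m wrt (b, m), plus measurement term
  g <- c(-1 / model$slope, -len / model$slope)
  var_fit <- as.numeric(t(g) %*% model$coef_cov %*% g)
  var_meas <- if (is.null(tds_sd)) 0 else (tds_sd / model$slope)^2
  se <- sqrt(var_fit + var_meas)
  flags <- character(0)
  if (len < 0) {
    flags <- c(flags, "below_range")
    len <- 0
  }
  if (len > max(model$points$helical_residues))
    flags <- c(flags, "extrapolated")
  structure(list(length = len, se = se, tds = tds, flags = flags),
            class = "helix_prediction")
}

#' @export
print.helix_prediction <- function(x, ...) {
  fl <- if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
        else ""
  cat(sprintf("<helix_prediction %.1f +/- %.1f residues from TDS %.3g D^2%s>\n",
              x$length, x$se, x$tds, fl))
  invisible(x)
}

#' Predict TDS from a helical length
#'
#' Forward evaluation of the calibration line,
#' `tds = intercept + slope * helical_residues`; the exact inverse of
#' [predict_helix_length()] on the fitted line.
#'
#' @param helical_residues Helix length in residues (>= 0); vectorized.
#' @param model A [helix_calibration()].
#' @return Predicted TDS in D^2.
#' @export
predict_tds <- function(helical_residues, model) {
  if (!inherits(model, "helix_calibration"))
    stop("`model` must be a helix_calibration")
  if (any(helical_residues < 0))
    stop("`helical_residues` must be non-negative")
  model$intercept + model$slope * helical_residues
}

#' Linear trend of amide I' frequency with helical length
#'
#' Fits the same OLS machinery to (helical residues, amide I' frequency)
#' pairs.  The result carries an explicit caveat flag: frequency redshifts
#' with helical length only for short soluble peptides; solvatochromic
#' shifts make it unreliable for globular or membrane proteins, which is why
#' length prediction uses TDS, not frequency.
#'
#' @param points Data frame with columns `helical_residues` and
#'   `frequency_cm1` (and optionally `label`).
#' @return A list of class `frequency_trend` with `slope` (cm^-1 per
#'   residue), `intercept`, `slope_se`, `intercept_se`, `r_squared`,
#'   `residual_sd`, `points`, and `caveat`.
#' @export
frequency_trend <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("helical_residues", "frequency_cm1") %in% names(points)))
    stop("`points` needs columns helical_residues and frequency_cm1")
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (length(unique(points$helical_residues)) < 2L)
    stop("degenerate x variance in helical_residues")
  fit <- stats::lm(frequency_cm1 ~ helical_residues, data = points)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    slope = unname(co["helical_residues", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["helical_residues", "Std. Error"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    points = points,
    caveat = paste("frequency-length correlation holds for short soluble",
                   "peptides only; unreliable for globular or membrane",
                   "proteins")
  ), class = "frequency_trend")
}

#' @export
print.frequency_trend <- function(x, ...) {
  cat(sprintf(
    "<frequency_trend freq = %.4g %+.4g * residues cm-1; r^2 = %.3f>\n",
    x$intercept, x$slope, x$r_squared))
  cat("  caveat:", x$caveat, "\n")
  invisible(x)
}
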