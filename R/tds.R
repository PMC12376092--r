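#' Diagonal slice of a 2D IR spectrum
#'
#' For every pump frequency lying inside the probe-axis range, reads the
#' Delta-OD value at equal pump and probe frequency, interpolating linearly
#' along the probe axis within that pump row, and returns its magnitude.
#' With the stored sign convention the diagonal is dominated by the negative
#' fundamental (bleach) lobe, so the magnitude returned is the fundamental
#' diagonal intensity entering the TDS ratio; the anharmonically shifted
#' overtone lobe lies off the diagonal and is ignored.
#'
#' @param spec2d A [grid2d_spectrum()].
#' @return An [axis_spectrum()] of `|Delta-OD(w, w)|` on the pump frequencies
#'   of the overlap.  A single-point overlap yields a degenerate length-1
#'   slice.
#' @export
diagonal_slice <- function(spec2d) {
  if (!inherits(spec2d, "grid2d_spectrum"))
    stop("`spec2d` must be a grid2d_spectrum")
  ov <- axis_intersection(spec2d$pump_axis, spec2d$probe_axis)
  if (length(ov) == 0L)
    stop("pump and probe axes do not overlap: no diagonal exists")
  rows <- match(ov, spec2d$pump_axis)
  vals <- vapply(seq_along(ov), function(i) {
    stats::approx(spec2d$probe_axis, spec2d$delta_od[rows[i], ],
                  xout = ov[i], method = "linear", rule = 1)$y
  }, numeric(1))
  vals <- abs(vals)
  if (length(ov) == 1L)           # boundary case: too short for the validator
    return(structure(list(axis = ov, values = vals, role = "linear_od",
                          meta = list(source = "diagonal_slice")),
                     class = "axis_spectrum"))
  axis_spectrum(ov, vals, role = "linear_od",
                meta = list(source = "diagonal_slice"))
}

#' Calibrant quantities for the TDS normalization
#'
#' Builds the record of calibrant quantities entering the TDS ratio from the
#' calibrant's 2D spectrum and its baseline-corrected linear OD:
#' the amide I' band maximum `omega_max` (argmax of the corrected linear OD,
#' which is smoother than the 2D diagonal), the diagonal magnitude
#' `|Delta-OD_c(omega_max, omega_max)|`, `OD_c(omega_max)`, and the
#' calibrant's known transition dipole strength.  The conventional calibrant
#' is N-methylacetamide (NMA), a single-amide model for an uncoupled amide I'
#' oscillator with a TDS of 0.12 D^2.
#'
#' @param spec2d_cal Calibrant [grid2d_spectrum()].
#' @param od_cal Calibrant linear OD ([axis_spectrum()], role `linear_od`),
#'   already baseline-corrected.
#' @param mu_sq Calibrant transition dipole strength in D^2 (default 0.12,
#'   the NMA value).
#' @return An object of class `calibrant_record` with fields `omega_max`,
#'   `delta_od_max`, `od_max`, `mu_sq`.
#' @export
calibrant_record <- function(spec2d_cal, od_cal, mu_sq = 0.12) {
  stopifnot_spectrum(od_cal, "linear_od")
  if (!is.numeric(mu_sq) || length(mu_sq) != 1L || mu_sq <= 0)
    stop("`mu_sq` must be a single positive number (D^2)")
  i <- which.max(od_cal$values)
  if (i == 1L || i == length(od_cal$values))
    stop("calibrant OD maximum falls on the axis boundary: the band is not ",
         "captured inside the measured window")
  omega_max <- od_cal$axis[i]
  od_max <- od_cal$values[i]
  if (od_max <= 0) stop("calibrant OD at its maximum must be positive")
  diag_cal <- diagonal_slice(spec2d_cal)
  delta_od_max <- stats::approx(diag_cal$axis, diag_cal$values,
                                xout = omega_max, rule = 1)$y
  if (is.na(delta_od_max))
    stop("calibrant 2D diagonal does not cover omega_max = ",
         format(omega_max), " cm-1")
  if (delta_od_max <= 0)
    stop("calibrant diagonal Delta-OD at omega_max must be positive")
  structure(list(omega_max = omega_max, delta_od_max = delta_od_max,
                 od_max = od_max, mu_sq = mu_sq),
            class = "calibrant_record")
}

#' @export
print.calibrant_record <- function(x, ...) {
  cat(sprintf(
    "<calibrant_record omega_max=%.5g cm-1, |dOD|=%.4g, OD=%.4g, mu^2=%.3g D^2>\n",
    x$omega_max, x$delta_od_max, x$od_max, x$mu_sq))
  invisible(x)
}

#' Transition dipole strength spectrum
#'
#' Computes the TDS spectrum
#' `d(w) = [|dOD_s(w,w)| / OD_s(w)] * [OD_c(wmax) / |dOD_c(wmax,wmax)|]
#'        * [I_pump(wmax) / I_pump(w)] * mu_cal^2`
#' on the sample diagonal axis restricted to the overlap with the OD and pump
#' axes.  Because both the 2D signal and the linear OD scale linearly with
#' concentration and path length, their ratio -- and hence `d(w)` -- is
#' independent of both; the calibrant factor converts the ratio to absolute
#' Debye^2 and the pump factor removes the spectral shape of the excitation
#' envelope.
#'
#' Points where the sample OD falls below `od_floor_frac` times its maximum
#' are masked (`NA`) rather than computed: the ratio diverges as OD tends to
#' zero and would only amplify noise there.
#'
#' @param diag Sample diagonal magnitude from [diagonal_slice()].
#' @param od Sample linear OD ([axis_spectrum()], role `linear_od`),
#'   baseline-corrected.
#' @param pump Pump intensity envelope ([axis_spectrum()], role `pump`),
#'   strictly positive on the overlap.
#' @param cal A [calibrant_record()].
#' @param od_floor_frac Masking threshold as a fraction of `max(OD)`
#'   (default 0.05).
#' @return An [axis_spectrum()] with role `tds` (units D^2); masked points are
#'   `NA`.
#' @export
tds_spectrum <- function(diag, od, pump, cal, od_floor_frac = 0.05) {
  stopifnot_spectrum(diag)
  stopifnot_spectrum(od, "linear_od")
  stopifnot_spectrum(pump, "pump")
  if (!inherits(cal, "calibrant_record"))
    stop("`cal` must be a calibrant_record")
  if (!is.numeric(od_floor_frac) || od_floor_frac < 0 || od_floor_frac >= 1)
    stop("`od_floor_frac` must lie in [0, 1)")
  ax <- axis_intersection(diag$axis, od$axis)
  ax <- axis_intersection(ax, pump$axis)
  if (length(ax) < 1L)
    stop("diagonal, OD and pump axes share no common range")
  dod <- abs(diag$values[match(ax, diag$axis)])
  od_s <- interp_values(od, ax)
  pump_s <- interp_values(pump, ax)
  pump_max <- stats::approx(pump$axis, pump$values, xout = cal$omega_max,
                            rule = 1)$y
  if (is.na(pump_max) || pump_max <= 0)
    stop("pump spectrum does not cover (or vanishes at) the calibrant ",
         "omega_max = ", format(cal$omega_max), " cm-1")
  keep <- od_s >= od_floor_frac * max(od_s)
  if (any(pump_s[keep] <= 0))
    stop("pump intensity must be strictly positive on the unmasked overlap")
  d <- rep(NA_real_, length(ax))
  d[keep] <- (dod[keep] / od_s[keep]) * (cal$od_max / cal$delta_od_max) *
    (pump_max / pump_s[keep]) * cal$mu_sq
  axis_spectrum(ax, d, role = "tds",
                meta = list(od_floor_frac = od_floor_frac,
                            omega_max = cal$omega_max,
                            mu_sq_calibrant = cal$mu_sq))
}

#' Read a per-mode TDS value inside an assignment window
#'
#' Locates the peak inside `window` as the argmax of a reference spectrum --
#' by default the TDS spectrum itself, optionally e.g. the 2D diagonal
#' magnitude -- over the unmasked points, and reports the TDS value there.
#' This is how per-structure values (an alpha-helix mode, a low-frequency
#' beta-sheet mode, ...) are extracted from a multi-peak TDS spectrum.
#'
#' @param tds TDS spectrum from [tds_spectrum()].
#' @param window Numeric `c(lo, hi)` wavenumber window (cm^-1).
#' @param reference Optional [axis_spectrum()] whose argmax locates the peak
#'   instead of the TDS spectrum's own maximum.
#' @param assignment Free-text label (e.g. `"alpha-helix"`).
#' @return An object of class `tds_peak` with fields `omega`, `tds`,
#'   `window`, `assignment`.
#' @export
peak_tds <- function(tds, window, reference = NULL, assignment = "") {
  stopifnot_spectrum(tds, "tds")
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be c(lo, hi) with lo < hi")
  sel <- which(tds$axis >= window[1] & tds$axis <= window[2] &
               !is.na(tds$values))
  if (length(sel) < 3L)
    stop("fewer than 3 unmasked TDS points inside the window [",
         window[1], ", ", window[2], "]")
  ref_vals <- if (is.null(reference)) {
    tds$values[sel]
  } else {
    stopifnot_spectrum(reference, arg = "reference")
    rv <- interp_values(reference, tds$axis[sel])
    if (anyNA(rv))
      stop("`reference` does not cover the unmasked window points")
    rv
  }
  i <- sel[which.max(ref_vals)]
  structure(list(omega = tds$axis[i], tds = tds$values[i],
                 window = as.numeric(window), assignment = assignment),
            class = "tds_peak")
}

#' @export
print.tds_peak <- function(x, ...) {
  lab <- if (nzchar(x$assignment)) paste0(" (", x$assignment, ")") else ""
  cat(sprintf("<tds_peak%s %.4g D^2 at %.5g cm-1, window [%g, %g]>\n",
              lab, x$tds, x$omega, x$window[1], x$window[2]))
  invisible(x)
}

#' Full TDS pipeline from raw inputs
#'
#' Convenience wrapper running the whole measurement chain: airPLS baseline
#' correction of the sample and calibrant linear ODs, calibrant record
#' extraction, sample diagonal slice, and the TDS ratio.
#'
#' @param sample_2d Sample [grid2d_spectrum()].
#' @param sample_od Sample linear OD, uncorrected.
#' @param cal_2d Calibrant [grid2d_spectrum()].
#' @param cal_od Calibrant linear OD, uncorrected.
#' @param pump Pump envelope ([axis_spectrum()], role `pump`).
#' @param baseline An [airpls_config()] for the OD baseline correction, or
#'   `NULL` to use the inputs as already corrected.
#' @param mu_sq Calibrant TDS in D^2 (default 0.12, NMA).
#' @param od_floor_frac Masking threshold, see [tds_spectrum()].
#' @return The TDS [axis_spectrum()].
#' @export
compute_tds <- function(sample_2d, sample_od, cal_2d, cal_od, pump,
                        baseline = airpls_config(), mu_sq = 0.12,
                        od_floor_frac = 0.05) {
  if (!is.null(baseline)) {
    sample_od <- correct_baseline(sample_od, baseline)
    cal_od <- correct_baseline(cal_od, baseline)
  }
  cal <- calibrant_record(cal_2d, cal_od, mu_sq = mu_sq)
  tds_spectrum(diagonal_slice(sample_2d), sample_od, pump, cal,
               od_floor_frac = od_floor_frac)
}
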