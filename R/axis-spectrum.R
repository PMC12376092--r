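#' Spectrum on a single frequency or wavelength axis
#'
#' `axis_spectrum()` builds the basic one-dimensional spectrum container used
#' throughout the package: a strictly monotonic axis (wavenumbers in cm^-1 for
#' IR roles, wavelengths in nm for CD) paired with values whose units depend on
#' the `role`.
#'
#' Roles and value units:
#' \describe{
#'   \item{`linear_od`}{optical density, dimensionless.}
#'   \item{`transmission`}{detected intensity, arbitrary units; must be
#'     strictly positive.}
#'   \item{`pump`}{pump-pulse intensity envelope, arbitrary units; must be
#'     non-negative.}
#'   \item{`tds`}{transition dipole strength, Debye^2; masked points are `NA`.}
#'   \item{`cd`}{ellipticity in millidegrees on a wavelength axis.}
#' }
#'
#' @param axis Numeric vector, strictly monotonic (ascending or descending),
#'   length >= 2.
#' @param values Numeric vector of the same length as `axis`.
#' @param role One of `"linear_od"`, `"transmission"`, `"pump"`, `"tds"`,
#'   `"cd"`.
#' @param meta Named list of free-form annotations.
#'
#' @return An object of class `axis_spectrum`: a list with elements `axis`,
#'   `values`, `role`, `meta`.  The axis is stored ascending; descending input
#'   is reversed together with its values.
#' @export
#' @examples
#' s <- axis_spectrum(seq(1600, 1700, 5), dnorm(seq(1600, 1700, 5), 1650, 10),
#'                    role = "linear_od")
#' s
axis_spectrum <- function(axis, values, role = c("linear_od", "transmission",
                                                 "pump", "tds", "cd"),
                          meta = list()) {
  role <- match.arg(role)
  axis <- as.numeric(axis)
  values <- as.numeric(values)
  if (length(axis) != length(values))
    stop("`axis` and `values` must have equal length, got ",
         length(axis), " and ", length(values))
  if (length(axis) < 2L)
    stop("an axis_spectrum needs at least 2 points, got ", length(axis))
  if (anyNA(axis) || !all(is.finite(axis)))
    stop("`axis` must be finite and non-missing")
  d <- diff(axis)
  if (all(d < 0)) {           # descending input: store ascending
    axis <- rev(axis)
    values <- rev(values)
  } else if (!all(d > 0)) {
    stop("`axis` must be strictly monotonic (duplicate or unordered values)")
  }
  if (role == "transmission" && !all(values > 0, na.rm = TRUE))
    stop("transmission spectra must be strictly positive")
  if (role == "pump" && !all(values >= 0, na.rm = TRUE))
    stop("pump spectra must be non-negative")
  if (!is.list(meta)) stop("`meta` must be a list")
  structure(list(axis = axis, values = values, role = role, meta = meta),
            class = "axis_spectrum")
}

#' @export
print.axis_spectrum <- function(x, ...) {
  unit <- if (x$role == "cd") "nm" else "cm-1"
  cat(sprintf("<axis_spectrum role=%s, %d points, axis %.6g..%.6g %s>\n",
              x$role, length(x$axis), min(x$axis), max(x$axis), unit))
  nm <- if (length(x$values[!is.na(x$values)]))
    range(x$values, na.rm = TRUE) else c(NA, NA)
  cat(sprintf("  values in [%.6g, %.6g]; %d masked\n",
              nm[1], nm[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.axis_spectrum <- function(x) length(x$axis)

is_axis_spectrum <- function(x) inherits(x, "axis_spectrum")

stopifnot_spectrum <- function(x, role = NULL, arg = deparse(substitute(x))) {
  if (!is_axis_spectrum(x))
    stop("`", arg, "` must be an axis_spectrum")
  if (!is.null(role) && !(x$role %in% role))
    stop("`", arg, "` must have role ", paste(role, collapse = " or "),
         ", got ", x$role)
  invisible(x)
}

# Linear interpolation onto `at`; extrapolation forbidden (NA outside range).
interp_values <- function(spectrum, at) {
  stats::approx(spectrum$axis, spectrum$values, xout = at,
                method = "linear", rule = 1)$y
}

# Points of `axis` that fall inside the closed range of `within` (a numeric
# axis).  Used to build common axes: operations restrict to the intersection,
# never extrapolate.
axis_intersection <- function(axis, within) {
  axis[axis >= min(within) & axis <= max(within)]
}

#' Optical density from sample and reference transmission
#'
#' Computes `OD(w) = -log10(I_sample(w) / I_reference(w))` on the part of the
#' sample axis covered by the reference, with the reference linearly
#' interpolated onto the sample grid.  This is how the linear OD entering the
#' TDS ratio is obtained from the transmitted probe intensity.
#'
#' @param transmission `axis_spectrum` with role `transmission` (the sample).
#' @param reference `axis_spectrum` with role `transmission` (the empty /
#'   solvent reference).
#' @return `axis_spectrum` with role `linear_od` on the common axis.
#' @export
#' @examples
#' w <- seq(1600, 1700, 2)
#' ref <- axis_spectrum(w, rep(1, length(w)), "transmission")
#' sam <- axis_spectrum(w, 10^(-0.3 * dnorm(w, 1650, 12) * 25),
#'                      "transmission")
#' od <- od_from_transmission(sam, ref)
od_from_transmission <- function(transmission, reference) {
  stopifnot_spectrum(transmission, "transmission")
  stopifnot_spectrum(reference, "transmission")
  ax <- axis_intersection(transmission$axis, reference$axis)
  if (length(ax) < 2L)
    stop("sample and reference transmission axes do not overlap")
  i_s <- transmission$values[match(ax, transmission$axis)]
  i_r <- interp_values(reference, ax)
  if (any(i_r <= 0) || any(i_s <= 0))
    stop("transmission must be strictly positive on the overlap")
  axis_spectrum(ax, -log10(i_s / i_r), role = "linear_od",
                meta = list(source = "od_from_transmission"))
}
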