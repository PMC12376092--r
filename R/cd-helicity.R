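#' Sample metadata for CD helicity estimation
#'
#' Holds the quantities needed to convert raw ellipticity into mean residue
#' ellipticity (MRE) and percent helicity: cuvette path length, molar peptide
#' concentration, residue count, temperature, and the empirical end-effect
#' constant `x_const` that corrects the theoretical helix maximum for
#' non-hydrogen-bonded carbonyls.  `x_const` is length dependent and
#' typically lies between 0 and 3; 2.5 is appropriate for peptides of
#' roughly 8-23 residues.
#'
#' @param path_length Path length in mm (> 0).
#' @param concentration Molar concentration in mol/L (> 0).
#' @param n_residues Integer residue count (>= 1).
#' @param temperature Temperature in degrees C.
#' @param x_const Empirical constant, `0 <= x_const < n_residues`.
#' @return An object of class `cd_sample_meta`.
#' @export
#' @examples
#' cd_sample_meta(path_length = 0.1, concentration = 1e-3, n_residues = 23)
cd_sample_meta <- function(path_length, concentration, n_residues,
                           temperature = 21, x_const = 2.5) {
  if (!is.numeric(path_length) || path_length <= 0)
    stop("`path_length` must be positive (mm)")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("`concentration` must be positive (mol/L)")
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 1L)
    stop("`n_residues` must be an integer >= 1")
  if (!is.numeric(x_const) || x_const < 0 || x_const >= n_residues)
    stop("`x_const` must satisfy 0 <= x_const < n_residues")
  structure(list(path_length = path_length, concentration = concentration,
                 n_residues = n_residues, temperature = temperature,
                 x_const = x_const), class = "cd_sample_meta")
}

#' @export
print.cd_sample_meta <- function(x, ...) {
  cat(sprintf(
    "<cd_sample_meta l=%g mm, C=%g M, n=%d residues, T=%g C, x=%g>\n",
    x$path_length, x$concentration, x$n_residues, x$temperature, x$x_const))
  invisible(x)
}

#' Mean residue ellipticity
#'
#' Converts measured ellipticity to mean residue ellipticity:
#' `MRE = theta / (l * C * n)` with `theta` in millidegrees, `l` in mm and
#' `C` in mol/L, giving deg cm^2/dmol (numerically identical to the textbook
#' `theta / (10 * l_cm * C * n)`).
#'
#' @param theta Measured ellipticity in millidegrees.
#' @param meta A [cd_sample_meta()].
#' @return Mean residue ellipticity in deg cm^2/dmol.
#' @export
#' @examples
#' m <- cd_sample_meta(0.1, 1e-3, 10)
#' mean_residue_ellipticity(-10, m)   # -10000 deg cm^2/dmol
mean_residue_ellipticity <- function(theta, meta) {
  if (!inherits(meta, "cd_sample_meta"))
    stop("`meta` must be a cd_sample_meta")
  theta / (meta$path_length * meta$concentration * meta$n_residues)
}

#' Theoretical maximum mean residue ellipticity of a perfect helix
#'
#' Length- and temperature-corrected theoretical MRE at 222 nm for a fully
#' helical peptide of `n` residues:
#' `theta_H = -40000 * (1 - x/n) + 100 * T`.
#' Shorter helices have shallower (less negative) maxima because a fixed
#' number `x` of carbonyls at the ends lack the helical hydrogen bond.
#'
#' @param meta A [cd_sample_meta()].
#' @return `theta_H` in deg cm^2/dmol (negative for any realistic n, T).
#' @export
#' @examples
#' theoretical_max_mre(cd_sample_meta(0.1, 1e-3, 23))   # about -33552
theoretical_max_mre <- function(meta) {
  if (!inherits(meta, "cd_sample_meta"))
    stop("`meta` must be a cd_sample_meta")
  # constructor guarantees x_const < n_residues, so the bracket stays positive
  -40000 * (1 - meta$x_const / meta$n_residues) + 100 * meta$temperature
}

#' Percent helicity from the 222 nm mean residue ellipticity
#'
#' `%helicity = 100 * MRE_222 / theta_H`.  Both quantities are negative for
#' helical content; a positive ratio of like signs gives the helical
#' fraction.  A negative ratio (MRE_222 of the "wrong" sign, a disordered
#' line shape) is clamped to 0 for reporting, with the raw ratio kept in the
#' `raw_percent` attribute for diagnostics.
#'
#' @param mre222 Mean residue ellipticity at 222 nm (deg cm^2/dmol).
#' @param theta_h Theoretical maximum from [theoretical_max_mre()]; must be
#'   nonzero.
#' @return Percent helicity (>= 0), with attribute `raw_percent`.
#' @export
percent_helicity <- function(mre222, theta_h) {
  if (!is.numeric(theta_h) || length(theta_h) != 1L || theta_h == 0)
    stop("`theta_h` must be a single nonzero number")
  raw <- 100 * mre222 / theta_h
  structure(max(raw, 0), raw_percent = raw)
}

#' Helical residue count from percent helicity
#'
#' `residues = percent/100 * n`, reported to 0.1 residue (round half up).
#'
#' @param percent Percent helicity (>= 0).
#' @param n_residues Chain length in residues (>= 1).
#' @return Helical residues, rounded to one decimal.
#' @export
#' @examples
#' helical_residues(88, 23)   # 20.2
helical_residues <- function(percent, n_residues) {
  if (any(percent < 0)) stop("`percent` must be non-negative")
  if (any(n_residues < 1)) stop("`n_residues` must be >= 1")
  round_half_up(percent / 100 * n_residues, 1L)
}

# round() ties to even; reported residue counts use conventional half-up.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Helicity estimate from a CD spectrum
#'
#' Reads the ellipticity at 222 nm from a CD spectrum (linear interpolation
#' if 222 nm is not a grid point), converts to mean residue ellipticity,
#' and applies the percent-helicity formulae.
#'
#' @param cd An [axis_spectrum()] with role `cd` (wavelength in nm,
#'   ellipticity in mdeg) covering 222 nm.
#' @param meta A [cd_sample_meta()].
#' @return An object of class `helicity_result` with fields `mre222`,
#'   `theta_h`, `percent_helicity`, `raw_percent`, `helical_residues`.
#' @export
helicity_from_cd <- function(cd, meta) {
  stopifnot_spectrum(cd, "cd")
  theta222 <- stats::approx(cd$axis, cd$values, xout = 222, rule = 1)$y
  if (is.na(theta222))
    stop("CD spectrum does not cover 222 nm")
  mre222 <- mean_residue_ellipticity(theta222, meta)
  theta_h <- theoretical_max_mre(meta)
  pct <- percent_helicity(mre222, theta_h)
  structure(list(mre222 = mre222, theta_h = theta_h,
                 percent_helicity = as.numeric(pct),
                 raw_percent = attr(pct, "raw_percent"),
                 helical_residues = helical_residues(as.numeric(pct),
                                                     meta$n_residues)),
            class = "helicity_result")
}

#' @export
print.helicity_result <- function(x, ...) {
  cat(sprintf(
    "<helicity_result %.1f%% helical (%.1f residues); [theta]222=%.5g, [theta]H=%.5g deg cm^2/dmol>\n",
    x$percent_helicity, x$helical_residues, x$mre222, x$theta_h))
  invisible(x)
}
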