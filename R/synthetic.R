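## Synthetic amide I' scenes with known ground truth.
##
## The generator emulates the observable structure of a TDS measurement --
## amide I' band shapes on 1600-1700 cm^-1, broad smooth baselines, a
## Gaussian pump envelope, and the |mu|^2 vs |mu|^4 scaling between the
## linear OD and the 2D diagonal -- so that a known TDS profile can be pushed
## through the full pipeline and recovered.  It is not a physics-based 2D IR
## response-function simulation: no pulse fields, no vibrational Hamiltonian,
## no orientational factors.

#' Specification of one amide I' band
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1, > 0).
#' @param od_amplitude Integrated band area in OD * cm^-1 (> 0): band line
#'   shapes are unit-area profiles scaled by this amplitude.
#' @param tds Ground-truth transition dipole strength of the band (D^2, > 0).
#' @param shape `"gaussian"`, `"lorentzian"`, or `"pseudo_voigt"`.
#' @param eta Lorentzian mixing fraction in `[0, 1]` for
#'   `shape = "pseudo_voigt"`.
#' @return An object of class `band_spec`.
#' @export
#' @examples
#' band_spec(center = 1640, fwhm = 25, od_amplitude = 5, tds = 0.2)
band_spec <- function(center, fwhm, od_amplitude, tds,
                      shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                      eta = 0.5) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("`fwhm` must be positive")
  if (od_amplitude <= 0) stop("`od_amplitude` must be positive")
  if (tds <= 0) stop("`tds` must be positive (D^2)")
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1]")
  structure(list(center = center, fwhm = fwhm, od_amplitude = od_amplitude,
                 tds = tds, shape = shape, eta = eta), class = "band_spec")
}

# Unit-area line-shape profile of a band at wavenumbers `w`.
band_profile <- function(band, w) {
  sigma <- band$fwhm / (2 * sqrt(2 * log(2)))
  gamma <- band$fwhm / 2
  g <- stats::dnorm(w, band$center, sigma)
  l <- (gamma / pi) / ((w - band$center)^2 + gamma^2)
  switch(band$shape,
         gaussian = g,
         lorentzian = l,
         pseudo_voigt = band$eta * l + (1 - band$eta) * g)
}

#' Specification of a complete synthetic scene
#'
#' Bundles everything needed to generate a consistent set of spectra: the
#' amide I' bands, a smooth baseline (polynomial plus optional broad Gaussian
#' background, emulating solvent and scatter drifts), additive noise levels,
#' the wavenumber axis, the pump envelope, and the random seed.
#'
#' The polynomial baseline is evaluated in the scaled coordinate
#' `u = (w - mid) / halfspan` (so `u` runs over \[-1, 1\] across the axis and
#' every coefficient is in OD units).
#'
#' @param bands List of [band_spec()] objects (possibly empty).
#' @param baseline_poly Polynomial coefficients, ascending powers of `u`.
#' @param baseline_bg Optional broad Gaussian background:
#'   `list(center, fwhm, amplitude)` with amplitude in OD (peak height).
#' @param noise_sd Gaussian noise SD on the linear OD (OD units, >= 0).
#' @param noise2d_sd Gaussian noise SD on the 2D Delta-OD matrix (>= 0).
#' @param axis `c(lo, hi, step)` in cm^-1; must cover every band center
#'   +/- 2 FWHM.
#' @param pump `list(center, fwhm)` of the Gaussian pump envelope (cm^-1).
#' @param seed Integer seed making every generated spectrum a deterministic
#'   function of the scene.
#' @return An object of class `scene_spec`.
#' @export
#' @examples
#' sc <- scene_spec(bands = list(band_spec(1640, 24, 5, 0.2)), seed = 7)
scene_spec <- function(bands = list(), baseline_poly = 0,
                       baseline_bg = NULL, noise_sd = 0, noise2d_sd = 0,
                       axis = c(1580, 1720, 1), pump = list(center = 1640,
                                                            fwhm = 120),
                       seed = 1L) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  if (!all(vapply(bands, inherits, logical(1), "band_spec")))
    stop("`bands` must be a list of band_spec objects")
  if (length(axis) != 3L || axis[2] <= axis[1] || axis[3] <= 0)
    stop("`axis` must be c(lo, hi, step) with lo < hi and step > 0")
  if (noise_sd < 0 || noise2d_sd < 0) stop("noise SDs must be non-negative")
  for (b in bands) {
    if (b$center - 2 * b$fwhm < axis[1] || b$center + 2 * b$fwhm > axis[2])
      stop("axis too narrow: band at ", b$center,
           " cm-1 needs coverage of center +/- 2*FWHM")
  }
  if (!is.null(baseline_bg) &&
      !all(c("center", "fwhm", "amplitude") %in% names(baseline_bg)))
    stop("`baseline_bg` needs center, fwhm, amplitude")
  if (!all(c("center", "fwhm") %in% names(pump)) || pump$fwhm <= 0)
    stop("`pump` needs center and positive fwhm")
  structure(list(bands = bands, baseline_poly = as.numeric(baseline_poly),
                 baseline_bg = baseline_bg, noise_sd = noise_sd,
                 noise2d_sd = noise2d_sd, axis = as.numeric(axis),
                 pump = pump, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec %d band(s), axis %g..%g by %g cm-1, noise_sd=%g, seed=%d>\n",
              length(x$bands), x$axis[1], x$axis[2], x$axis[3],
              x$noise_sd, x$seed))
  invisible(x)
}

scene_axis <- function(scene) seq(scene$axis[1], scene$axis[2], by = scene$axis[3])

scene_baseline <- function(scene, w) {
  mid <- mean(scene$axis[1:2])
  half <- diff(scene$axis[1:2]) / 2
  u <- (w - mid) / half
  bl <- rep(0, length(w))
  for (k in seq_along(scene$baseline_poly))
    bl <- bl + scene$baseline_poly[k] * u^(k - 1)
  bg <- scene$baseline_bg
  if (!is.null(bg)) {
    sigma <- bg$fwhm / (2 * sqrt(2 * log(2)))
    bl <- bl + bg$amplitude * exp(-(w - bg$center)^2 / (2 * sigma^2))
  }
  bl
}

# Noise-free band-only OD (the true baseline-corrected spectrum).
scene_band_od <- function(scene, w) {
  od <- rep(0, length(w))
  for (b in scene$bands) od <- od + b$od_amplitude * band_profile(b, w)
  od
}

# Ground-truth TDS profile: OD-weighted mean of band TDS values, mirroring
# how overlapping unresolved modes present one apparent TDS.
scene_truth_tds <- function(scene, w) {
  if (length(scene$bands) == 0L) return(rep(NA_real_, length(w)))
  num <- rep(0, length(w)); den <- rep(0, length(w))
  for (b in scene$bands) {
    wt <- b$od_amplitude * band_profile(b, w)
    num <- num + wt * b$tds
    den <- den + wt
  }
  ifelse(den > 0, num / den, NA_real_)
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate the linear OD spectrum of a scene
#'
#' Sum of the band line shapes plus the scene baseline plus i.i.d. Gaussian
#' noise (seeded by `scene$seed`).  The noise-free band-only truth and the
#' true baseline are stored in `meta` for validation.
#'
#' @param scene A [scene_spec()].
#' @return An [axis_spectrum()] with role `linear_od`.
#' @export
gen_linear_od <- function(scene) {
  if (!inherits(scene, "scene_spec")) stop("`scene` must be a scene_spec")
  w <- scene_axis(scene)
  truth <- scene_band_od(scene, w)
  bl <- scene_baseline(scene, w)
  noise <- if (scene$noise_sd > 0)
    with_seed(scene$seed, stats::rnorm(length(w), sd = scene$noise_sd))
  else rep(0, length(w))
  axis_spectrum(w, truth + bl + noise, role = "linear_od",
                meta = list(truth_od = truth, baseline_true = bl,
                            noise_sd = scene$noise_sd, seed = scene$seed))
}

#' Generate the pump intensity envelope of a scene
#'
#' Strictly positive Gaussian envelope on the scene axis, peak-normalized
#' to 1.
#'
#' @param scene A [scene_spec()].
#' @return An [axis_spectrum()] with role `pump`.
#' @export
gen_pump <- function(scene) {
  if (!inherits(scene, "scene_spec")) stop("`scene` must be a scene_spec")
  w <- scene_axis(scene)
  sigma <- scene$pump$fwhm / (2 * sqrt(2 * log(2)))
  v <- exp(-(w - scene$pump$center)^2 / (2 * sigma^2))
  axis_spectrum(w, v, role = "pump",
                meta = list(center = scene$pump$center,
                            fwhm = scene$pump$fwhm))
}

#' Generate a 2D IR spectrum consistent with a ground-truth TDS profile
#'
#' Inverts the TDS ratio: the diagonal magnitude is set to
#' `|dOD(w,w)| = d_true(w) * OD(w) * [I_pump(w)/I_pump(w_ref)] * S / mu^2`,
#' where `d_true` is the scene's ground-truth TDS profile (the OD-weighted
#' mean of band TDS values), `OD` the noise-free band-only linear OD, and
#' `S = dOD_c/OD_c` the instrument's 2D-to-1D conversion scale taken from the
#' calibrant record (or given directly as a number).  Running the generated
#' spectra back through [tds_spectrum()] therefore recovers `d_true`.
#'
#' Off the diagonal each pump row carries a peak-pair template: a negative
#' fundamental lobe centered on the diagonal and a positive overtone lobe
#' red-shifted along the probe axis by the anharmonicity (default 16 cm^-1,
#' typical for amide I').  The template is cosmetic -- only the diagonal
#' enters the TDS ratio -- but reproduces the blue/red peak-pair look of
#' measured spectra.
#'
#' @param scene A [scene_spec()] with at least one band.
#' @param od Noise-free band-only linear OD of the scene ([axis_spectrum()]);
#'   default `NULL` computes it from the scene.  Must be positive wherever a
#'   band has support.
#' @param pump Pump envelope; default `NULL` uses [gen_pump()] of the scene.
#' @param cal A [calibrant_record()], or a single positive number used
#'   directly as the conversion scale `S` (with `mu_sq` below).
#' @param mu_sq Calibrant TDS (D^2) when `cal` is numeric; ignored otherwise.
#' @param anharmonic_shift Probe red-shift of the overtone lobe (cm^-1).
#' @param lobe_fwhm Probe-axis FWHM of each lobe of the pair (cm^-1).
#' @return A [grid2d_spectrum()] whose `meta$truth_tds` holds the ground-truth
#'   TDS profile on the scene axis.
#' @export
gen_2d_from_truth <- function(scene, od = NULL, pump = NULL, cal = 1,
                              mu_sq = 0.12, anharmonic_shift = 16,
                              lobe_fwhm = 10) {
  if (!inherits(scene, "scene_spec")) stop("`scene` must be a scene_spec")
  if (length(scene$bands) == 0L)
    stop("scene has no bands: a 2D spectrum needs at least one")
  w <- scene_axis(scene)
  if (is.null(od)) {
    od_v <- scene_band_od(scene, w)
  } else {
    stopifnot_spectrum(od, "linear_od")
    od_v <- interp_values(od, w)
    support <- scene_band_od(scene, w) > 1e-6 * max(scene_band_od(scene, w))
    if (any(is.na(od_v[support])) || any(od_v[support] <= 0))
      stop("`od` contains zeros or gaps inside a band's support")
    od_v[is.na(od_v)] <- 0
  }
  if (is.null(pump)) pump <- gen_pump(scene)
  stopifnot_spectrum(pump, "pump")
  if (inherits(cal, "calibrant_record")) {
    scale <- cal$delta_od_max / cal$od_max
    mu_sq <- cal$mu_sq
    omega_ref <- cal$omega_max
  } else {
    if (!is.numeric(cal) || length(cal) != 1L || cal <= 0)
      stop("`cal` must be a calibrant_record or a single positive scale")
    scale <- cal
    omega_ref <- pump$axis[which.max(pump$values)]
  }
  pump_v <- interp_values(pump, w)
  if (anyNA(pump_v))
    stop("pump envelope does not cover the scene axis ",
         scene$axis[1], "..", scene$axis[2], " cm-1")
  pump_ref <- stats::approx(pump$axis, pump$values, xout = omega_ref,
                            rule = 1)$y
  if (is.na(pump_ref) || pump_ref <= 0)
    stop("pump envelope does not cover the reference frequency")
  d_true <- scene_truth_tds(scene, w)
  diag_mag <- ifelse(is.na(d_true), 0,
                     d_true * od_v * (pump_v / pump_ref) * scale / mu_sq)
  # peak-pair template along the probe axis, peak-normalized lobes
  lobe <- function(x) exp(-4 * log(2) * (x / lobe_fwhm)^2)
  offs <- outer(-w, w, `+`)               # probe - pump
  m <- (-lobe(offs) + lobe(offs + anharmonic_shift)) * diag_mag
  if (scene$noise2d_sd > 0)
    m <- m + with_seed(scene$seed + 1L,
                       matrix(stats::rnorm(length(m), sd = scene$noise2d_sd),
                              nrow = nrow(m)))
  grid2d_spectrum(w, w, m,
                  meta = list(truth_tds = list(axis = w, values = d_true),
                              scale = scale, mu_sq = mu_sq,
                              omega_ref = omega_ref,
                              anharmonic_shift = anharmonic_shift,
                              lobe_fwhm = lobe_fwhm))
}

#' Generate a synthetic CD spectrum with known helicity
#'
#' Builds a mean-residue-ellipticity curve as a mixture of fixed parametric
#' basis shapes -- a helix basis with negative bands at 208 and 222 nm and a
#' positive band near 193 nm, and a coil basis with a single negative band at
#' 198 nm (constructed to vanish exactly at 222 nm) -- scaled so the
#' noise-free MRE at 222 nm equals `frac_helix * theoretical_max_mre(meta)`.
#' The curve is then converted to raw ellipticity in millidegrees by
#' inverting the MRE definition, and seeded noise is added.
#'
#' @param frac_helix Helical fraction in `[0, 1]`.
#' @param meta A [cd_sample_meta()].
#' @param noise_sd Gaussian noise SD in mdeg (>= 0).
#' @param seed Integer seed.
#' @param axis Wavelength grid, default `seq(190, 250, 1)` nm.
#' @return An [axis_spectrum()] with role `cd`; `meta$frac_helix` holds the
#'   truth.
#' @export
gen_cd <- function(frac_helix, meta, noise_sd = 0, seed = 1L,
                   axis = seq(190, 250, 1)) {
  if (!is.numeric(frac_helix) || length(frac_helix) != 1L ||
      frac_helix < 0 || frac_helix > 1)
    stop("`frac_helix` must lie in [0, 1]")
  if (!inherits(meta, "cd_sample_meta"))
    stop("`meta` must be a cd_sample_meta")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  g <- function(l, c, s) exp(-(l - c)^2 / (2 * s^2))
  helix_raw <- function(l) g(l, 222, 7) + 0.95 * g(l, 208, 6) -
    1.3 * g(l, 193, 5.5)
  helix <- helix_raw(axis) / helix_raw(222)          # H(222) = 1 exactly
  coil_raw <- function(l) g(l, 198, 9) - g(222, 198, 9) * g(l, 222, 4)
  coil <- coil_raw(axis) / coil_raw(198)             # C(222) = 0 exactly
  theta_h <- theoretical_max_mre(meta)
  mre <- frac_helix * theta_h * helix +
    (1 - frac_helix) * (-12000) * coil
  theta <- mre * (meta$path_length * meta$concentration * meta$n_residues)
  if (noise_sd > 0)
    theta <- theta + with_seed(seed, stats::rnorm(length(axis),
                                                  sd = noise_sd))
  axis_spectrum(axis, theta, role = "cd",
                meta = list(frac_helix = frac_helix, noise_sd = noise_sd,
                            seed = seed))
}

#' Draw a random amide I' scene
#'
#' Deterministic function of `seed`: 1-3 bands with centers in 1615-1675
#' cm^-1, FWHM 15-30 cm^-1, peak OD 0.1-0.3 and TDS 0.12-0.35 D^2, over a
#' gentle linear drift plus a broad Gaussian background (the smooth residual
#' left by solvent subtraction).  Used by the recovery test suites.
#'
#' @param seed Integer seed.
#' @param n_bands Number of bands, or `NULL` to draw 1-3 at random.
#' @param noise_sd Linear-OD noise SD passed to the scene.
#' @return A [scene_spec()] (its own `seed` is derived from `seed`).
#' @export
random_scene <- function(seed, n_bands = NULL, noise_sd = 0) {
  with_seed(seed, {
    if (is.null(n_bands)) n_bands <- sample(1:3, 1)
    bands <- lapply(seq_len(n_bands), function(i) {
      fwhm <- stats::runif(1, 15, 30)
      peak_od <- stats::runif(1, 0.1, 0.3)
      sigma <- fwhm / (2 * sqrt(2 * log(2)))
      band_spec(center = stats::runif(1, 1615, 1675), fwhm = fwhm,
                od_amplitude = peak_od * sigma * sqrt(2 * pi),
                tds = stats::runif(1, 0.12, 0.35))
    })
    scene_spec(
      bands = bands,
      baseline_poly = c(stats::runif(1, 0, 0.1), stats::runif(1, -0.05, 0.05)),
      baseline_bg = list(center = stats::runif(1, 1550, 1750),
                         fwhm = stats::runif(1, 250, 400),
                         amplitude = stats::runif(1, 0, 0.05)),
      noise_sd = noise_sd,
      axis = c(1540, 1750, 1),
      seed = seed
    )
  })
}

#' Scene emulating the NMA calibrant
#'
#' Single uncoupled-amide band whose ground-truth TDS equals the calibrant
#' value, with no baseline: running it through the pipeline as a sample must
#' return `mu_sq` at the band maximum (self-calibration).
#'
#' @param mu_sq Calibrant TDS (D^2), default 0.12.
#' @param center Band center, default 1625 cm^-1.
#' @param seed Integer seed.
#' @return A [scene_spec()].
#' @export
calibrant_scene <- function(mu_sq = 0.12, center = 1625, seed = 1L) {
  scene_spec(bands = list(band_spec(center = center, fwhm = 24,
                                    od_amplitude = 3, tds = mu_sq)),
             axis = c(1560, 1720, 1), seed = seed)
}
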