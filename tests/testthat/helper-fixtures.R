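# Shared fixtures, all generated in code.

# One "instrument": a wide pump envelope plus an NMA-like calibrant
# measurement and its record.  Memoised so suites share a single build.
make_instrument <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cal_sc <- calibrant_scene()              # 0.12 D^2 band at 1625 cm-1
    pump <- gen_pump(scene_spec(axis = c(1540, 1750, 1), seed = 1L))
    od_cal <- gen_linear_od(cal_sc)          # no baseline, noise-free
    g2d_cal <- gen_2d_from_truth(cal_sc, pump = pump, cal = 0.05)
    cache <<- list(pump = pump, cal_scene = cal_sc, od_cal = od_cal,
                   g2d_cal = g2d_cal,
                   cal = calibrant_record(g2d_cal, od_cal))
    cache
  }
})

# Linear ramp plus two positive Gaussian peaks, noise-free; the canonical
# baseline-correction fixture with every truth component retained.
ramp_two_gauss <- function() {
  w <- seq(1580, 1720, 1)
  ramp <- 0.25 - 0.001 * (w - 1580)
  pk <- function(center, fwhm, height) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    height * exp(-(w - center)^2 / (2 * s^2))
  }
  peaks <- pk(1625, 18, 0.30) + pk(1660, 16, 0.20)
  list(w = w, ramp = ramp, peaks = peaks,
       centers = c(1625, 1660), fwhms = c(18, 16), heights = c(0.30, 0.20),
       spectrum = axis_spectrum(w, ramp + peaks, role = "linear_od"))
}

# Run a scene through the full measurement chain and return the TDS spectrum
# together with the generator's truth profile.
scene_tds <- function(scene, instr = make_instrument(),
                      baseline = airpls_config()) {
  od <- gen_linear_od(scene)
  g2d <- gen_2d_from_truth(scene, pump = instr$pump, cal = instr$cal)
  od_corr <- if (is.null(baseline)) od else correct_baseline(od, baseline)
  list(tds = tds_spectrum(diagonal_slice(g2d), od_corr, instr$pump,
                          instr$cal),
       truth = g2d$meta$truth_tds, g2d = g2d, od = od_corr)
}

truth_at <- function(truth, omega) {
  stats::approx(truth$axis, truth$values, xout = omega)$y
}

# Relative recovery error of a band's peak TDS against the truth profile,
# evaluated at the recovered peak position.
band_recovery_error <- function(res, band, reference = NULL) {
  pk <- peak_tds(res$tds, c(band$center - band$fwhm / 2,
                            band$center + band$fwhm / 2),
                 reference = reference)
  tt <- truth_at(res$truth, pk$omega)
  abs(pk$tds - tt) / tt
}

# Strongest band of a scene (the main amide I' mode).
main_band <- function(scene) {
  w <- seq(scene$axis[1], scene$axis[2], by = scene$axis[3])
  pk_od <- vapply(scene$bands, function(b)
    b$od_amplitude * max(tdsir:::band_profile(b, w)), numeric(1))
  scene$bands[[which.max(pk_od)]]
}

# Peak band-only OD of a scene, for setting SNR-referenced noise levels.
scene_peak_od <- function(scene) {
  w <- seq(scene$axis[1], scene$axis[2], by = scene$axis[3])
  max(tdsir:::scene_band_od(scene, w))
}
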