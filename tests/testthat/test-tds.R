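test_that("diagonal_slice reads |dOD(w,w)| with probe interpolation", {
  w <- seq(1600, 1660, 10)
  m <- matrix(0, length(w), length(w))
  diag(m) <- -0.02
  g <- grid2d_spectrum(w, w, m)
  sl <- diagonal_slice(g)
  expect_equal(sl$axis, w)
  expect_equal(sl$values, rep(0.02, length(w)))

  # pump axis offset by half a grid step: slice equals linear interpolation
  # along probe, verified against an analytic 2D Gaussian evaluated densely
  pump_ax <- w + 5
  f <- function(p, q) -0.05 * exp(-((p - 1630)^2 + (q - 1630)^2) / 200)
  g2 <- grid2d_spectrum(pump_ax, w, outer(pump_ax, w, f))
  sl2 <- diagonal_slice(g2)
  ov <- pump_ax[pump_ax <= max(w)]
  oracle <- vapply(ov, function(p) {
    j <- max(which(w <= p))
    th <- (p - w[j]) / (w[j + 1] - w[j])
    abs((1 - th) * f(p, w[j]) + th * f(p, w[j + 1]))
  }, numeric(1))
  expect_equal(sl2$values, oracle, tolerance = 1e-12)

  # single-point overlap gives a degenerate length-1 slice
  g3 <- grid2d_spectrum(c(1590, 1600), c(1600, 1610),
                        matrix(c(-1, -2, -3, -4), 2, 2))
  sl3 <- diagonal_slice(g3)
  expect_equal(length(sl3$axis), 1L)
  expect_equal(sl3$axis, 1600)
  expect_equal(sl3$values, 2)   # |dOD| at pump row 1600, probe 1600
})

test_that("calibrant_record locates the band maximum and rejects boundary argmax", {
  instr <- make_instrument()
  expect_equal(instr$cal$omega_max, 1625)      # construction center
  expect_equal(instr$cal$mu_sq, 0.12)          # NMA default
  expect_gt(instr$cal$delta_od_max, 0)
  expect_gt(instr$cal$od_max, 0)

  w <- seq(1600, 1700, 2)
  flat <- axis_spectrum(w, rep(0.1, length(w)), "linear_od")
  expect_error(calibrant_record(instr$g2d_cal, flat), "boundary")
})

test_that("running the calibrant as the sample returns mu^2 at omega_max", {
  instr <- make_instrument()
  d <- tds_spectrum(diagonal_slice(instr$g2d_cal), instr$od_cal,
                    instr$pump, instr$cal)
  expect_equal(d$role, "tds")
  i <- which(d$axis == instr$cal$omega_max)
  expect_equal(d$values[i], 0.12, tolerance = 1e-14)
})

test_that("the TDS ratio is invariant under concentration and pump rescaling", {
  instr <- make_instrument()
  sc <- random_scene(5, n_bands = 1)
  res <- scene_tds(sc, instr, baseline = NULL)
  base <- res$tds$values
  diag_s <- diagonal_slice(res$g2d)
  for (c_fac in 10^seq(-2, 2, 1)) {
    # joint rescaling of dOD and OD: concentration / path length change
    diag_c <- axis_spectrum(diag_s$axis, diag_s$values * c_fac, "linear_od")
    od_c <- axis_spectrum(res$od$axis, res$od$values * c_fac, "linear_od")
    d2 <- tds_spectrum(diag_c, od_c, instr$pump, instr$cal)
    expect_lt(max(abs(d2$values - base) / base, na.rm = TRUE), 1e-12)
  }
  # global pump rescaling cancels (only the ratio at omega_max enters)
  pump2 <- axis_spectrum(instr$pump$axis, instr$pump$values * 37.5, "pump")
  d3 <- tds_spectrum(diag_s, res$od, pump2, instr$cal)
  expect_lt(max(abs(d3$values - base) / base, na.rm = TRUE), 1e-12)
  # doubling dOD at fixed OD doubles d pointwise
  diag_d <- axis_spectrum(diag_s$axis, diag_s$values * 2, "linear_od")
  d4 <- tds_spectrum(diag_d, res$od, instr$pump, instr$cal)
  expect_equal(d4$values, 2 * base, tolerance = 1e-12)
})

test_that("low-OD points are masked, not computed", {
  instr <- make_instrument()
  sc <- scene_spec(bands = list(band_spec(1640, 20, 4, 0.2)),
                   axis = c(1560, 1720, 1), seed = 2)
  res <- scene_tds(sc, instr, baseline = NULL)
  od_v <- stats::approx(res$od$axis, res$od$values, xout = res$tds$axis)$y
  expect_true(all(is.na(res$tds$values[od_v < 0.05 * max(od_v)])))
  expect_true(all(!is.na(res$tds$values[od_v >= 0.05 * max(od_v)])))
})

test_that("peak_tds reads windowed peaks and honors the reference option", {
  instr <- make_instrument()
  sc <- scene_spec(bands = list(band_spec(1640, 22, 4, 0.25)),
                   axis = c(1560, 1720, 1), seed = 3)
  res <- scene_tds(sc, instr, baseline = NULL)
  pk <- peak_tds(res$tds, c(1630, 1650), assignment = "alpha-helix")
  expect_equal(pk$tds, truth_at(res$truth, pk$omega), tolerance = 0.01)
  expect_true(pk$omega >= 1630 && pk$omega <= 1650)
  expect_equal(pk$assignment, "alpha-helix")

  # a window excluding the peak returns the windowed argmax at its boundary
  # side (d is monotone toward the band there)
  pk2 <- peak_tds(res$tds, c(1655, 1675))
  expect_true(pk2$omega >= 1655 && pk2$omega <= 1675)

  # locating on the 2D diagonal magnitude instead of the TDS maximum
  dg <- diagonal_slice(res$g2d)
  pk3 <- peak_tds(res$tds, c(1630, 1650), reference = dg)
  expect_equal(pk3$omega, 1640)

  expect_error(peak_tds(res$tds, c(2000, 2010)), "unmasked")
  expect_error(peak_tds(res$tds, c(1650, 1630)), "lo < hi")
})

test_that("two unresolved modes with equal TDS report equal values", {
  # emulates the two beta-sheet modes of a barrel-plus-interface protein:
  # 1634 and 1626 cm-1, different intensities, same ground-truth TDS
  instr <- make_instrument()
  sc <- scene_spec(bands = list(band_spec(1634, 12, 3.0, 0.24),
                                band_spec(1626, 12, 1.5, 0.24)),
                   axis = c(1560, 1720, 1), seed = 4)
  res <- scene_tds(sc, instr, baseline = NULL)
  pk_hi <- peak_tds(res$tds, c(1630, 1640), assignment = "beta main")
  pk_lo <- peak_tds(res$tds, c(1620, 1630), assignment = "beta dimer")
  expect_lt(abs(pk_hi$tds - pk_lo$tds) / pk_hi$tds, 0.02)
  expect_equal(pk_hi$tds, 0.24, tolerance = 0.01)
})

test_that("compute_tds chains baseline correction, calibration and the ratio", {
  instr <- make_instrument()
  sc <- random_scene(9, n_bands = 1)
  od <- gen_linear_od(sc)
  g2d <- gen_2d_from_truth(sc, pump = instr$pump, cal = instr$cal)
  d <- compute_tds(g2d, od, instr$g2d_cal, instr$od_cal, instr$pump)
  b <- sc$bands[[1]]
  pk <- peak_tds(d, c(b$center - b$fwhm / 2, b$center + b$fwhm / 2))
  expect_equal(pk$tds, truth_at(g2d$meta$truth_tds, pk$omega),
               tolerance = 0.02)
})
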