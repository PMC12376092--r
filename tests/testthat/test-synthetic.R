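test_that("gen_linear_od sums analytic band shapes, baseline and seeded noise", {
  # single Gaussian band, zero baseline, zero noise: closed-form values
  b <- band_spec(1640, 20, od_amplitude = 5, tds = 0.2)
  sc <- scene_spec(bands = list(b), axis = c(1560, 1720, 1), seed = 1)
  od <- gen_linear_od(sc)
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  expect_equal(od$values, 5 * dnorm(od$axis, 1640, sigma), tolerance = 1e-12)

  # empty scene: all zero
  empty <- scene_spec(axis = c(1600, 1700, 1), seed = 1)
  expect_true(all(gen_linear_od(empty)$values == 0))

  # determinism contract
  scn <- scene_spec(bands = list(b), axis = c(1560, 1720, 1),
                    noise_sd = 0.01, seed = 42)
  expect_identical(gen_linear_od(scn)$values, gen_linear_od(scn)$values)
  scn2 <- scene_spec(bands = list(b), axis = c(1560, 1720, 1),
                     noise_sd = 0.01, seed = 43)
  expect_false(identical(gen_linear_od(scn)$values,
                         gen_linear_od(scn2)$values))

  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_linear_od(scn)); after <- runif(1)
  expect_identical(before, after)

  expect_error(scene_spec(bands = list(band_spec(1590, 40, 1, 0.2)),
                          axis = c(1580, 1720, 1)), "too narrow")
})

test_that("line shapes are unit-area and pseudo-Voigt mixes them", {
  w <- seq(1400, 1900, 0.25)
  for (shape in c("gaussian", "lorentzian", "pseudo_voigt")) {
    b <- band_spec(1650, 18, 1, 0.2, shape = shape, eta = 0.3)
    area <- sum(tdsir:::band_profile(b, w)) * 0.25
    tol <- if (shape == "gaussian") 1e-6 else 0.03  # Lorentzian tails
    expect_equal(area, 1, tolerance = tol)
  }
  bg <- band_spec(1650, 18, 1, 0.2, "gaussian")
  bl <- band_spec(1650, 18, 1, 0.2, "lorentzian")
  bv <- band_spec(1650, 18, 1, 0.2, "pseudo_voigt", eta = 0.3)
  expect_equal(tdsir:::band_profile(bv, w),
               0.3 * tdsir:::band_profile(bl, w) +
                 0.7 * tdsir:::band_profile(bg, w), tolerance = 1e-12)
})

test_that("gen_pump produces a normalized symmetric envelope of the right width", {
  sc <- scene_spec(axis = c(1540, 1740, 1),
                   pump = list(center = 1640, fwhm = 120), seed = 1)
  p <- gen_pump(sc)
  expect_equal(p$values[p$axis == 1640], 1)
  expect_true(all(p$values > 0))
  left <- p$values[p$axis < 1640]
  right <- rev(p$values[p$axis > 1640])
  expect_equal(left, right, tolerance = 1e-12)
  # numeric FWHM within one grid step of the requested width
  above <- range(p$axis[p$values >= 0.5])
  expect_lt(abs(diff(above) - 120), 1 + 1e-9)
})

test_that("gen_2d inverts the TDS ratio so the pipeline recovers the truth", {
  instr <- make_instrument()
  # single band: d(w) constant at the band tds, recovered within 1%
  sc1 <- scene_spec(bands = list(band_spec(1645, 22, 4, 0.3)),
                    axis = c(1560, 1720, 1), seed = 6)
  res1 <- scene_tds(sc1, instr, baseline = NULL)
  keep <- !is.na(res1$tds$values)
  expect_lt(max(abs(res1$tds$values[keep] - 0.3) / 0.3), 0.01)

  # two overlapping bands with tds 0.12 and 0.26: peak values within 2%
  sc2 <- scene_spec(bands = list(band_spec(1630, 20, 3, 0.12),
                                 band_spec(1660, 20, 3, 0.26)),
                    axis = c(1560, 1730, 1), seed = 7)
  res2 <- scene_tds(sc2, instr, baseline = NULL)
  for (b in sc2$bands)
    expect_lt(band_recovery_error(res2, b), 0.02)

  # truth metadata is the OD-weighted mean of band TDS values
  w0 <- 1645
  wts <- vapply(sc2$bands, function(b)
    b$od_amplitude * tdsir:::band_profile(b, w0), numeric(1))
  expect_equal(truth_at(res2$truth, w0),
               sum(wts * c(0.12, 0.26)) / sum(wts), tolerance = 1e-10)

  expect_error(gen_2d_from_truth(scene_spec(axis = c(1600, 1700, 1))),
               "no bands")
})

test_that("calibration-line scenes regenerate the generating line", {
  instr <- make_instrument()
  slope <- 0.0067; intercept <- 0.122
  lens <- c(0, 6, 13, 20)
  tds_hat <- vapply(lens, function(L) {
    sc <- scene_spec(bands = list(band_spec(1642 - 0.25 * L, 22, 3.5,
                                            intercept + slope * L)),
                     axis = c(1560, 1720, 1), seed = 100 + L)
    res <- scene_tds(sc, instr, baseline = NULL)
    b <- sc$bands[[1]]
    peak_tds(res$tds, c(b$center - b$fwhm / 2, b$center + b$fwhm / 2))$tds
  }, numeric(1))
  fit <- suppressWarnings(   # recovery is near-perfect; lm warns
    fit_calibration(data.frame(label = as.character(lens),
                               helical_residues = lens,
                               tds_D2 = tds_hat, tds_sd_D2 = 0)))
  expect_lt(abs(fit$slope - slope) / slope, 0.05)
  expect_lt(abs(fit$intercept - intercept) / intercept, 0.05)
})

test_that("random_scene is a deterministic, valid scene factory", {
  a <- random_scene(17); b <- random_scene(17)
  expect_equal(a, b)
  expect_false(identical(random_scene(17)$bands, random_scene(18)$bands))
  for (s in 1:10) {
    sc <- random_scene(s)
    expect_s3_class(sc, "scene_spec")
    expect_true(length(sc$bands) >= 1 && length(sc$bands) <= 3)
  }
  expect_length(random_scene(3, n_bands = 2)$bands, 2)
})
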