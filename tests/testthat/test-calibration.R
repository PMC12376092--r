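ek_fit <- fit_calibration(ek_calibration_points())

test_that("OLS calibration recovers exact lines and rejects degenerate input", {
  pts <- data.frame(label = letters[1:4], helical_residues = c(0, 5, 10, 20),
                    tds_D2 = 0.12 + 0.007 * c(0, 5, 10, 20), tds_sd_D2 = 0.01)
  fit <- suppressWarnings(fit_calibration(pts))  # lm warns on perfect fits
  expect_equal(fit$slope, 0.007, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.12, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  expect_error(fit_calibration(pts[1:2, ]), "at least 3")
  degen <- pts; degen$helical_residues <- 7
  expect_error(fit_calibration(degen), "degenerate")
})

test_that("the EK calibration line matches closed-form OLS on the four points", {
  # independent closed-form oracle
  x <- c(0, 5.9, 13.2, 20.2); y <- c(0.13, 0.15, 0.21, 0.26)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_o <- mean(y) - slope_o * mean(x)
  expect_equal(ek_fit$slope, slope_o, tolerance = 1e-12)
  expect_equal(ek_fit$intercept, int_o, tolerance = 1e-12)
  expect_equal(ek_fit$slope, 0.0067, tolerance = 0.01)
  expect_equal(ek_fit$intercept, 0.122, tolerance = 0.01)
  expect_gt(ek_fit$slope, 0)
  # r^2 equals 1 - SSR/SST computed by brute force
  pred <- int_o + slope_o * x
  r2_o <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(ek_fit$r_squared, r2_o, tolerance = 1e-12)
  # fitted line passes through the centroid (OLS identity)
  expect_equal(predict_tds(mean(x), ek_fit), mean(y), tolerance = 1e-12)
})

test_that("inverse prediction reproduces the reported protein helix lengths", {
  expect_equal(predict_helix_length(0.21, ek_fit)$length, 13.1,
               tolerance = 0.5 / 13.1)
  expect_equal(predict_helix_length(0.30, ek_fit)$length, 26.6,
               tolerance = 0.5 / 26.6)
  expect_equal(predict_helix_length(0.20, ek_fit)$length, 11.6,
               tolerance = 0.5 / 11.6)
  expect_equal(predict_helix_length(0.26, ek_fit)$length, 21,
               tolerance = 0.5 / 21)
  expect_equal(predict_helix_length(0.20, ek_fit)$length, 12,
               tolerance = 0.5 / 12)
})

test_that("predict_helix_length and predict_tds are inverse, monotone, flagged", {
  for (x in c(0, 3.3, 9.8, 20.2, 30)) {
    expect_equal(predict_helix_length(predict_tds(x, ek_fit), ek_fit)$length,
                 x, tolerance = 1e-10)
  }
  # monotone increasing in tds
  lens <- vapply(seq(0.13, 0.4, 0.01),
                 function(t) predict_helix_length(t, ek_fit)$length,
                 numeric(1))
  expect_true(all(diff(lens) > 0))
  # flags: below calibration range and extrapolated
  lo <- predict_helix_length(ek_fit$intercept / 2, ek_fit)
  expect_equal(lo$length, 0)
  expect_true("below_range" %in% lo$flags)
  hi <- predict_helix_length(0.30, ek_fit)
  expect_true("extrapolated" %in% hi$flags)
  within <- predict_helix_length(0.21, ek_fit)
  expect_length(within$flags, 0)
  # measurement uncertainty widens the standard error
  expect_gt(predict_helix_length(0.21, ek_fit, tds_sd = 0.02)$se,
            predict_helix_length(0.21, ek_fit)$se)
})

test_that("weighted fits use 1/sd^2 weights", {
  pts <- ek_calibration_points()
  wfit <- fit_calibration(pts, weighted = TRUE)
  # oracle: weighted closed form
  w <- 1 / pts$tds_sd_D2^2
  x <- pts$helical_residues; y <- pts$tds_D2
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  slope_o <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  expect_equal(wfit$slope, slope_o, tolerance = 1e-12)
  expect_true(wfit$weighted)
  pts$tds_sd_D2 <- 0
  expect_error(fit_calibration(pts, weighted = TRUE), "positive tds_sd")
})

test_that("calibration points round trip through the CSV interface", {
  path <- withr::local_tempfile(fileext = ".csv")
  pts <- ek_calibration_points()
  utils::write.csv(pts, path, row.names = FALSE, quote = FALSE)
  back <- read_calibration_points(path)
  expect_equal(back$helical_residues, pts$helical_residues)
  expect_equal(back$tds_D2, pts$tds_D2)
  fit2 <- fit_calibration(back)
  expect_equal(fit2$slope, ek_fit$slope)
})

test_that("frequency trend is fitted with a negative slope and a caveat", {
  # redshift with length: EK-like frequencies from disordered 1647 down to
  # 1637 cm-1 for the longest helix
  pts <- data.frame(helical_residues = c(0, 5.9, 13.2, 20.2),
                    frequency_cm1 = c(1647, 1642, 1639, 1637))
  tr <- frequency_trend(pts)
  expect_lt(tr$slope, 0)
  expect_match(tr$caveat, "globular")
  # collinear points fit exactly
  pts2 <- data.frame(helical_residues = 0:3, frequency_cm1 = 1650 - 0:3)
  tr2 <- suppressWarnings(frequency_trend(pts2))  # perfect fit
  expect_equal(tr2$slope, -1, tolerance = 1e-12)
  expect_equal(tr2$r_squared, 1)
})
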