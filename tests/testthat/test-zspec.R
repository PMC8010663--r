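test_that("normalisation divides by S0, sorts offsets and flags overshoot", {
  zs <- normalize_zspectrum(c(80, 70), c(-300, 300), 100)
  expect_equal(zs$z, c(0.8, 0.7))
  # identical signals give a flat unit spectrum
  flat <- normalize_zspectrum(rep(50, 5), seq(-60, 60, 30), 50)
  expect_true(all(flat$z == 1))
  # permuted input order: sorted output, value pairing preserved
  o <- c(3, 1, 4, 2, 5)
  perm <- normalize_zspectrum(c(10, 20, 30, 40, 50)[o], seq(-60, 60, 30)[o], 100)
  expect_equal(perm$offsets_hz, seq(-60, 60, 30))
  expect_equal(perm$z, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_error(normalize_zspectrum(1:3, c(-30, 0, 30), 0), "s0")
  flagged <- normalize_zspectrum(c(120, 90), c(-30, 30), 100)
  expect_equal(attr(flagged, "flagged"), c(TRUE, FALSE))
})

test_that("shared natural-spline interpolator agrees with stats::spline", {
  withr::with_seed(5, {
    x <- sort(c(-500, 500, runif(15, -480, 480)))
    y <- sin(x / 150) + 0.1 * rnorm(17)
    xq <- seq(-450, 450, length.out = 101)
    ref <- stats::spline(x, y, xout = xq, method = "natural")$y
    env <- asNamespace("glucocest")
    mine <- env$ns_eval(env$ns_fit(x, y), xq)
    expect_lt(max(abs(mine - ref)), 1e-10)
    # matrix form is columnwise identical to repeated scalar fits
    Y <- cbind(y, rev(y), y^2)
    fitm <- env$ns_fit(x, Y)
    for (j in 1:3)
      expect_equal(env$ns_eval(fitm, xq)[, j],
                   env$ns_eval(env$ns_fit(x, Y[, j]), xq), tolerance = 1e-12)
  })
})

test_that("B0 shift is recovered from shifted spectra", {
  offs <- seq(-900, 900, 30)
  # water-like symmetric dip: truth 0
  z0 <- zspectrum(offs, analytic_spectrum(offs))
  expect_lt(abs(estimate_b0_shift(z0)), 1e-6)
  for (s in c(30, -90)) {
    zs <- zspectrum(offs, analytic_spectrum(offs - s))
    expect_lt(abs(estimate_b0_shift(zs) - s), ifelse(abs(s) > 60, 2, 1))
  }
  # a spectrum with no dip in the window has no estimable shift
  mono <- zspectrum(offs, seq(0.2, 0.9, length.out = length(offs)))
  expect_error(estimate_b0_shift(mono), "minimum")
  expect_error(estimate_b0_shift(zspectrum(c(-30, 0, 30), c(1, 0, 1))),
               "at least 7")
})

test_that("B0 correction is an identity at zero shift and round-trips", {
  offs <- seq(-900, 900, 30)
  zs <- zspectrum(offs, analytic_spectrum(offs, a = 0.08))
  z0 <- b0_correct(zs, 0)
  expect_lt(max(abs(z0$z - zs$z)), 1e-12)
  for (s in seq(-90, 90, 15)) {
    rt <- b0_correct(b0_correct(zs, s), -s)
    sel <- rt$valid
    expect_lt(max(abs(rt$z[sel] - zs$z[sel])), 1e-3)
  }
  expect_error(b0_correct(zs, 2000), "support")
})

test_that("MTRasym evaluates the subtraction formula by interpolation", {
  # three-point spectrum engineered so z(-0.9 ppm) = 0.8, z(+0.9 ppm) = 0.7
  d <- 0.9 * 298.06
  zs <- zspectrum(c(-2 * d, -d, 0, d, 2 * d), c(0.85, 0.8, 0.1, 0.7, 0.75))
  expect_equal(mtr_asym(zs, 0.9), 0.1)
  # symmetric spectrum: exactly zero
  sym <- zspectrum(seq(-900, 900, 30), analytic_spectrum(seq(-900, 900, 30)))
  expect_lt(abs(mtr_asym(sym, 0.9)), 1e-12)
  # antisymmetry under mirroring the spectrum about 0 Hz
  offs <- seq(-900, 900, 30)
  zz <- analytic_spectrum(offs, a = 0.08)
  mirrored <- zspectrum(-rev(offs), rev(zz))
  expect_equal(mtr_asym(mirrored, 0.9), -mtr_asym(zspectrum(offs, zz), 0.9),
               tolerance = 1e-12)
  expect_error(mtr_asym(zspectrum(c(-100, 0, 100), c(1, 0, 1)), 0.9),
               "support")
})

test_that("30 Hz sampling evaluates MTRasym within 1e-3 of a 1 Hz oracle", {
  sys <- glucose_phantom_system(25)
  sch30 <- saturation_scheme(1.5, 5, 5.04, seq(-450, 450, 30))
  z30 <- simulate_zspectrum(sys, sch30)
  # dense-grid oracle: simulate the exact +/-0.9 ppm offsets directly
  d <- 0.9 * sch30$larmor_hz_per_ppm
  schd <- saturation_scheme(1.5, 5, 5.04, c(-d, d, -450, 450))
  zd <- simulate_zspectrum(sys, schd)
  oracle <- zd$z[zd$offsets_hz == -d] - zd$z[zd$offsets_hz == d]
  expect_lt(abs(mtr_asym(z30, 0.9) - oracle), 1e-3)
})

test_that("asymmetry curve matches pointwise evaluation and finds the peak", {
  offs <- seq(-900, 900, 30)
  zs <- zspectrum(offs, analytic_spectrum(offs, a = 0.08))
  curve <- asymmetry_curve(zs)
  for (i in c(1, 10, 20)) {
    expect_equal(curve$mtr_asym[i],
                 mtr_asym(zs, curve$offset_hz[i] / zs$larmor_hz_per_ppm),
                 tolerance = 1e-12)
  }
  expect_gt(attr(curve, "peak_asym"), max(curve$mtr_asym) - 1e-6)
  # the analytic lobe sits at 0.9 ppm
  expect_lt(abs(attr(curve, "peak_ppm") - 0.9), 0.15)
})

test_that("voxelwise map equals the scalar pipeline on a uniform image", {
  offs <- seq(-900, 900, 30)
  zz <- analytic_spectrum(offs, a = 0.08)
  nx <- 6; ny <- 5
  stack <- array(rep(zz, each = nx * ny) * 50, c(nx, ny, length(offs)))
  s0 <- matrix(50, nx, ny)
  shift <- 45
  b0 <- b0_map(matrix(shift, nx, ny))
  mp <- mtr_asym_map(stack, s0, offs, b0 = b0)
  scal <- mtr_asym(b0_correct(normalize_zspectrum(zz * 50, offs, 50), shift))
  expect_true(all(mp$valid))
  expect_lt(max(abs(mp$values - scal)), 1e-12)
  # degenerate voxels are masked, not propagated
  s0[2, 2] <- 0
  mp2 <- mtr_asym_map(stack, s0, offs, b0 = b0)
  expect_false(mp2$valid[2, 2])
  expect_true(is.na(mp2$values[2, 2]))
  expect_error(mtr_asym_map(stack, matrix(1, 3, 3), offs), "grid|match")
})

test_that("a smooth B0 field is corrected to within 0.005 in MTRasym", {
  offs <- seq(-900, 900, 30)
  zz <- analytic_spectrum(offs, a = 0.08)
  nx <- 8; ny <- 8
  shifts <- matrix(seq(-60, 60, length.out = nx), nx, ny)
  stack <- array(0, c(nx, ny, length(offs)))
  sf <- stats::splinefun(offs, zz, method = "natural")
  for (i in seq_len(nx)) for (j in seq_len(ny))
    stack[i, j, ] <- sf(offs - shifts[i, j])
  s0 <- matrix(1, nx, ny)
  ref <- mtr_asym(zspectrum(offs, zz))
  mp <- mtr_asym_map(stack, s0, offs, b0 = b0_map(shifts))
  expect_lt(max(abs(mp$values[mp$valid] - ref)), 0.005)
  # per-voxel automatic estimation gets the same answer
  mp_auto <- mtr_asym_map(stack, s0, offs, b0 = "auto")
  expect_lt(max(abs(mp_auto$values[mp_auto$valid] - ref)), 0.005)
})
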