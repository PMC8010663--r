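# Forward-model tests. Coarse offset grids (still covering +/-0.9 ppm with
# margin) keep the matrix-exponential work light without changing physics.

coarse_scheme <- function(B1_uT = 1.5, t_sat = 5, TR = 5.04, step = 150)
  saturation_scheme(B1_uT, t_sat, TR, seq(-1500, 1500, by = step))

test_that("pure direct saturation is symmetric: zero-solute MTRasym vanishes", {
  water_only <- pool_system(water_pool_phantom())
  z <- simulate_zspectrum(water_only, coarse_scheme())
  curve <- asymmetry_curve(z)
  expect_lt(max(abs(curve$mtr_asym)), 1e-9)
  expect_lt(abs(mtr_asym(z, 0.9)), 1e-9)
})

test_that("matrix-exponential evolution matches stiff ODE integration", {
  sys <- glucose_phantom_system(25)
  sch <- coarse_scheme()
  # within the offset sweep range; the 10 kHz reference is outside what a
  # non-stiff-aware observer can integrate in reasonable time (3e4 rad/s
  # oscillation over 5 s) and is covered by the steady-state oracle instead
  offs <- c(-268.254, 0, 268.254, 450, 1500)
  env <- asNamespace("glucocest")
  w1 <- 2 * pi * 42.577 * sch$B1_uT
  m_rec <- env$bm_matrix(sys, 0, 0, sch$larmor_hz_per_ppm)
  rec <- env$bm_propagator(m_rec$A, m_rec$c, sch$TR - sch$t_sat)
  for (o in offs) {
    m <- env$bm_matrix(sys, o, w1, sch$larmor_hz_per_ppm)
    sat <- env$bm_propagator(m$A, m$c, sch$t_sat)
    mine <- env$bm_cycle_signal(rec, sat)
    ode <- oracle_cycle_signal(sys, sch, o)
    expect_lt(abs(mine - ode), 1e-6)
  }
})

test_that("long saturation reaches the algebraic steady state", {
  sys <- glucose_phantom_system(25)
  sch_long <- saturation_scheme(1.5, 60, 60.04, seq(-1500, 1500, by = 300))
  z_long <- simulate_zspectrum(sys, sch_long)
  z_ss <- zspec_steady_state(sys, sch_long)
  expect_lt(max(abs(z_long$z - z_ss$z)), 1e-6)
})

test_that("simulated spectra stay physical", {
  for (conc in c(25, 100)) {
    z <- simulate_zspectrum(glucose_phantom_system(conc), coarse_scheme())
    expect_true(all(z$z <= 1 + 1e-9))
    # the cyclic model's on-resonance nutation transient may undershoot zero
    # slightly; beyond -1e-2 would be unphysical
    expect_true(all(z$z >= -1e-2))
  }
})

test_that("extreme exchange rates fail loudly instead of returning garbage", {
  sys <- pool_system(water_pool_phantom(),
                     list(cest_pool("wild", 1.2, 125, 1e9, 1, 1e-6)))
  expect_error(simulate_zspectrum(sys, coarse_scheme()), "extreme|stiff|ill")
})

test_that("sweeps reproduce the printed phantom orderings", {
  sys <- glucose_phantom_system(25)
  sch <- coarse_scheme()
  sw_c <- cest_sweep(sys, sch, "concentration", c(6.25, 12.5, 25, 50, 75, 100))
  expect_true(all(diff(sw_c$mtr_asym) > 0))
  sw_ph <- cest_sweep(sys, sch, "ph", c(6.4, 7.4, 8.4))
  expect_true(all(diff(sw_ph$mtr_asym) < 0))
  sw_ts <- cest_sweep(sys, sch, "t_sat", c(4, 5, 6))
  expect_true(all(diff(sw_ts$mtr_asym) > 0))
  sw_tr <- cest_sweep(sys, sch, "TR", c(5, 6, 7, 8))
  expect_true(all(diff(sw_tr$mtr_asym) > 0))
  expect_error(cest_sweep(sys, sch, "flip_angle", 1:3), "arg")
})

test_that("raising B1 grows the asymmetry peak and shifts it upfield", {
  sys <- glucose_phantom_system(25)
  sw <- cest_sweep(sys, coarse_scheme(step = 60), "B1_uT",
                   c(1.5, 2, 2.5, 3, 3.5, 4))
  expect_true(all(diff(sw$peak_asym) >= 0))
  expect_true(all(diff(sw$peak_ppm) > 0))
  # at the 0.9 ppm readout the growth holds until the peak passes it
  expect_true(all(diff(sw$mtr_asym[sw$value <= 3]) > 0))
})

test_that("the concentration response is linear in the dilute limit", {
  sys <- glucose_phantom_system(1)
  sw <- cest_sweep(sys, coarse_scheme(), "concentration", c(1, 2, 5, 10))
  per_mM <- sw$mtr_asym / sw$value
  expect_lt(max(abs(per_mM / per_mM[1] - 1)), 0.10)
})

test_that("higher concentration moves the asymmetry-curve peak upfield", {
  sys <- glucose_phantom_system(25)
  sch <- coarse_scheme(step = 60)
  sw <- cest_sweep(sys, sch, "concentration", c(25, 100))
  expect_gte(sw$peak_ppm[2], sw$peak_ppm[1])
})

test_that("phantom renderer paints exact spectra and honours the layout", {
  sch <- coarse_scheme(step = 300)
  systems <- list(glucose_phantom_system(25), glucose_phantom_system(100))
  layout <- data.frame(x = c(8, 24), y = c(16, 16), radius = c(5, 5))
  ph <- phantom_image(systems, layout, sch, grid = c(32, 32))
  for (i in 1:2) {
    vox <- which(ph$masks[[i]], arr.ind = TRUE)[1, ]
    expect_equal(ph$stack[vox[1], vox[2], ], ph$spectra[[i]]$z)
  }
  # background pixel carries the water spectrum (symmetric)
  bgv <- ph$stack[1, 1, ]
  bg_spec <- zspectrum(ph$offsets_hz, bgv)
  expect_lt(abs(mtr_asym(bg_spec, 0.9)), 1e-9)

  # with noise, the per-tube mean spectrum stays within sampling error
  phn <- phantom_image(systems, layout, sch, grid = c(32, 32),
                       noise_sigma = 0.01, seed = 99)
  m <- ph$masks[[1]]
  mean_spec <- apply(phn$stack, 3, function(sl) mean(sl[m]))
  bound <- 3 * 0.01 / sqrt(sum(m))
  expect_lt(max(abs(mean_spec - ph$spectra[[1]]$z)), 3 * bound)

  # empty layout: pure water everywhere
  ph0 <- phantom_image(list(), data.frame(x = numeric(), y = numeric(),
                                          radius = numeric()),
                       sch, grid = c(16, 16))
  z00 <- zspectrum(ph0$offsets_hz, ph0$stack[8, 8, ])
  expect_lt(abs(mtr_asym(z00, 0.9)), 1e-9)

  expect_error(phantom_image(systems, data.frame(x = c(2, 24), y = c(16, 16),
                                                 radius = c(5, 5)),
                             sch, grid = c(32, 32)), "grid")
  expect_error(phantom_image(systems, data.frame(x = c(14, 18), y = c(16, 16),
                                                 radius = c(5, 5)),
                             sch, grid = c(32, 32)), "overlap")
})
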