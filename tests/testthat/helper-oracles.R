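# Independent oracles used by the tests. These re-derive the physics and
# numerics from first principles and must stay independent of the package's
# implementation paths.

# Bloch-McConnell right-hand side built directly from the pool parameters
# (own conventions and code path; only the water Mz observable is compared).
oracle_bm_derivs <- function(pools, water_conc, offset_hz, w1, larmor) {
  n <- length(pools)
  f <- vapply(pools, function(p) p$proton_conc, 0) / water_conc
  f[1] <- 1
  k <- vapply(pools, function(p) p$k_exch, 0)
  function(t, y, parms) {
    dy <- numeric(3 * n)
    for (i in seq_len(n)) {
      p <- pools[[i]]
      ix <- 3 * (i - 1) + 1
      dw <- 2 * pi * (p$delta_ppm * larmor - offset_hz)
      mx <- y[ix]; my <- y[ix + 1]; mz <- y[ix + 2]
      dy[ix]     <- -mx / p$T2 - dw * my
      dy[ix + 1] <- dw * mx - my / p$T2 + w1 * mz
      dy[ix + 2] <- -w1 * my - (mz - f[i]) / p$T1
      if (i > 1) {
        for (d in 0:2) {
          dy[ix + d] <- dy[ix + d] + k[i] * f[i] * y[1 + d] - k[i] * y[ix + d]
          dy[1 + d]  <- dy[1 + d] + k[i] * y[ix + d] - k[i] * f[i] * y[1 + d]
        }
      }
    }
    list(dy)
  }
}

# water Mz after the spoiled-recovery + CW-saturation cycle, by stiff ODE
# integration (lsoda); mirrors the acquisition cycle of the simulator
oracle_cycle_signal <- function(system, scheme, offset_hz,
                                rtol = 1e-10, atol = 1e-12,
                                maxsteps = 500000L) {
  pools <- c(list(system$water), system$solutes)
  w1 <- 2 * pi * 42.577 * scheme$B1_uT
  lar <- scheme$larmor_hz_per_ppm
  n <- length(pools)
  y <- numeric(3 * n)
  rec <- oracle_bm_derivs(pools, system$water_proton_conc, 0, 0, lar)
  t_rec <- scheme$TR - scheme$t_sat
  if (t_rec > 0) {
    sol <- deSolve::lsoda(y, c(0, t_rec), rec, NULL, rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
    y <- as.numeric(sol[2, -1])
  }
  sat <- oracle_bm_derivs(pools, system$water_proton_conc, offset_hz, w1, lar)
  sol <- deSolve::lsoda(y, c(0, scheme$t_sat), sat, NULL,
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  as.numeric(sol[2, -1])[3]
}

# a small analytic test spectrum: symmetric water dip plus a CEST-like
# Gaussian lobe of amplitude `a` centred at +centre_hz
analytic_spectrum <- function(offsets_hz, a = 0, centre_hz = 268.254,
                              width_hz = 120, dip_width_hz = 180) {
  1 - 0.6 * exp(-(offsets_hz / dip_width_hz)^2) -
    a * exp(-((offsets_hz - centre_hz) / width_hz)^2)
}

# quick uniform dynamic series for the GCE arithmetic tests: every brain
# voxel at timepoint k carries the analytic spectrum with amplitude amps[k]
uniform_series <- function(amps, grid = c(12L, 12L),
                           offsets = seq(-900, 900, 30)) {
  tp <- default_timepoints()
  stopifnot(length(amps) == nrow(tp))
  rois <- list(total_brain = matrix(TRUE, grid[1], grid[2]))
  stacks <- list(); s0s <- list()
  for (k in seq_len(nrow(tp))) {
    z <- analytic_spectrum(offsets, amps[k])
    stacks[[tp$label[k]]] <- array(rep(z, each = prod(grid)),
                                   c(grid[1], grid[2], length(offsets)))
    s0s[[tp$label[k]]] <- matrix(1, grid[1], grid[2])
  }
  cest_series(stacks, s0s, offsets, tp, b0 = NULL, rois = rois)
}

# random symmetric positive-definite 3x3 tensor on the diffusivity scale
random_spd_tensor <- function() {
  ev <- sort(runif(3, 0.2e-3, 1.8e-3), decreasing = TRUE)
  th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
  R1 <- rotation_matrix(c(0, 0, 1), ph) %*% rotation_matrix(c(0, 1, 0), th)
  R1 %*% diag(ev) %*% t(R1)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
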