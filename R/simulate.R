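# Bloch-McConnell forward simulation under continuous-wave saturation.
#
# State vector: (Mx, My, Mz) per pool, water first. Evolution is the linear
# affine system dM/dt = A M + c; propagation over a fixed interval uses the
# matrix exponential of the augmented (3n+1) system, so arbitrarily stiff
# exchange is handled without step-size control.

bm_pools <- function(system) c(list(system$water), system$solutes)

# Build A (3n x 3n) and c (3n) for saturation at offset_hz with amplitude
# w1 (rad/s). Chemical shifts enter as rotating-frame offsets
# dw_i = 2*pi*(delta_i*larmor - offset_hz).
bm_matrix <- function(system, offset_hz, w1, larmor_hz_per_ppm) {
  pools <- bm_pools(system)
  n <- length(pools)
  f <- vapply(pools, function(p) p$proton_conc, 0) / system$water_proton_conc
  M0 <- f
  k <- vapply(pools, function(p) p$k_exch, 0)
  A <- matrix(0, 3L * n, 3L * n)
  cc <- numeric(3L * n)
  kout <- k                         # solute -> water
  kout[1] <- sum(k[-1] * f[-1])     # water -> all solutes (detailed balance)
  for (i in seq_len(n)) {
    p <- pools[[i]]
    ix <- 3L * (i - 1L) + 1L; iy <- ix + 1L; iz <- ix + 2L
    dw <- 2 * pi * (p$delta_ppm * larmor_hz_per_ppm - offset_hz)
    A[ix, ix] <- -1 / p$T2 - kout[i];  A[ix, iy] <- -dw
    A[iy, ix] <- dw;                   A[iy, iy] <- -1 / p$T2 - kout[i]
    A[iy, iz] <- w1
    A[iz, iy] <- -w1;                  A[iz, iz] <- -1 / p$T1 - kout[i]
    cc[iz] <- M0[i] / p$T1
    if (i > 1L) {
      # exchange coupling with water, componentwise
      for (d in 0:2) {
        A[1L + d, ix + d] <- A[1L + d, ix + d] + k[i]          # gain to water
        A[ix + d, 1L + d] <- A[ix + d, 1L + d] + k[i] * f[i]   # gain from water
      }
    }
  }
  list(A = A, c = cc, M0 = M0)
}

# Affine propagator over time t: M(t) = E M(0) + f, via the augmented
# matrix exponential. t = 0 returns the identity map.
bm_propagator <- function(A, cc, t) {
  n <- nrow(A)
  if (t == 0) return(list(E = diag(n), f = numeric(n)))
  aug <- rbind(cbind(A, cc), 0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(aug * t)))
  if (!all(is.finite(P)))
    stop("Bloch-McConnell propagator is not finite: the system is too stiff ",
         "or ill-conditioned (check k_exch and relaxation rates)")
  list(E = P[seq_len(n), seq_len(n), drop = FALSE], f = P[seq_len(n), n + 1L])
}

# One acquisition cycle: post-readout spoiling (all magnetisation zero) ->
# free recovery for TR - t_sat -> CW saturation for t_sat -> readout of
# water Mz. Iterated to the periodic steady state; because the readout
# spoils the full magnetisation the cycle map has no memory and the
# iteration converges at the second pass, but the loop keeps the fixed-point
# check explicit.
bm_cycle_signal <- function(rec, sat, max_cycles = 10L, tol = 1e-8) {
  n <- length(rec$f)
  M <- numeric(n)
  sig_prev <- Inf
  for (cyc in seq_len(max_cycles)) {
    M <- rec$E %*% M + rec$f
    M <- sat$E %*% M + sat$f
    sig <- M[3L]                    # water Mz
    if (abs(sig - sig_prev) < tol && cyc >= 2L) break
    sig_prev <- sig
    M <- numeric(n)                 # readout spoiling
  }
  as.numeric(sig)
}

#' Simulate a Z-spectrum with the Bloch-McConnell model
#'
#' Evolves the coupled water + solute magnetisation under continuous-wave
#' saturation for every offset of the scheme, embedded in the cyclic
#' saturation-readout-recovery model of the acquisition (each repetition:
#' spoiled readout, free recovery for `TR - t_sat`, CW saturation for
#' `t_sat`). The reference signal S0 is simulated with the same cycle at
#' `ref_offset_hz`, matching an acquisition whose "unsaturated" image is in
#' fact saturated far off resonance.
#'
#' @param system A [pool_system()].
#' @param scheme A [saturation_scheme()].
#' @param max_cycles,tol Fixed-point iteration control for the cycle model.
#' @return A [zspectrum()] with `z = Ssat/S0` per offset.
#' @examples
#' z <- simulate_zspectrum(glucose_phantom_system(25), phantom_scheme())
#' mtr_asym(z, 0.9)
#' @export
simulate_zspectrum <- function(system, scheme, max_cycles = 10L, tol = 1e-8) {
  stopifnot(inherits(system, "pool_system"),
            inherits(scheme, "saturation_scheme"))
  if (any(vapply(bm_pools(system), function(p) p$k_exch, 0) * scheme$t_sat > 1e9))
    stop("exchange rates too extreme for a stable simulation")
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * scheme$B1_uT
  lar <- scheme$larmor_hz_per_ppm
  # recovery is offset-independent: it starts from spoiled magnetisation and
  # the longitudinal block decouples from the transverse one when w1 = 0
  m_rec <- bm_matrix(system, 0, 0, lar)
  rec <- bm_propagator(m_rec$A, m_rec$c, scheme$TR - scheme$t_sat)
  signal_at <- function(offset_hz) {
    m <- bm_matrix(system, offset_hz, w1, lar)
    sat <- bm_propagator(m$A, m$c, scheme$t_sat)
    bm_cycle_signal(rec, sat, max_cycles, tol)
  }
  s0 <- signal_at(scheme$ref_offset_hz)
  if (s0 <= 0) stop("simulated S0 is non-positive")
  z <- vapply(scheme$offsets_hz, signal_at, 0) / s0
  # on-resonance nutation out of the spoiled state can undershoot zero by a
  # small transient (< 1e-2 even at fast exchange); anything beyond that is
  # numerical garbage
  if (any(z < -1e-2 | z > 1 + 1e-6))
    stop("simulated Z-spectrum left [0, 1]: the system is ill-conditioned")
  zspectrum(scheme$offsets_hz, z, larmor_hz_per_ppm = lar)
}

#' Algebraic steady state of the saturation block
#'
#' Solves the linear fixed point `A M + c = 0` of the Bloch-McConnell system
#' under CW irradiation, i.e. the infinite-`t_sat` limit without any
#' repetition-time history, normalised by the equivalent steady state at the
#' reference offset.
#'
#' @inheritParams simulate_zspectrum
#' @return A [zspectrum()] of steady-state `z` values.
#' @export
zspec_steady_state <- function(system, scheme) {
  stopifnot(inherits(system, "pool_system"),
            inherits(scheme, "saturation_scheme"))
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * scheme$B1_uT
  lar <- scheme$larmor_hz_per_ppm
  ss <- function(offset_hz) {
    m <- bm_matrix(system, offset_hz, w1, lar)
    M <- solve(m$A, -m$c)
    M[3L]
  }
  s0 <- ss(scheme$ref_offset_hz)
  zspectrum(scheme$offsets_hz, vapply(scheme$offsets_hz, ss, 0) / s0,
            larmor_hz_per_ppm = lar)
}

#' Sweep one acquisition or sample parameter
#'
#' Re-simulates the Z-spectrum over a sequence of values of a single
#' parameter, holding everything else fixed, and summarises the glucoCEST
#' readouts: MTRasym at `delta_ppm` and the asymmetry-curve peak.
#'
#' For `t_sat` sweeps the repetition time is moved with the saturation time
#' (`TR = t_sat + (TR0 - t_sat0)`) so the recovery dead time of the template
#' scheme is preserved and `t_sat <= TR` always holds.
#'
#' @param system Template [pool_system()]; concentration and pH sweeps modify
#'   its `solute`-th pool.
#' @param scheme Template [saturation_scheme()].
#' @param parameter One of `"concentration"`, `"ph"`, `"B1_uT"`, `"t_sat"`,
#'   `"TR"`.
#' @param values Sweep values (mM, pH units, uT or s).
#' @param solute Index of the swept solute pool.
#' @param delta_ppm Evaluation offset for MTRasym.
#' @return A data.frame with columns `parameter`, `value`, `mtr_asym`,
#'   `peak_ppm`, `peak_asym`; the simulated spectra are attached as the
#'   `"spectra"` attribute.
#' @export
cest_sweep <- function(system, scheme, parameter, values, solute = 1L,
                       delta_ppm = 0.9) {
  parameter <- match.arg(parameter,
                         c("concentration", "ph", "B1_uT", "t_sat", "TR"))
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  dead <- scheme$TR - scheme$t_sat
  build <- function(v) {
    sys <- system; sch <- scheme
    switch(parameter,
      concentration = {
        p <- sys$solutes[[solute]]
        if (!is.finite(p$protons_per_molecule))
          stop("pool '", p$name, "' has no protons_per_molecule; ",
               "cannot sweep molecular concentration")
        p$proton_conc <- v * p$protons_per_molecule
        sys$solutes[[solute]] <- p
      },
      ph = {
        sys$solutes <- lapply(sys$solutes, function(p) {
          p$k_exch <- exchange_rate_at_ph(p$k_exch, v, sys$ph); p
        })
        sys$ph <- v
      },
      B1_uT = sch$B1_uT <- v,
      t_sat = { sch$t_sat <- v; sch$TR <- v + dead },
      TR = {
        if (v < sch$t_sat) stop("TR sweep value below t_sat")
        sch$TR <- v
      })
    list(sys = sys, sch = if (parameter %in% c("B1_uT", "t_sat", "TR"))
      saturation_scheme(sch$B1_uT, sch$t_sat, sch$TR, sch$offsets_hz,
                        sch$ref_offset_hz, sch$larmor_hz_per_ppm) else sch)
  }
  spectra <- vector("list", length(values))
  out <- data.frame(parameter = parameter, value = values,
                    mtr_asym = NA_real_, peak_ppm = NA_real_,
                    peak_asym = NA_real_)
  for (i in seq_along(values)) {
    bb <- build(values[i])
    zs <- simulate_zspectrum(bb$sys, bb$sch)
    spectra[[i]] <- zs
    out$mtr_asym[i] <- mtr_asym(zs, delta_ppm)
    curve <- asymmetry_curve(zs)
    out$peak_ppm[i] <- attr(curve, "peak_ppm")
    out$peak_asym[i] <- attr(curve, "peak_asym")
  }
  attr(out, "spectra") <- spectra
  out
}

#' Render a multi-tube phantom as a per-offset image stack
#'
#' Places circular tubes on an image grid; every pixel inside a tube carries
#' that tube's simulated Z-spectrum, the background carries a free-water
#' spectrum, and optional Gaussian noise is added to the magnitude values.
#'
#' @param systems List of [pool_system()]s, one per tube.
#' @param layout data.frame with columns `x`, `y`, `radius` (pixels).
#' @param scheme A [saturation_scheme()].
#' @param grid Image size `c(nx, ny)`.
#' @param noise_sigma Gaussian noise sd on the normalised signal.
#' @param seed Optional RNG seed for the noise.
#' @return List with `stack` (nx x ny x n_offsets array of z values), `s0`
#'   (unit reference image), `masks` (list of logical tube masks),
#'   `offsets_hz` and the ground-truth `spectra`.
#' @export
phantom_image <- function(systems, layout, scheme, grid = c(64L, 64L),
                          noise_sigma = 0, seed = NULL) {
  stopifnot(is.data.frame(layout),
            all(c("x", "y", "radius") %in% names(layout)),
            nrow(layout) == length(systems), noise_sigma >= 0)
  nx <- grid[1]; ny <- grid[2]
  if (nrow(layout)) {
    if (any(layout$x - layout$radius < 1 | layout$x + layout$radius > nx |
            layout$y - layout$radius < 1 | layout$y + layout$radius > ny))
      stop("tube layout exceeds the image grid")
    if (nrow(layout) > 1L) {
      dd <- as.matrix(dist(layout[, c("x", "y")]))
      rr <- outer(layout$radius, layout$radius, "+")
      if (any(dd[upper.tri(dd)] <= rr[upper.tri(rr)]))
        stop("tubes overlap")
    }
  }
  water_only <- pool_system(systems_water(systems, scheme),
                            list(), ph = 7.4, label = "background water")
  bg <- simulate_zspectrum(water_only, scheme)
  spectra <- lapply(systems, simulate_zspectrum, scheme = scheme)
  noff <- length(scheme$offsets_hz)
  stack <- array(rep(bg$z, each = nx * ny), dim = c(nx, ny, noff))
  xx <- matrix(seq_len(nx), nx, ny)
  yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  masks <- vector("list", nrow(layout))
  for (i in seq_along(masks)) {
    m <- (xx - layout$x[i])^2 + (yy - layout$y[i])^2 <= layout$radius[i]^2
    masks[[i]] <- m
    for (k in seq_len(noff)) {
      sl <- stack[, , k]; sl[m] <- spectra[[i]]$z[k]; stack[, , k] <- sl
    }
  }
  if (noise_sigma > 0) {
    add_noise <- function() {
      stack <<- stack + array(rnorm(length(stack), 0, noise_sigma), dim(stack))
    }
    if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  }
  list(stack = stack, s0 = matrix(1, nx, ny), masks = masks,
       offsets_hz = scheme$offsets_hz, spectra = spectra,
       larmor_hz_per_ppm = scheme$larmor_hz_per_ppm)
}

# water pool shared by the tube systems (background medium)
systems_water <- function(systems, scheme) {
  if (length(systems)) systems[[1]]$water else water_pool_phantom()
}
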