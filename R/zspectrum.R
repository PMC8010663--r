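# Z-spectrum container and processing: normalisation, B0 correction,
# asymmetry analysis. All interpolation is natural cubic spline, evaluated
# through one shared implementation that also handles many spectra (voxels)
# with common knots at once, so the scalar and voxelwise pipelines are the
# same arithmetic.

#' Z-spectrum object
#'
#' Normalised saturated signal `z = Ssat/S0` sampled over saturation offsets.
#'
#' @param offsets_hz Offsets (Hz); sorted ascending, must be unique.
#' @param z Normalised signal per offset.
#' @param larmor_hz_per_ppm ppm-to-Hz conversion of the acquisition.
#' @param valid Optional logical validity flag per offset (defaults to
#'   `is.finite(z)`).
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets_hz, z, larmor_hz_per_ppm = LARMOR_HZ_PER_PPM_7T,
                      valid = NULL) {
  stopifnot(length(offsets_hz) == length(z))
  o <- order(offsets_hz)
  offsets_hz <- offsets_hz[o]; z <- z[o]
  if (any(diff(offsets_hz) <= 0)) stop("offsets must be strictly increasing")
  valid <- if (is.null(valid)) is.finite(z) else as.logical(valid)[o] & is.finite(z)
  structure(list(offsets_hz = offsets_hz, z = z, valid = valid,
                 larmor_hz_per_ppm = larmor_hz_per_ppm),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets [%g, %g] Hz (%d valid), z in [%.4g, %.4g]\n",
              length(x$offsets_hz), min(x$offsets_hz), max(x$offsets_hz),
              sum(x$valid), min(x$z[x$valid]), max(x$z[x$valid])))
  invisible(x)
}

#' @export
as.data.frame.zspectrum <- function(x, ...) {
  data.frame(offset_hz = x$offsets_hz,
             ppm = x$offsets_hz / x$larmor_hz_per_ppm,
             z = x$z, valid = x$valid)
}

#' Normalise raw saturated signals by the unsaturated reference
#'
#' @param raw_signals Saturated signal per offset.
#' @param offsets_hz Offsets (Hz), any order.
#' @param s0 Reference (unsaturated) signal, > 0.
#' @param larmor_hz_per_ppm ppm-to-Hz conversion.
#' @return A [zspectrum()]; values above 1.05 are flagged in the
#'   `"flagged"` attribute (they indicate corrupt normalisation).
#' @export
normalize_zspectrum <- function(raw_signals, offsets_hz, s0,
                                larmor_hz_per_ppm = LARMOR_HZ_PER_PPM_7T) {
  if (!is.finite(s0) || s0 <= 0)
    stop("s0 must be a positive finite reference signal")
  zs <- zspectrum(offsets_hz, raw_signals / s0,
                  larmor_hz_per_ppm = larmor_hz_per_ppm)
  attr(zs, "flagged") <- zs$z > 1.05
  zs
}

## ---- shared natural cubic spline ------------------------------------------

# Fit natural cubic splines on common knots x for every column of Y.
# Returns the knots, values and second derivatives (M, with M[1]=M[n]=0).
ns_fit <- function(x, Y) {
  Y <- as.matrix(Y)
  n <- length(x)
  stopifnot(n >= 3L, nrow(Y) == n)
  h <- diff(x)
  if (any(h <= 0)) stop("spline knots must be strictly increasing")
  if (anyNA(Y)) stop("spline values contain NA")
  Tm <- matrix(0, n - 2L, n - 2L)
  diag(Tm) <- (h[-(n - 1L)] + h[-1L]) / 3
  if (n > 3L) {
    up <- cbind(seq_len(n - 3L), seq_len(n - 3L) + 1L)
    Tm[up] <- h[2:(n - 2L)] / 6
    Tm[up[, 2:1, drop = FALSE]] <- h[2:(n - 2L)] / 6
  }
  D <- (Y[-1L, , drop = FALSE] - Y[-n, , drop = FALSE]) / h
  M <- rbind(0, solve(Tm, D[-1L, , drop = FALSE] - D[-(n - 1L), , drop = FALSE]), 0)
  list(x = x, Y = Y, M = M, n = n, V = ncol(Y))
}

# Evaluate the fitted splines. q may be a vector (same queries for every
# column) or an m x V matrix (per-column queries). Outside the knot range the
# result is NA unless extrapolate = TRUE, in which case the natural-spline
# linear extension (end slopes) is used.
ns_eval <- function(fit, q, extrapolate = FALSE) {
  x <- fit$x; n <- fit$n; V <- fit$V
  per_col <- is.matrix(q)
  # a single fitted spline broadcasts over any number of query columns
  broadcast <- per_col && V == 1L && ncol(q) != 1L
  if (per_col && !broadcast && ncol(q) != V)
    stop("query matrix columns must match fit")
  Q <- if (per_col) q else matrix(q, length(q), V)
  m <- nrow(Q)
  nc <- ncol(Q)
  j <- findInterval(Q, x, rightmost.closed = TRUE)
  out_lo <- Q < x[1L]; out_hi <- Q > x[n]
  j[j < 1L] <- 1L; j[j >= n] <- n - 1L
  jj <- as.vector(j)
  colidx <- if (broadcast) rep(1L, m * nc) else rep(seq_len(V), each = m)
  hj <- x[jj + 1L] - x[jj]
  A <- (x[jj + 1L] - as.vector(Q)) / hj
  B <- 1 - A
  li <- jj + (colidx - 1L) * n          # linear indices into the n x V arrays
  Yj  <- fit$Y[li];      Yj1 <- fit$Y[li + 1L]
  Mj  <- fit$M[li];      Mj1 <- fit$M[li + 1L]
  val <- A * Yj + B * Yj1 + ((A^3 - A) * Mj + (B^3 - B) * Mj1) * hj^2 / 6
  val <- matrix(val, m, nc)
  if (any(out_lo) || any(out_hi)) {
    if (extrapolate) {
      h1 <- x[2L] - x[1L]; hn <- x[n] - x[n - 1L]
      s1 <- (fit$Y[2L, ] - fit$Y[1L, ]) / h1 - h1 * fit$M[2L, ] / 6
      sn <- (fit$Y[n, ] - fit$Y[n - 1L, ]) / hn + hn * fit$M[n - 1L, ] / 6
      ci <- matrix(colidx, m, nc)
      val[out_lo] <- fit$Y[1L, ci[out_lo]] + s1[ci[out_lo]] * (Q[out_lo] - x[1L])
      val[out_hi] <- fit$Y[n, ci[out_hi]] + sn[ci[out_hi]] * (Q[out_hi] - x[n])
    } else {
      val[out_lo | out_hi] <- NA_real_
    }
  }
  if (!per_col && nc == 1L) drop(val) else val
}

# scalar convenience: natural spline through (x, y) evaluated at xout
interp_natural <- function(x, y, xout, extrapolate = FALSE) {
  ns_eval(ns_fit(x, y), xout, extrapolate = extrapolate)
}

## ---- B0 estimation and correction -----------------------------------------

#' Estimate the B0 (water-centre) shift of a Z-spectrum
#'
#' Fits a smoothing spline to the direct-saturation dip within a window
#' around 0 Hz and returns the location of its minimum. This is the
#' spectrum-minimum estimate of the per-voxel water frequency offset.
#'
#' @param spec A [zspectrum()] covering 0 Hz.
#' @param window_hz Half-width of the search window around 0 Hz.
#' @param df Degrees of freedom of the smoothing spline; `NULL` selects by
#'   generalised cross-validation (near-interpolation on noise-free data).
#' @return Estimated shift (Hz).
#' @export
estimate_b0_shift <- function(spec, window_hz = 300, df = NULL) {
  stopifnot(inherits(spec, "zspectrum"))
  sel <- spec$valid & abs(spec$offsets_hz) <= window_hz
  if (sum(sel) < 7L)
    stop("need at least 7 valid points within the B0 search window")
  x <- spec$offsets_hz[sel]; y <- spec$z[sel]
  fit <- if (is.null(df)) smooth.spline(x, y) else smooth.spline(x, y, df = df)
  opt <- optimize(function(q) predict(fit, q)$y, range(x))
  span <- diff(range(x))
  if (min(opt$minimum - min(x), max(x) - opt$minimum) < 1e-3 * span)
    stop("no interior minimum in the B0 search window; cannot estimate shift")
  opt$minimum
}

#' Re-centre a Z-spectrum for a known B0 shift
#'
#' Resamples the measured spectrum on its original offset grid after
#' removing the water-centre shift: `z_corr(x) = z_meas(x + shift)`, with
#' natural cubic-spline interpolation. Grid points whose source location
#' falls outside the measured support are marked invalid (`NA`), never
#' silently filled.
#'
#' @param spec A [zspectrum()].
#' @param shift_hz Water-centre shift as returned by [estimate_b0_shift()].
#' @return A corrected [zspectrum()] with an updated validity flag.
#' @export
b0_correct <- function(spec, shift_hz) {
  stopifnot(inherits(spec, "zspectrum"), is.finite(shift_hz))
  x <- spec$offsets_hz[spec$valid]; y <- spec$z[spec$valid]
  span <- max(x) - min(x)
  if (abs(shift_hz) > span / 2)
    stop("B0 shift exceeds half the spectrum support; refusing to correct")
  q <- spec$offsets_hz + shift_hz
  zc <- ns_eval(ns_fit(x, y), q)
  zspectrum(spec$offsets_hz, zc, larmor_hz_per_ppm = spec$larmor_hz_per_ppm,
            valid = is.finite(zc))
}

#' MTRasym at a chemical-shift offset
#'
#' The magnetisation transfer ratio asymmetry
#' `MTRasym(delta) = z(-delta) - z(+delta)`, with both values obtained by
#' natural cubic-spline interpolation at exactly `+/- delta_ppm *
#' larmor_hz_per_ppm` (the acquisition grid need not contain those offsets).
#'
#' @param spec A [zspectrum()].
#' @param delta_ppm Evaluation offset (ppm); the glucoCEST readout uses 0.9.
#' @return MTRasym value (dimensionless).
#' @export
mtr_asym <- function(spec, delta_ppm = 0.9) {
  stopifnot(inherits(spec, "zspectrum"))
  d_hz <- delta_ppm * spec$larmor_hz_per_ppm
  x <- spec$offsets_hz[spec$valid]; y <- spec$z[spec$valid]
  if (-d_hz < min(x) || d_hz > max(x))
    stop("+/-", delta_ppm, " ppm lies outside the valid spectrum support")
  v <- ns_eval(ns_fit(x, y), c(-d_hz, d_hz))
  v[1L] - v[2L]
}

#' Full asymmetry curve of a Z-spectrum
#'
#' Applies [mtr_asym()] over all positive sampled offsets whose mirror is
#' within support, and locates the curve peak on a continuous (spline) scale.
#'
#' @param spec A [zspectrum()].
#' @return data.frame with `offset_hz`, `ppm`, `mtr_asym`; attributes
#'   `peak_ppm` and `peak_asym` give the interpolated curve maximum.
#' @export
asymmetry_curve <- function(spec) {
  stopifnot(inherits(spec, "zspectrum"))
  x <- spec$offsets_hz[spec$valid]; y <- spec$z[spec$valid]
  fit <- ns_fit(x, y)
  pos <- spec$offsets_hz[spec$offsets_hz > 0 &
                           spec$offsets_hz <= min(max(x), -min(x))]
  vals <- ns_eval(fit, c(-pos, pos))
  k <- length(pos)
  curve <- data.frame(offset_hz = pos, ppm = pos / spec$larmor_hz_per_ppm,
                      mtr_asym = vals[seq_len(k)] - vals[k + seq_len(k)])
  # continuous peak via the spline of the curve itself
  if (k >= 4L) {
    cfit <- ns_fit(curve$offset_hz, curve$mtr_asym)
    opt <- optimize(function(q) ns_eval(cfit, q), range(curve$offset_hz),
                    maximum = TRUE)
    attr(curve, "peak_ppm") <- opt$maximum / spec$larmor_hz_per_ppm
    attr(curve, "peak_asym") <- opt$objective
  } else {
    i <- which.max(curve$mtr_asym)
    attr(curve, "peak_ppm") <- curve$ppm[i]
    attr(curve, "peak_asym") <- curve$mtr_asym[i]
  }
  curve
}

## ---- voxelwise pipeline ----------------------------------------------------

#' Per-voxel B0 field map
#'
#' @param shift_hz Matrix of water-centre shifts (Hz).
#' @param valid Optional logical matrix of the same shape.
#' @return An object of class `b0_map`.
#' @export
b0_map <- function(shift_hz, valid = NULL) {
  shift_hz <- as.matrix(shift_hz)
  if (is.null(valid)) valid <- is.finite(shift_hz)
  stopifnot(all(dim(valid) == dim(shift_hz)))
  structure(list(shift_hz = shift_hz, valid = valid & is.finite(shift_hz)),
            class = "b0_map")
}

#' Voxelwise MTRasym map
#'
#' Applies the scalar pipeline (normalise, B0-correct, interpolate MTRasym)
#' to every voxel of a per-offset image stack. Voxels are grouped by their
#' B0 edge-trim pattern so the spline systems can be solved for many voxels
#' at once; the arithmetic is identical to the scalar functions.
#'
#' Voxels with non-positive `s0`, invalid B0 or insufficient post-correction
#' support are masked out explicitly, never returned as silent zeros.
#'
#' @param stack nx x ny x n_offsets array of saturated signals.
#' @param s0 nx x ny reference image.
#' @param offsets_hz Offset per stack slice (Hz), strictly increasing.
#' @param b0 `NULL` (no correction), a [b0_map()], a shift matrix, or the
#'   string `"auto"` to estimate the shift per voxel from the spectrum
#'   minimum.
#' @param delta_ppm Evaluation offset (ppm).
#' @param larmor_hz_per_ppm ppm-to-Hz conversion.
#' @param mask Optional logical matrix restricting the computation (voxels
#'   outside it are reported invalid without being processed).
#' @return List with `values` (nx x ny MTRasym map, NA where masked) and
#'   `valid` (logical matrix).
#' @export
mtr_asym_map <- function(stack, s0, offsets_hz, b0 = NULL, delta_ppm = 0.9,
                         larmor_hz_per_ppm = LARMOR_HZ_PER_PPM_7T,
                         mask = NULL) {
  dm <- dim(stack)
  if (length(dm) != 3L) stop("stack must be a 3-d array (x, y, offset)")
  if (length(offsets_hz) != dm[3L])
    stop("offsets_hz length does not match the stack depth")
  if (any(diff(offsets_hz) <= 0)) stop("offsets must be strictly increasing")
  if (!all(dim(s0) == dm[1:2])) stop("s0 grid does not match the stack")
  nx <- dm[1L]; ny <- dm[2L]; noff <- dm[3L]; V <- nx * ny
  Z <- matrix(aperm(stack, c(3L, 1L, 2L)), noff, V)
  s0v <- as.vector(s0)
  ok <- is.finite(s0v) & s0v > 0 & colSums(!is.finite(Z)) == 0L
  if (!is.null(mask)) {
    if (!all(dim(mask) == dm[1:2])) stop("mask grid does not match the stack")
    ok <- ok & as.vector(mask)
  }
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, s0v[ok], "/")

  if (identical(b0, "auto")) {
    shifts <- rep(NA_real_, V)
    for (v in which(ok)) {
      shifts[v] <- tryCatch(
        estimate_b0_shift(zspectrum(offsets_hz, Z[, v],
                                    larmor_hz_per_ppm = larmor_hz_per_ppm)),
        error = function(e) NA_real_)
    }
    b0 <- b0_map(matrix(shifts, nx, ny))
  } else if (is.matrix(b0)) {
    b0 <- b0_map(b0)
  }
  if (!is.null(b0)) {
    stopifnot(inherits(b0, "b0_map"))
    if (!all(dim(b0$shift_hz) == c(nx, ny))) stop("b0 grid does not match")
    shifts <- as.vector(b0$shift_hz)
    ok <- ok & as.vector(b0$valid)
  } else {
    shifts <- numeric(V)
  }

  d_hz <- delta_ppm * larmor_hz_per_ppm
  span <- max(offsets_hz) - min(offsets_hz)
  ok <- ok & abs(shifts) <= span / 2
  values <- rep(NA_real_, V)
  if (any(ok)) {
    fit1 <- ns_fit(offsets_hz, Z[, ok, drop = FALSE])
    Q <- outer(offsets_hz, shifts[ok], "+")
    Zc <- ns_eval(fit1, Q)                       # NA outside support
    # bucket voxels by which grid rows survived the shift
    n_lo <- colSums(is.na(Zc[seq_len(noff %/% 2L), , drop = FALSE]))
    n_hi <- colSums(is.na(Zc[(noff %/% 2L + 1L):noff, , drop = FALSE]))
    idx_ok <- which(ok)
    asym <- rep(NA_real_, length(idx_ok))
    keys <- n_lo * (noff + 1L) + n_hi
    for (key in unique(keys)) {
      sel <- which(keys == key)
      rows <- (n_lo[sel[1L]] + 1L):(noff - n_hi[sel[1L]])
      xs <- offsets_hz[rows]
      if (length(rows) < 4L || -d_hz < min(xs) || d_hz > max(xs)) next
      fit2 <- ns_fit(xs, Zc[rows, sel, drop = FALSE])
      vv <- matrix(ns_eval(fit2, c(-d_hz, d_hz)), 2L)
      asym[sel] <- vv[1L, ] - vv[2L, ]
    }
    values[idx_ok] <- asym
    ok[idx_ok] <- is.finite(asym)
  }
  list(values = matrix(values, nx, ny), valid = matrix(ok, nx, ny))
}
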