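# Diffusion tensor fitting from S0 + 6-direction DWI: with exactly six
# gradient directions the log-linear system is square, so the noiseless fit
# is exact. ADC is the tensor trace over 3, FA the normalised eigenvalue
# dispersion.

#' Six-direction gradient table
#'
#' A standard non-collinear dual-gradient set, unit-normalised, spanning
#' 3-space.
#'
#' @return 3 x 6 matrix, one direction per column.
#' @export
default_bvecs <- function() {
  g <- cbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1),
             c(0, 1, -1), c(1, 1, 0), c(-1, 1, 0))
  sweep(g, 2L, sqrt(colSums(g^2)), "/")
}

#' S0 + six-direction diffusion-weighted set
#'
#' @param s0 nx x ny unweighted (b = 0) image.
#' @param dwi nx x ny x 6 array of diffusion-weighted images, one per
#'   gradient direction.
#' @param bvecs 3 x 6 matrix of unit gradient directions spanning 3-space.
#' @param bval Diffusion weighting (s/mm^2), > 0.
#' @return An object of class `diffusion_set`.
#' @export
diffusion_set <- function(s0, dwi, bvecs = default_bvecs(), bval = 1031) {
  s0 <- as.matrix(s0)
  dm <- dim(dwi)
  if (length(dm) != 3L || dm[3L] != 6L)
    stop("dwi must be an nx x ny x 6 array")
  if (!all(dim(s0) == dm[1:2])) stop("s0 grid does not match dwi")
  if (!is.matrix(bvecs) || !all(dim(bvecs) == c(3L, 6L)))
    stop("bvecs must be a 3 x 6 matrix")
  nrm <- sqrt(colSums(bvecs^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("gradient directions must be unit vectors")
  if (!is.finite(bval) || bval <= 0) stop("bval must be > 0")
  B <- dti_design(bvecs)
  if (qr(B)$rank < 6L)
    stop("gradient set is rank deficient; directions do not span the tensor space")
  structure(list(s0 = s0, dwi = dwi, bvecs = bvecs, bval = bval),
            class = "diffusion_set")
}

# design matrix rows: (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)
dti_design <- function(bvecs) {
  t(apply(bvecs, 2L, function(g)
    c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3],
      2 * g[2] * g[3])))
}

# forward model: signals S_i = s0 * exp(-b g' D g) for a 3x3 tensor D
#' Noise-free forward DWI signals for a ground-truth tensor
#'
#' @param s0 Unweighted signal (scalar or matrix).
#' @param D Symmetric 3 x 3 diffusion tensor (mm^2/s).
#' @param bvecs 3 x 6 gradient directions.
#' @param bval Diffusion weighting (s/mm^2).
#' @return Vector of 6 attenuation factors times `s0`.
#' @export
dti_forward <- function(s0, D, bvecs = default_bvecs(), bval = 1031) {
  q <- vapply(seq_len(ncol(bvecs)), function(i) {
    g <- bvecs[, i]
    exp(-bval * drop(t(g) %*% D %*% g))
  }, 0)
  if (is.matrix(s0)) {
    out <- array(0, c(dim(s0), length(q)))
    for (i in seq_along(q)) out[, , i] <- s0 * q[i]
    out
  } else s0 * q
}

#' Fit the diffusion tensor voxelwise
#'
#' Solves `ln(S_i/S0) = -b g_i' D g_i` per voxel (six equations, six tensor
#' elements: exact in the noiseless case), then derives ADC (mean
#' diffusivity, trace/3) and FA from the eigenvalues,
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`. Negative
#' eigenvalues arising from noise are clamped to zero before FA; voxels with
#' non-positive signals or with any `S_i >= S0` are masked out of the fit.
#'
#' @param ds A [diffusion_set()].
#' @param mask Optional logical matrix restricting the fit.
#' @return An object of class `tensor_map`: list with `tensor`
#'   (nx x ny x 6, elements Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `adc`, `fa`,
#'   `mask`.
#' @export
fit_tensor <- function(ds, mask = NULL) {
  stopifnot(inherits(ds, "diffusion_set"))
  dm <- dim(ds$dwi)
  nx <- dm[1L]; ny <- dm[2L]; V <- nx * ny
  S <- matrix(aperm(ds$dwi, c(3L, 1L, 2L)), 6L, V)
  s0v <- as.vector(ds$s0)
  ok <- is.finite(s0v) & s0v > 0 &
    colSums(!is.finite(S) | S <= 0) == 0L &
    colSums(S >= rep(s0v, each = 6L)) == 0L
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  B <- dti_design(ds$bvecs)
  D6 <- matrix(NA_real_, 6L, V)
  if (any(ok)) {
    Y <- -log(sweep(S[, ok, drop = FALSE], 2L, s0v[ok], "/")) / ds$bval
    D6[, ok] <- solve(B, Y)
  }
  adc <- (D6[1L, ] + D6[2L, ] + D6[3L, ]) / 3
  fa <- rep(NA_real_, V)
  for (v in which(ok)) {
    d <- D6[, v]
    Dm <- matrix(c(d[1], d[4], d[5],
                   d[4], d[2], d[6],
                   d[5], d[6], d[3]), 3L, 3L)
    ev <- pmax(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values, 0)
    den <- sum(ev^2)
    fa[v] <- if (den == 0) 0 else
      sqrt(1.5 * sum((ev - mean(ev))^2) / den)
  }
  structure(list(tensor = array(t(D6), c(nx, ny, 6L)),
                 adc = matrix(adc, nx, ny), fa = matrix(fa, nx, ny),
                 mask = matrix(ok, nx, ny)),
            class = "tensor_map")
}

#' ROI means of ADC and FA
#'
#' @param tm A [fit_tensor()] result.
#' @param mask Logical ROI matrix.
#' @return List with `mean_adc`, `mean_fa` and the voxel count `n`.
#' @export
roi_summary <- function(tm, mask) {
  stopifnot(inherits(tm, "tensor_map"))
  sel <- as.logical(mask) & as.vector(tm$mask)
  if (!any(sel)) stop("ROI is empty after masking")
  list(mean_adc = mean(tm$adc[sel]), mean_fa = mean(tm$fa[sel]),
       n = sum(sel))
}

#' Read and write FSL-dialect gradient tables
#'
#' `bvec` files carry 3 rows (x, y, z) of one column per volume; `bval`
#' files carry a single row. The S0 volume is column 1 with direction
#' (0,0,0) and b = 0.
#'
#' @param path File path.
#' @return `read_bvec()`: 3 x n matrix; `read_bval()`: numeric vector.
#' @export
read_bvec <- function(path) {
  m <- as.matrix(read.table(path))
  if (nrow(m) != 3L) stop("bvec file must have 3 rows")
  dimnames(m) <- NULL
  m
}

#' @rdname read_bvec
#' @export
read_bval <- function(path) {
  m <- as.matrix(read.table(path))
  if (nrow(m) != 1L) stop("bval file must have 1 row")
  as.numeric(m)
}

#' @rdname read_bvec
#' @param bvecs,bvals Gradient table to write.
#' @export
write_bvec <- function(bvecs, path) {
  write.table(format(bvecs, digits = 10), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_bvec
#' @export
write_bval <- function(bvals, path) {
  write.table(matrix(bvals, 1L), path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
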