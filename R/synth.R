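# Seeded synthetic generator for the in vivo study design: AD-vs-control
# cohorts of dynamic CEST series (spectra from the Bloch-McConnell forward
# model, smooth B0 fields, Gaussian noise, parametric ROI geometry), paired
# 6-direction DWI sets and a per-animal metabolite table with a configurable
# GCE-mI link. Every ground-truth parameter is recorded so the full
# analysis pipeline can be tested as a round trip.

#' Default infusion uptake curves
#'
#' Baseline-anchored MTRasym changes at the seven timepoints. Controls rise
#' to a plateau of 0.03 during the infusion and hold it (homeostasis);
#' AD animals reach a lower plateau of 0.012 early and then decline, with
#' the time-course minimum at the 40-min timepoint.
#'
#' @return Named list of numeric length-7 vectors (`control`, `ad`) plus a
#'   `plateau` attribute per curve.
#' @export
default_uptake_curves <- function() {
  ctrl <- c(0, 0.010, 0.020, 0.028, 0.030, 0.030, 0.030)
  ad <- c(0, 0.008, 0.012, 0.004, -0.008, -0.004, -0.002)
  attr(ctrl, "plateau") <- 0.030
  attr(ad, "plateau") <- 0.012
  list(control = ctrl, ad = ad)
}

#' Parametric ROI geometry
#'
#' Elliptical whole-brain mask with bilateral hippocampal and parietal
#' cortical sub-regions, scaled to the grid.
#'
#' @param grid Image size `c(nx, ny)`.
#' @return Named list of logical masks: `total_brain`, `hippocampus_L/R`,
#'   `parietal_cortex_L/R`; all sub-ROIs are subsets of `total_brain`.
#' @export
make_roi_masks <- function(grid = c(32L, 32L)) {
  nx <- grid[1L]; ny <- grid[2L]
  xx <- matrix(seq_len(nx), nx, ny); yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ell <- function(cx, cy, rx, ry)
    ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
  brain <- ell(0.50 * nx, 0.52 * ny, 0.42 * nx, 0.38 * ny)
  hip_l <- ell(0.38 * nx, 0.60 * ny, 0.07 * nx, 0.07 * ny) & brain
  hip_r <- ell(0.62 * nx, 0.60 * ny, 0.07 * nx, 0.07 * ny) & brain
  ctx_l <- ell(0.35 * nx, 0.32 * ny, 0.10 * nx, 0.08 * ny) & brain & !hip_l
  ctx_r <- ell(0.65 * nx, 0.32 * ny, 0.10 * nx, 0.08 * ny) & brain & !hip_r
  list(total_brain = brain, hippocampus_L = hip_l, hippocampus_R = hip_r,
       parietal_cortex_L = ctx_l, parietal_cortex_R = ctx_r)
}

#' Cohort specification for the synthetic study
#'
#' The defaults encode the emulated study design: two groups of six animals,
#' a 7-timepoint infusion protocol, baseline MTRasym(0.9 ppm) of 0.035 in
#' both groups, the [default_uptake_curves()], an animal-level random effect
#' of sd 0.005 on baseline and plateau, Gaussian image noise of sd 0.01 on
#' the normalised signal, and a smooth bilinear B0 field within +/- 50 Hz.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param grid Image size `c(nx, ny)`.
#' @param baseline_mtr Named per-group baseline MTRasym(0.9 ppm); set the AD
#'   entry higher to emulate an elevated pre-infusion signal.
#' @param uptake_curves Named list of length-7 baseline-anchored curves with
#'   a `plateau` attribute; first element must be 0.
#' @param animal_sd Named sd of the animal random effects: `baseline`
#'   (additive) and `plateau` (additive on the plateau, scaling the curve).
#' @param noise_sigma Gaussian noise sd on normalised images (>= 0).
#' @param b0_coef Coefficients `c(c0, cx, cy, cxy)` of the bilinear B0 field
#'   (Hz) over normalised coordinates in [-1, 1].
#' @param mi_model Linear GCE-to-myo-inositol link `mI = alpha + beta * GCE
#'   + N(0, sigma)`; `sigma = NULL` fixes the population R^2 at `r2` via
#'   [mi_sigma_for_r2()].
#' @param scheme In vivo [saturation_scheme()].
#' @param system_template In vivo water + glucose [pool_system()] whose
#'   glucose pool is rescaled to hit the per-voxel MTRasym targets.
#' @param dwi_tensor Ground-truth brain diffusion tensor (mm^2/s).
#' @param dwi_noise Gaussian noise sd on DWI signals.
#' @param seed RNG seed for [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 6L,
                        grid = c(32L, 32L),
                        baseline_mtr = c(control = 0.035, ad = 0.035),
                        uptake_curves = default_uptake_curves(),
                        animal_sd = c(baseline = 0.005, plateau = 0.005),
                        noise_sigma = 0.01,
                        b0_coef = c(5, 20, -15, 10),
                        mi_model = list(alpha = 4, beta = 50, sigma = NULL,
                                        r2 = 0.626),
                        scheme = invivo_scheme(),
                        system_template = glucose_invivo_system(10),
                        dwi_tensor = diag(c(1.05, 0.75, 0.60)) * 1e-3,
                        dwi_noise = 0.01,
                        seed = 1L) {
  stopifnot(n_per_group >= 2L, noise_sigma >= 0,
            all(names(uptake_curves) == names(baseline_mtr)))
  for (g in names(uptake_curves)) {
    cu <- uptake_curves[[g]]
    if (length(cu) != 7L || cu[1L] != 0)
      stop("uptake curve '", g, "' must have 7 points with curve[baseline] = 0")
    if (is.null(attr(cu, "plateau"))) stop("uptake curve '", g,
                                           "' needs a plateau attribute")
  }
  if (is.null(mi_model$sigma)) {
    gce_true <- vapply(names(uptake_curves), function(g) {
      cu <- uptake_curves[[g]]; mean(cu[c(5L, 6L)])
    }, 0)
    sc <- vapply(names(uptake_curves), function(g) {
      cu <- uptake_curves[[g]]
      abs(mean(cu[c(5L, 6L)])) * animal_sd[["plateau"]] / attr(cu, "plateau")
    }, 0)
    var_gce <- var_population(gce_true) + mean(sc^2)
    mi_model$sigma <- mi_sigma_for_r2(mi_model$beta, var_gce, mi_model$r2)
  }
  structure(list(n_per_group = n_per_group, grid = grid,
                 baseline_mtr = baseline_mtr, uptake_curves = uptake_curves,
                 animal_sd = animal_sd, noise_sigma = noise_sigma,
                 b0_coef = b0_coef, mi_model = mi_model, scheme = scheme,
                 system_template = system_template, dwi_tensor = dwi_tensor,
                 dwi_noise = dwi_noise, seed = seed),
            class = "cohort_spec")
}

# population (not sample) variance of equally likely values
var_population <- function(x) mean((x - mean(x))^2)

#' Residual sd giving a target population R-squared
#'
#' For `y = alpha + beta x + N(0, sigma)` with predictor variance `var_x`,
#' the population coefficient of determination is
#' `R^2 = beta^2 var_x / (beta^2 var_x + sigma^2)`; this inverts it.
#'
#' @param beta Slope of the link.
#' @param var_x Predictor variance.
#' @param r2 Target population R^2 in (0, 1).
#' @return Residual standard deviation.
#' @export
mi_sigma_for_r2 <- function(beta, var_x, r2) {
  stopifnot(r2 > 0, r2 < 1, var_x > 0)
  sqrt(beta^2 * var_x * (1 - r2) / r2)
}

# bilinear B0 field (Hz) over the grid
b0_field <- function(grid, coef) {
  nx <- grid[1L]; ny <- grid[2L]
  u <- matrix(seq(-1, 1, length.out = nx), nx, ny)
  v <- matrix(seq(-1, 1, length.out = ny), nx, ny, byrow = TRUE)
  coef[1L] + coef[2L] * u + coef[3L] * v + coef[4L] * u * v
}

# Calibration of the forward model: Z-spectra and MTRasym(0.9 ppm) on a
# glucose-concentration grid for a given scheme/system, memoised per
# parameter set. Supplies both the inverse map target -> concentration and
# the spectra used for interpolation at arbitrary targets.
mtr_calibration <- function(scheme, system_template, conc_max = 450,
                            n_conc = 30L) {
  key <- paste(collapse = "|", c(
    format(c(scheme$B1_uT, scheme$t_sat, scheme$TR, scheme$ref_offset_hz,
             scheme$larmor_hz_per_ppm, range(scheme$offsets_hz),
             length(scheme$offsets_hz), conc_max, n_conc), digits = 17),
    format(unlist(lapply(bm_pools(system_template),
                         function(p) c(p$delta_ppm, p$k_exch, p$T1, p$T2,
                                       p$protons_per_molecule))), digits = 17)))
  hit <- .glucocest_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- system_template$solutes[[1L]]
  if (!is.finite(p$protons_per_molecule))
    stop("system template's glucose pool needs protons_per_molecule")
  conc <- seq(0, conc_max, length.out = n_conc)
  spectra <- matrix(0, length(scheme$offsets_hz), n_conc)
  mtr <- numeric(n_conc)
  for (i in seq_along(conc)) {
    sys <- system_template
    sys$solutes[[1L]]$proton_conc <- conc[i] * p$protons_per_molecule
    zs <- simulate_zspectrum(sys, scheme)
    spectra[, i] <- zs$z
    mtr[i] <- mtr_asym(zs, 0.9)
  }
  if (any(diff(mtr) <= 0))
    stop("calibration MTRasym(conc) is not monotone; narrow conc_max")
  cal <- list(conc = conc, mtr = mtr, spectra = spectra,
              offsets_hz = scheme$offsets_hz,
              inv = splinefun(mtr, conc, method = "hyman"),
              sfit = ns_fit(conc, t(spectra)))
  .glucocest_cache[[key]] <- cal
  cal
}

# Z-spectrum whose MTRasym(0.9 ppm) equals `target`, by inverting the
# calibration and interpolating the spectra across concentration.
spectrum_for_target <- function(cal, target) {
  if (target < min(cal$mtr) - 1e-9 || target > max(cal$mtr) + 1e-9)
    stop("MTRasym target ", signif(target, 4),
         " is outside the achievable range [", signif(min(cal$mtr), 4), ", ",
         signif(max(cal$mtr), 4), "] of the forward model")
  conc <- cal$inv(target)
  as.vector(ns_eval(cal$sfit, conc))
}

#' Generate one synthetic animal
#'
#' Builds the dynamic CEST series (per-voxel Z-spectra hitting the group's
#' MTRasym targets, shifted by the B0 field, plus noise), the paired DWI
#' set, and the myo-inositol value, drawing the animal-level random effects
#' from the current RNG stream.
#'
#' @param spec A [cohort_spec()].
#' @param group Group name (must match the spec's curves).
#' @param animal_id Identifier stored in the truth record.
#' @return List with `series` ([cest_series()]), `dwi` ([diffusion_set()]),
#'   `mi` and the ground-truth record `truth`.
#' @export
generate_animal <- function(spec, group, animal_id) {
  stopifnot(inherits(spec, "cohort_spec"),
            group %in% names(spec$uptake_curves))
  grid <- spec$grid; nx <- grid[1L]; ny <- grid[2L]
  tp <- default_timepoints()
  curve <- spec$uptake_curves[[group]]
  plateau <- attr(curve, "plateau")
  re_base <- rnorm(1L, 0, spec$animal_sd[["baseline"]])
  re_plat <- rnorm(1L, 0, spec$animal_sd[["plateau"]])
  scale <- (plateau + re_plat) / plateau
  curve_a <- as.numeric(curve) * scale
  base_a <- spec$baseline_mtr[[group]] + re_base
  targets <- base_a + curve_a

  cal <- mtr_calibration(spec$scheme, spec$system_template)
  shifts <- b0_field(grid, spec$b0_coef)
  brain <- make_roi_masks(grid)
  offs <- spec$scheme$offsets_hz
  noff <- length(offs)
  bvox <- as.vector(brain$total_brain)
  stacks <- list(); s0s <- list()
  for (k in seq_len(nrow(tp))) {
    ztrue <- spectrum_for_target(cal, targets[k])
    # measured(x) = Z(x - s): water centred at +s; evaluated per voxel
    sf <- ns_fit(offs, ztrue)
    Q <- outer(offs, -as.vector(shifts)[bvox], "+")
    Zm <- ns_eval(sf, Q, extrapolate = TRUE)
    stack <- matrix(1, noff, nx * ny)     # background: unsaturated unit signal
    stack[, bvox] <- Zm
    if (spec$noise_sigma > 0)
      stack <- stack + matrix(rnorm(length(stack), 0, spec$noise_sigma),
                              nrow(stack))
    s0 <- matrix(1, nx, ny)
    if (spec$noise_sigma > 0)
      s0 <- s0 + matrix(rnorm(nx * ny, 0, spec$noise_sigma / sqrt(2)), nx, ny)
    stacks[[tp$label[k]]] <- array(t(stack), c(nx, ny, noff))
    s0s[[tp$label[k]]] <- s0
  }
  series <- cest_series(
    stacks = stacks, s0_images = s0s, offsets_hz = offs,
    timepoints = tp, b0 = b0_map(shifts), rois = brain,
    larmor_hz_per_ppm = spec$scheme$larmor_hz_per_ppm)

  s0d <- matrix(0.05, nx, ny); s0d[brain$total_brain] <- 1
  dwi <- dti_forward(s0d, spec$dwi_tensor)
  if (spec$dwi_noise > 0)
    dwi <- dwi + array(rnorm(length(dwi), 0, spec$dwi_noise), dim(dwi))
  ds <- diffusion_set(s0d, dwi)

  gce_true <- mean(curve_a[c(5L, 6L)])
  mi <- spec$mi_model$alpha + spec$mi_model$beta * gce_true +
    rnorm(1L, 0, spec$mi_model$sigma)
  truth <- list(animal = animal_id, group = group, re_baseline = re_base,
                re_plateau = re_plat, baseline_mtr = base_a,
                uptake_curve = curve_a, gce = gce_true, mi = mi,
                b0_coef = spec$b0_coef, noise_sigma = spec$noise_sigma)
  list(series = series, dwi = ds, mi = mi, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Seeded, deterministic generation of `n_per_group` animals per group. The
#' returned manifest records the spec and every animal's ground truth, so an
#' identical cohort can be regenerated from it.
#'
#' @param spec A [cohort_spec()]; `spec$seed` drives all randomness.
#' @param out_dir Optional directory; when given, every animal is written
#'   with [write_series()] plus DWI NIfTI/bvec/bval files, a
#'   `metabolites.csv` table and a `manifest.json`.
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `animals` (named list from [generate_animal()]),
#'   `groups`, `spec` and `manifest`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, force = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$uptake_curves), each = spec$n_per_group)
  ids <- sprintf("%s%02d", groups, sequence(rep(spec$n_per_group,
                                                length(spec$uptake_curves))))
  animals <- withr::with_seed(spec$seed, {
    lapply(seq_along(ids), function(i)
      generate_animal(spec, groups[i], ids[i]))
  })
  names(animals) <- ids
  manifest <- list(seed = spec$seed, n_per_group = spec$n_per_group,
                   grid = spec$grid, groups = as.list(stats::setNames(groups, ids)),
                   truth = lapply(animals, `[[`, "truth"))
  out <- list(animals = animals, groups = stats::setNames(groups, ids),
              spec = spec, manifest = manifest)
  if (!is.null(out_dir)) write_cohort(out, out_dir, force = force)
  out
}

#' Per-animal metabolite table of a generated cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return data.frame with `animal`, `group`, `mi` (mM).
#' @export
cohort_metabolite_table <- function(cohort) {
  data.frame(animal = names(cohort$animals),
             group = unname(cohort$groups),
             mi = vapply(cohort$animals, `[[`, 0, "mi"))
}
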