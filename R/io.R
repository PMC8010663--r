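# Readers and writers: NIfTI image stacks with JSON sidecars (BIDS-like),
# CSV tables, YAML configuration for pool systems and schemes. Every
# artifact carries the metadata needed to re-derive it (offsets, timepoints,
# conversion constant, provenance).

pkg_version <- function() as.character(utils::packageVersion("glucocest"))

#' Write / read a dynamic CEST series
#'
#' One NIfTI stack per timepoint (`cest_<label>.nii.gz`, offset as 4th
#' dimension collapsed to 3rd for 2D slices), per-timepoint S0 images, the
#' B0 map, an integer ROI label map, and a `series_manifest.json` sidecar
#' listing offsets, timepoints, conversion constant and file names (relative
#' paths, so the directory is relocatable).
#'
#' @param series A [cest_series()].
#' @param dir Output directory (created if needed).
#' @param provenance Optional list (seed, config hash...) stored verbatim.
#' @return `write_series()`: the directory, invisibly. `read_series()`: a
#'   validated [cest_series()].
#' @export
write_series <- function(series, dir, provenance = list()) {
  stopifnot(inherits(series, "cest_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- series$timepoints$label
  man <- list(version = pkg_version(),
              offsets_hz = series$offsets_hz,
              timepoints = series$timepoints,
              larmor_hz_per_ppm = series$larmor_hz_per_ppm,
              stacks = as.list(stats::setNames(sprintf("cest_%s.nii.gz", labs),
                                               labs)),
              s0 = as.list(stats::setNames(sprintf("s0_%s.nii.gz", labs),
                                           labs)),
              provenance = provenance)
  for (l in labs) {
    RNifti::writeNifti(series$stacks[[l]], file.path(dir, man$stacks[[l]]))
    RNifti::writeNifti(series$s0_images[[l]], file.path(dir, man$s0[[l]]))
  }
  if (!is.null(series$b0)) {
    man$b0 <- "b0.nii.gz"
    RNifti::writeNifti(series$b0$shift_hz, file.path(dir, man$b0))
  }
  rn <- names(series$rois)
  lab_img <- matrix(0L, nrow(series$rois[[1L]]), ncol(series$rois[[1L]]))
  for (i in seq_along(rn)) lab_img[series$rois[[rn[i]]]] <- i
  # overlapping ROIs are re-derived from the label legend at read time, so
  # sub-ROIs must be painted after total_brain
  ord <- order(rn != "total_brain")
  lab_img[] <- 0L
  for (i in ord) lab_img[series$rois[[rn[i]]]] <- i
  man$rois <- list(file = "rois.nii.gz", labels = as.list(
    stats::setNames(seq_along(rn), rn)))
  RNifti::writeNifti(lab_img, file.path(dir, man$rois$file))
  jsonlite::write_json(man, file.path(dir, "series_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  mf <- file.path(dir, "series_manifest.json")
  if (!file.exists(mf)) stop("missing series_manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (field in c("offsets_hz", "timepoints", "stacks", "s0", "rois"))
    if (is.null(man[[field]]))
      stop("series manifest is missing field '", field, "'")
  tp <- as.data.frame(man$timepoints)
  labs <- tp$label
  read_img <- function(rel, field) {
    p <- file.path(dir, rel)
    if (!file.exists(p))
      stop("file referenced by manifest field '", field, "' not found: ", rel)
    img <- as.array(RNifti::readNifti(p))
    array(as.numeric(img), dim(img))   # bare array, no NIfTI attributes
  }
  stacks <- lapply(labs, function(l) read_img(man$stacks[[l]],
                                              paste0("stacks.", l)))
  names(stacks) <- labs
  for (l in labs)
    if (dim(stacks[[l]])[3L] != length(man$offsets_hz))
      stop("offsets_hz length does not match stack depth for timepoint '",
           l, "'")
  s0s <- lapply(labs, function(l) read_img(man$s0[[l]], paste0("s0.", l)))
  names(s0s) <- labs
  b0 <- if (!is.null(man$b0)) b0_map(read_img(man$b0, "b0")) else NULL
  lab_img <- read_img(man$rois$file, "rois")
  # total_brain is the union of every painted label (sub-ROIs overwrote it)
  rois <- lapply(man$rois$labels, function(i) lab_img == i)
  if ("total_brain" %in% names(rois))
    rois$total_brain <- lab_img > 0L
  cest_series(stacks, s0s, as.numeric(man$offsets_hz), tp, b0, rois,
              larmor_hz_per_ppm = man$larmor_hz_per_ppm)
}

# full cohort layout: one subdirectory per animal + metabolite table +
# manifest with all ground truth
write_cohort <- function(cohort, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$animals)) {
    an <- cohort$animals[[id]]
    adir <- file.path(out_dir, id)
    write_series(an$series, adir,
                 provenance = list(seed = cohort$spec$seed, animal = id))
    RNifti::writeNifti(an$dwi$s0, file.path(adir, "dwi_s0.nii.gz"))
    RNifti::writeNifti(an$dwi$dwi, file.path(adir, "dwi.nii.gz"))
    write_bvec(cbind(0, an$dwi$bvecs), file.path(adir, "dwi.bvec"))
    write_bval(c(0, rep(an$dwi$bval, 6L)), file.path(adir, "dwi.bval"))
  }
  write.csv(cohort_metabolite_table(cohort),
            file.path(out_dir, "metabolites.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write / read a Z-spectrum as CSV
#'
#' Columns `offset_hz`, `z`, `valid`; the conversion constant is stored in a
#' `# larmor_hz_per_ppm:` header comment.
#'
#' @param spec A [zspectrum()].
#' @param path CSV path.
#' @return The path / the [zspectrum()].
#' @export
write_zspectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "zspectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# larmor_hz_per_ppm: %.10g", spec$larmor_hz_per_ppm), con)
  write.csv(data.frame(offset_hz = spec$offsets_hz, z = spec$z,
                       valid = spec$valid),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zspectrum_csv
#' @export
read_zspectrum_csv <- function(path) {
  first <- readLines(path, n = 1L)
  lar <- if (grepl("larmor_hz_per_ppm", first))
    as.numeric(sub(".*:", "", first)) else LARMOR_HZ_PER_PPM_7T
  d <- read.csv(path, comment.char = "#")
  zspectrum(d$offset_hz, d$z, larmor_hz_per_ppm = lar, valid = d$valid)
}

#' Read a pool-system / scheme configuration from YAML
#'
#' Schema: top-level `system` (water: T1/T2; ph; solutes: list of either
#' preset `name` + `conc_mM` or explicit pool parameters) and `scheme`
#' (B1_uT, t_sat, TR, offsets as min/max/step or an explicit list,
#' ref_offset_hz, larmor_hz_per_ppm).
#'
#' @param path YAML file.
#' @return List with `system` ([pool_system()]) and `scheme`
#'   ([saturation_scheme()]).
#' @export
read_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$system) || is.null(cfg$scheme))
    stop("config must contain 'system' and 'scheme' sections")
  sy <- cfg$system
  ph <- sy$ph %||% 7.4
  water <- cest_pool("water", 0, WATER_PROTON_CONC_MM, 0,
                     sy$water$T1 %||% 3.0, sy$water$T2 %||% 1.0)
  solutes <- lapply(sy$solutes, function(s) {
    if (!is.null(s$name) && !is.null(s$conc_mM) && is.null(s$delta_ppm))
      solute_pool(s$name, s$conc_mM, ph = ph)
    else
      cest_pool(s$name %||% "solute", s$delta_ppm, s$proton_conc, s$k_exch,
                s$T1, s$T2, s$protons_per_molecule %||% NA_real_)
  })
  sc <- cfg$scheme
  offsets <- if (!is.null(sc$offsets_hz)) as.numeric(sc$offsets_hz)
    else seq(sc$offset_min_hz, sc$offset_max_hz, by = sc$offset_step_hz)
  list(system = pool_system(water, solutes, ph = ph,
                            label = sy$label %||% ""),
       scheme = saturation_scheme(sc$B1_uT, sc$t_sat, sc$TR, offsets,
                                  sc$ref_offset_hz %||% 10000,
                                  sc$larmor_hz_per_ppm %||%
                                    LARMOR_HZ_PER_PPM_7T))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter-sweep table as CSV
#'
#' @param sweep A [cest_sweep()] result.
#' @param path CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}

#' Write an MTRasym / GCE map as NIfTI
#'
#' Masked voxels are written as NA.
#'
#' @param map A list with `values` and `valid` (from [mtr_asym_map()] or
#'   [gce_map()]).
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_map_nifti <- function(map, path) {
  vals <- map$values
  vals[!map$valid] <- NA_real_
  RNifti::writeNifti(vals, path)
  invisible(path)
}
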