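# Dynamic glucoCEST-enhancement analysis: per-timepoint MTRasym maps, the
# GCE subtraction map, ROI time courses and the cohort table that feeds the
# statistics stage.

#' Canonical infusion timepoints
#'
#' Baseline, four timepoints during the glucose infusion and two after it.
#'
#' @return data.frame with `label` and `minutes`.
#' @export
default_timepoints <- function() {
  data.frame(label = c("baseline", "inf10", "inf20", "inf30", "inf40",
                       "post10", "post20"),
             minutes = c(0, 10, 20, 30, 40, 50, 60))
}

#' Dynamic CEST series of one animal
#'
#' @param stacks Named list (one per timepoint label) of nx x ny x n_offsets
#'   arrays of saturated signals.
#' @param s0_images Named list of nx x ny reference images.
#' @param offsets_hz Offsets per stack slice (Hz).
#' @param timepoints data.frame(label, minutes); see [default_timepoints()].
#' @param b0 Optional [b0_map()] (or shift matrix) shared by all timepoints.
#' @param rois Named list of logical masks; must include `total_brain`, and
#'   every other ROI must be a subset of it.
#' @param larmor_hz_per_ppm ppm-to-Hz conversion.
#' @return An object of class `cest_series`.
#' @export
cest_series <- function(stacks, s0_images, offsets_hz,
                        timepoints = default_timepoints(), b0 = NULL, rois,
                        larmor_hz_per_ppm = LARMOR_HZ_PER_PPM_7T) {
  stopifnot(is.data.frame(timepoints),
            all(c("label", "minutes") %in% names(timepoints)))
  if (any(diff(timepoints$minutes) <= 0))
    stop("timepoints must be strictly ordered in time")
  labs <- timepoints$label
  if (!setequal(names(stacks), labs) || !setequal(names(s0_images), labs))
    stop("stacks and s0_images must be named by the timepoint labels")
  stacks <- stacks[labs]; s0_images <- s0_images[labs]
  dm <- dim(stacks[[1L]])
  for (l in labs) {
    if (!identical(dim(stacks[[l]]), dm))
      stop("stack grids are not congruent (timepoint ", l, ")")
    if (!all(dim(s0_images[[l]]) == dm[1:2]))
      stop("s0 grid does not match the stacks (timepoint ", l, ")")
  }
  if (length(offsets_hz) != dm[3L])
    stop("offsets_hz length does not match the stack depth")
  if (is.matrix(b0)) b0 <- b0_map(b0)
  if (!is.null(b0) && !all(dim(b0$shift_hz) == dm[1:2]))
    stop("b0 grid does not match the stacks")
  if (!("total_brain" %in% names(rois))) stop("rois must include total_brain")
  for (rn in names(rois)) {
    if (!all(dim(rois[[rn]]) == dm[1:2]))
      stop("ROI grid does not match the stacks (", rn, ")")
    if (rn != "total_brain" && any(rois[[rn]] & !rois$total_brain))
      stop("ROI '", rn, "' is not a subset of total_brain")
  }
  structure(list(stacks = stacks, s0_images = s0_images,
                 offsets_hz = offsets_hz, timepoints = timepoints, b0 = b0,
                 rois = rois, larmor_hz_per_ppm = larmor_hz_per_ppm),
            class = "cest_series")
}

#' @export
print.cest_series <- function(x, ...) {
  dm <- dim(x$stacks[[1L]])
  cat(sprintf("<cest_series> %dx%d grid, %d offsets, %d timepoints, ROIs: %s\n",
              dm[1], dm[2], dm[3], nrow(x$timepoints),
              paste(names(x$rois), collapse = ", ")))
  invisible(x)
}

#' GlucoCEST (MTRasym) map at one timepoint
#'
#' @param series A [cest_series()].
#' @param t Timepoint label.
#' @param delta_ppm Evaluation offset (ppm).
#' @param mask Optional logical matrix restricting the computation.
#' @return As [mtr_asym_map()].
#' @export
glucocest_map <- function(series, t, delta_ppm = 0.9, mask = NULL) {
  stopifnot(inherits(series, "cest_series"))
  if (!t %in% series$timepoints$label) stop("unknown timepoint '", t, "'")
  mtr_asym_map(series$stacks[[t]], series$s0_images[[t]], series$offsets_hz,
               b0 = series$b0, delta_ppm = delta_ppm,
               larmor_hz_per_ppm = series$larmor_hz_per_ppm, mask = mask)
}

# all timepoint maps plus the common validity mask
series_maps <- function(series, delta_ppm = 0.9, mask = NULL) {
  maps <- lapply(series$timepoints$label, function(t)
    glucocest_map(series, t, delta_ppm, mask = mask))
  names(maps) <- series$timepoints$label
  valid <- Reduce(`&`, lapply(maps, `[[`, "valid"))
  list(maps = maps, valid = valid)
}

#' GlucoCEST-enhancement (GCE) map
#'
#' The difference between the infusion-state and baseline glucoCEST images:
#' the mean of the 40-min-infusion and 10-min-post-infusion MTRasym maps
#' minus the pre-injection map. With the default `"post-pre"` sign
#' convention glucose uptake yields positive GCE; `"pre-post"` flips it.
#'
#' @param series A [cest_series()] containing `baseline`, `inf40`, `post10`.
#' @param sign `"post-pre"` (default) or `"pre-post"`.
#' @param delta_ppm Evaluation offset (ppm).
#' @param maps Optional precomputed [series_maps] result (internal reuse).
#' @return List with `values` (nx x ny GCE map) and `valid`.
#' @export
gce_map <- function(series, sign = c("post-pre", "pre-post"),
                    delta_ppm = 0.9, maps = NULL) {
  stopifnot(inherits(series, "cest_series"))
  sign <- match.arg(sign)
  need <- c("baseline", "inf40", "post10")
  if (!all(need %in% series$timepoints$label))
    stop("series must contain timepoints: ", paste(need, collapse = ", "))
  if (is.null(maps)) {
    maps <- lapply(need, function(t) glucocest_map(series, t, delta_ppm))
    names(maps) <- need
    valid <- Reduce(`&`, lapply(maps, `[[`, "valid"))
    maps <- list(maps = maps, valid = valid)
  }
  g <- (maps$maps$inf40$values + maps$maps$post10$values) / 2 -
    maps$maps$baseline$values
  if (sign == "pre-post") g <- -g
  g[!maps$valid] <- NA_real_
  list(values = g, valid = maps$valid)
}

#' ROI time course of the glucoCEST signal
#'
#' ROI-mean MTRasym at every timepoint, and its change from baseline.
#' Means are taken over the ROI voxels that are valid at every timepoint,
#' so the time course and [gce_map()] are exactly consistent.
#'
#' @param series A [cest_series()].
#' @param roi ROI name; `"hippocampus"` and `"parietal_cortex"` address the
#'   bilateral unions of the `_L`/`_R` masks when present.
#' @param delta_ppm Evaluation offset (ppm).
#' @param maps Optional precomputed [series_maps] result (internal reuse).
#' @return data.frame with `label`, `minutes`, `mtr_asym`, `delta_mtr`;
#'   attributes `baseline_mtr`, `roi` and `n_voxels`.
#' @export
roi_timecourse <- function(series, roi, delta_ppm = 0.9, maps = NULL) {
  stopifnot(inherits(series, "cest_series"))
  mask <- roi_mask(series, roi)
  if (is.null(maps)) maps <- series_maps(series, delta_ppm)
  mask <- mask & maps$valid
  if (!any(mask)) stop("ROI '", roi, "' is empty (after validity masking)")
  mm <- vapply(maps$maps, function(m) mean(m$values[mask]), 0)
  out <- data.frame(label = series$timepoints$label,
                    minutes = series$timepoints$minutes,
                    mtr_asym = unname(mm),
                    delta_mtr = unname(mm - mm[["baseline"]]))
  attr(out, "baseline_mtr") <- unname(mm[["baseline"]])
  attr(out, "roi") <- roi
  attr(out, "n_voxels") <- sum(mask)
  out
}

# resolve an ROI name, supporting bilateral unions
roi_mask <- function(series, roi) {
  if (roi %in% names(series$rois)) return(series$rois[[roi]])
  lr <- paste0(roi, c("_L", "_R"))
  if (all(lr %in% names(series$rois)))
    return(series$rois[[lr[1L]]] | series$rois[[lr[2L]]])
  stop("unknown ROI '", roi, "'")
}

#' Cohort summary table
#'
#' One row per animal and ROI with the baseline MTRasym, the GCE value and
#' the per-timepoint baseline-subtracted time course, ready for the
#' statistics stage. Bilateral ROIs are reported as unions alongside the
#' individual sides.
#'
#' @param series_list Named list of [cest_series()], one per animal id.
#' @param groups Character vector of group labels, aligned with
#'   `series_list`.
#' @param rois ROI names to summarise; defaults to total brain plus the
#'   bilateral hippocampus and parietal cortex (unions and sides).
#' @param delta_ppm Evaluation offset (ppm).
#' @return data.frame in deterministic (animal, roi) order; time-course
#'   columns are named `tc_<label>`.
#' @export
cohort_table <- function(series_list, groups, rois = NULL, delta_ppm = 0.9) {
  ids <- names(series_list)
  if (is.null(ids) || anyDuplicated(ids))
    stop("series_list must be uniquely named by animal id")
  stopifnot(length(groups) == length(series_list))
  if (is.null(rois)) {
    rns <- names(series_list[[1L]]$rois)
    rois <- "total_brain"
    for (bi in c("hippocampus", "parietal_cortex"))
      if (all(paste0(bi, c("_L", "_R")) %in% rns))
        rois <- c(rois, bi, paste0(bi, c("_L", "_R")))
  }
  rows <- list()
  for (i in seq_along(series_list)) {
    ser <- series_list[[i]]
    # every requested ROI is inside total_brain, so the per-voxel work can be
    # confined there
    maps <- series_maps(ser, delta_ppm, mask = ser$rois$total_brain)
    g <- gce_map(ser, delta_ppm = delta_ppm, maps = maps)
    for (rn in rois) {
      mask <- roi_mask(ser, rn) & maps$valid
      tc <- roi_timecourse(ser, rn, delta_ppm, maps = maps)
      row <- data.frame(animal = ids[i], group = groups[i], roi = rn,
                        n_voxels = sum(mask),
                        baseline_mtr = attr(tc, "baseline_mtr"),
                        gce = mean(g$values[mask]))
      for (k in seq_len(nrow(tc)))
        row[[paste0("tc_", tc$label[k])]] <- tc$delta_mtr[k]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$animal, match(out$roi, rois)), , drop = FALSE]
}
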