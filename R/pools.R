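#' Define an exchanging proton pool
#'
#' A pool is one population of exchangeable protons: bulk water or a labile
#' solute site (hydroxyl, amine, guanidinium...). Chemical shift is expressed
#' relative to water, exchange is first order towards water.
#'
#' @param name Pool label.
#' @param delta_ppm Chemical shift relative to water (ppm).
#' @param proton_conc Exchangeable-proton concentration (mM). For a molecule
#'   with several equivalent labile protons this is concentration times
#'   `protons_per_molecule`.
#' @param k_exch Solute-to-water exchange rate (s^-1). Zero for water.
#' @param T1,T2 Longitudinal / transverse relaxation times (s); `T2 <= T1`.
#' @param protons_per_molecule Optional count of labile protons per molecule,
#'   used by concentration sweeps to convert molarity into proton
#'   concentration.
#' @return An object of class `cest_pool`.
#' @examples
#' cest_pool("glucose", delta_ppm = 1.2, proton_conc = 125,
#'           k_exch = 1500, T1 = 1.0, T2 = 0.01, protons_per_molecule = 5)
#' @export
cest_pool <- function(name, delta_ppm, proton_conc, k_exch, T1, T2,
                      protons_per_molecule = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  num <- c(delta_ppm = delta_ppm, proton_conc = proton_conc,
           k_exch = k_exch, T1 = T1, T2 = T2)
  if (!all(is.finite(num)))
    stop("non-finite parameter for pool '", name, "'")
  if (proton_conc < 0) stop("proton_conc must be >= 0 (pool '", name, "')")
  if (k_exch < 0) stop("k_exch must be >= 0 (pool '", name, "')")
  if (T1 <= 0 || T2 <= 0) stop("T1 and T2 must be > 0 (pool '", name, "')")
  if (T2 > T1) stop("T2 must not exceed T1 (pool '", name, "')")
  structure(list(name = name, delta_ppm = delta_ppm,
                 proton_conc = proton_conc, k_exch = k_exch,
                 T1 = T1, T2 = T2,
                 protons_per_molecule = protons_per_molecule),
            class = "cest_pool")
}

#' Bulk-water pools with default relaxation
#'
#' `water_pool_phantom()` uses PBS/1% agarose phantom defaults,
#' `water_pool_invivo()` uses rat-brain defaults at 7 T.
#'
#' @param T1,T2 Relaxation times (s).
#' @return A `cest_pool` at 0 ppm carrying the reference proton concentration.
#' @export
water_pool_phantom <- function(T1 = 3.0, T2 = 1.0) {
  cest_pool("water", 0, WATER_PROTON_CONC_MM, 0, T1, T2)
}

#' @rdname water_pool_phantom
#' @export
water_pool_invivo <- function(T1 = 2.0, T2 = 0.06) {
  cest_pool("water", 0, WATER_PROTON_CONC_MM, 0, T1, T2)
}

#' Assemble a multi-pool spin system
#'
#' @param water The water `cest_pool` (chemical shift must be 0 ppm).
#' @param solutes List of solute `cest_pool`s (possibly empty).
#' @param water_proton_conc Reference proton concentration of pure water (mM);
#'   solute pool fractions are `proton_conc / water_proton_conc`.
#' @param ph pH at which the solute `k_exch` values are quoted.
#' @param label Free-text provenance note (buffer, temperature...).
#' @return An object of class `pool_system`.
#' @export
pool_system <- function(water, solutes = list(),
                        water_proton_conc = WATER_PROTON_CONC_MM,
                        ph = 7.4, label = "") {
  stopifnot(inherits(water, "cest_pool"))
  if (water$delta_ppm != 0) stop("water pool must sit at 0 ppm")
  if (!is.list(solutes) || !all(vapply(solutes, inherits, TRUE, "cest_pool")))
    stop("solutes must be a list of cest_pool objects")
  if (any(vapply(solutes, function(p) identical(p$delta_ppm, 0) &&
                   p$name == "water", TRUE)))
    stop("exactly one water pool is allowed")
  fr <- vapply(solutes, function(p) p$proton_conc, 0) / water_proton_conc
  if (any(fr >= 0.01))
    warning("solute proton fraction >= 1% -- outside the dilute phantom regime")
  structure(list(water = water, solutes = solutes,
                 water_proton_conc = water_proton_conc,
                 ph = ph, label = label),
            class = "pool_system")
}

#' @export
print.pool_system <- function(x, ...) {
  cat("<pool_system> pH", x$ph,
      if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  water: T1=%.3g s T2=%.3g s\n", x$water$T1, x$water$T2))
  for (p in x$solutes)
    cat(sprintf("  %s: %+0.2f ppm, %.4g mM protons, k=%.4g /s, T1=%.3g, T2=%.3g\n",
                p$name, p$delta_ppm, p$proton_conc, p$k_exch, p$T1, p$T2))
  invisible(x)
}

#' pH dependence of hydroxyl exchange
#'
#' Base-catalysed proton exchange: the rate scales with hydroxide
#' concentration, i.e. one decade per pH unit,
#' `k = k_ref * 10^(ph - ph_ref)`.
#'
#' @param k_ref Exchange rate at the reference pH (s^-1), > 0.
#' @param ph Target pH.
#' @param ph_ref Reference pH at which `k_ref` is quoted.
#' @return Exchange rate at `ph` (s^-1).
#' @examples
#' exchange_rate_at_ph(1500, 8.4, 7.4)  # 15000
#' @export
exchange_rate_at_ph <- function(k_ref, ph, ph_ref = 7.4) {
  if (!all(is.finite(c(k_ref, ph, ph_ref))))
    stop("non-finite input to exchange_rate_at_ph")
  if (k_ref <= 0) stop("k_ref must be > 0")
  k_ref * 10^(ph - ph_ref)
}

#' Literature-default solute pool presets
#'
#' Chemical shifts, labile proton counts, exchange rates and relaxation
#' defaults for the phantom metabolites. These are implementation defaults
#' drawn from the CEST literature for the 7 T / room-temperature phantom
#' regime; they are the single frozen parameter table used throughout the
#' package. The table ships as plain CSV
#' (`system.file("extdata/pool_presets.csv", package = "glucocest")`) and can
#' be edited or replaced via the `file` argument.
#'
#' @param file Path to an alternative preset CSV with the same columns.
#' @return A data.frame with one row per metabolite.
#' @export
pool_presets <- function(file = system.file("extdata", "pool_presets.csv",
                                            package = "glucocest")) {
  out <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "delta_ppm", "protons_per_molecule", "k_exch", "T1", "T2")
  if (!all(need %in% names(out)))
    stop("preset file is missing columns: ",
         paste(setdiff(need, names(out)), collapse = ", "))
  out
}

#' Build a solute pool from the preset table
#'
#' @param name Metabolite name as listed in [pool_presets()].
#' @param conc_mM Molecular concentration (mM); proton concentration is
#'   `conc_mM * protons_per_molecule`.
#' @param ph Sample pH; the preset exchange rate (quoted at `ph_ref`) is
#'   rescaled with [exchange_rate_at_ph()].
#' @param ph_ref pH at which the preset rates are quoted.
#' @param presets Preset table, see [pool_presets()].
#' @return A `cest_pool`.
#' @export
solute_pool <- function(name, conc_mM, ph = 7.4, ph_ref = 7.4,
                        presets = pool_presets()) {
  row <- presets[presets$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("no unique preset for '", name, "'")
  k <- exchange_rate_at_ph(row$k_exch, ph, ph_ref)
  cest_pool(name, row$delta_ppm, conc_mM * row$protons_per_molecule, k,
            row$T1, row$T2, protons_per_molecule = row$protons_per_molecule)
}

#' Canonical phantom and in vivo glucose systems
#'
#' `glucose_phantom_system()` models one PBS/agarose tube of D-glucose
#' (single effective hydroxyl pool, 5 exchangeable protons per molecule);
#' `glucose_invivo_system()` uses brain water relaxation instead.
#'
#' @param conc_mM D-glucose concentration (mM).
#' @param ph Tube pH (exchange rate rescaled from the pH 7.4 preset).
#' @return A `pool_system`.
#' @export
glucose_phantom_system <- function(conc_mM, ph = 7.4) {
  pool_system(water_pool_phantom(),
              list(solute_pool("glucose", conc_mM, ph = ph)),
              ph = ph, label = "PBS + 1% agarose phantom")
}

#' @rdname glucose_phantom_system
#' @export
glucose_invivo_system <- function(conc_mM, ph = 7.4) {
  pool_system(water_pool_invivo(),
              list(solute_pool("glucose", conc_mM, ph = ph)),
              ph = ph, label = "rat brain")
}
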