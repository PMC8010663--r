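#' Continuous-wave saturation scheme
#'
#' Describes the CW saturation block and acquisition cycle of a CEST
#' experiment: saturation amplitude `B1_uT`, saturation time `t_sat`,
#' repetition time `TR`, the offset list, and the far off-resonance reference
#' offset used for the unsaturated image S0.
#'
#' @param B1_uT Saturation amplitude (microtesla), > 0.
#' @param t_sat Saturation duration (s), `0 < t_sat <= TR`.
#' @param TR Repetition time of the acquisition cycle (s).
#' @param offsets_hz Saturation offsets (Hz); stored sorted ascending.
#' @param ref_offset_hz Reference offset treated as unsaturated (Hz); must be
#'   at least 5x the largest offset magnitude.
#' @param larmor_hz_per_ppm Field-dependent ppm-to-Hz conversion
#'   (default 298.06 Hz/ppm, i.e. 7 T).
#' @return An object of class `saturation_scheme`.
#' @export
saturation_scheme <- function(B1_uT, t_sat, TR, offsets_hz,
                              ref_offset_hz = 10000,
                              larmor_hz_per_ppm = LARMOR_HZ_PER_PPM_7T) {
  if (!all(is.finite(c(B1_uT, t_sat, TR, offsets_hz, ref_offset_hz,
                       larmor_hz_per_ppm))))
    stop("non-finite saturation scheme parameter")
  if (B1_uT <= 0) stop("B1_uT must be > 0")
  if (t_sat <= 0 || t_sat > TR) stop("need 0 < t_sat <= TR")
  offsets_hz <- sort(unique(as.numeric(offsets_hz)))
  if (length(offsets_hz) < 2L) stop("need at least two offsets")
  if (abs(ref_offset_hz) < 5 * max(abs(offsets_hz)))
    stop("ref_offset_hz must lie far outside the offset range (>= 5x max)")
  structure(list(B1_uT = B1_uT, t_sat = t_sat, TR = TR,
                 offsets_hz = offsets_hz, ref_offset_hz = ref_offset_hz,
                 larmor_hz_per_ppm = larmor_hz_per_ppm),
            class = "saturation_scheme")
}

#' Acquisition schemes of the phantom and in vivo protocols
#'
#' Phantom protocol: offsets -1500..+1500 Hz in 30 Hz steps, S0 reference at
#' 10 kHz, B1 = 1.5 uT, t_sat = 5 s, TR = 5.04 s. In vivo protocol: offsets
#' -900..+900 Hz in 30 Hz steps, TR = 6 s, otherwise identical.
#'
#' @param B1_uT,t_sat,TR Override the protocol defaults.
#' @return A `saturation_scheme`.
#' @export
phantom_scheme <- function(B1_uT = 1.5, t_sat = 5, TR = 5.04) {
  saturation_scheme(B1_uT, t_sat, TR, seq(-1500, 1500, by = 30))
}

#' @rdname phantom_scheme
#' @export
invivo_scheme <- function(B1_uT = 1.5, t_sat = 5, TR = 6) {
  saturation_scheme(B1_uT, t_sat, TR, seq(-900, 900, by = 30))
}

#' @export
print.saturation_scheme <- function(x, ...) {
  cat(sprintf(
    "<saturation_scheme> B1=%.3g uT, t_sat=%.3g s, TR=%.3g s, %d offsets [%g, %g] Hz, ref %g Hz\n",
    x$B1_uT, x$t_sat, x$TR, length(x$offsets_hz), min(x$offsets_hz),
    max(x$offsets_hz), x$ref_offset_hz))
  invisible(x)
}
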