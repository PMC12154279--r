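#' Default spectral species for hyperpolarized [1-13C]pyruvate imaging
#'
#' Returns the table of resonances observed after an intravenous
#' hyperpolarized pyruvate injection: the substrate (Pyr) and its
#' enzymatic products lactate (Lac, via LDH), bicarbonate (Bic, via
#' PDH-mediated decarboxylation) and alanine (Ala, via ALT), plus the
#' non-enzymatic pyruvate-hydrate resonance as an optional confounder.
#'
#' Chemical shifts are standard HP-13C assignments and are configurable;
#' the carrier is placed on pyruvate so that all frequency offsets are
#' expressed relative to the Pyr resonance.
#'
#' @param hydrate include the pyruvate-hydrate resonance?
#' @return A tibble with columns `name`, `shift_ppm` and `t2star_s`.
#' @examples
#' default_peaks()
#' @export
default_peaks <- function(hydrate = FALSE) {
  pk <- tibble::tibble(
    name = c("pyruvate", "lactate", "alanine", "bicarbonate", "pyruvate_hydrate"),
    shift_ppm = c(171.0, 183.2, 176.5, 161.1, 179.5),
    t2star_s = 0.02
  )
  if (!hydrate) pk <- pk[pk$name != "pyruvate_hydrate", ]
  validate_peaks(pk)
  pk
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("name", "shift_ppm", "t2star_s") %in% names(peaks)))
  allowed <- c("pyruvate", "lactate", "bicarbonate", "alanine", "pyruvate_hydrate")
  if (!all(peaks$name %in% allowed))
    stop("unknown metabolite name(s): ",
         paste(setdiff(peaks$name, allowed), collapse = ", "))
  if (any(peaks$shift_ppm < 150 | peaks$shift_ppm > 195))
    stop("chemical shifts must lie within [150, 195] ppm")
  if (any(peaks$t2star_s <= 0)) stop("t2star_s must be positive")
  invisible(peaks)
}

#' Convert a chemical-shift offset to a frequency offset
#'
#' Offsets are relative to the carrier (placed on pyruvate by default).
#' At 3 T the 13C carrier frequency is approximately 32.13 MHz, so
#' 1 ppm corresponds to 32.13 Hz.
#'
#' @param ppm chemical shift(s) in ppm
#' @param ref_ppm carrier position in ppm (default: the pyruvate shift)
#' @param f0_mhz carrier frequency in MHz
#' @return frequency offset(s) in Hz
#' @export
ppm_to_hz <- function(ppm, ref_ppm = 171.0, f0_mhz = 32.13) {
  (ppm - ref_ppm) * f0_mhz
}

#' @rdname ppm_to_hz
#' @param hz frequency offset(s) in Hz
#' @export
hz_to_ppm <- function(hz, ref_ppm = 171.0, f0_mhz = 32.13) {
  ref_ppm + hz / f0_mhz
}

# Frequency offsets (Hz) of each peak relative to the carrier.
peak_offsets_hz <- function(peaks, ref_ppm = 171.0, f0_mhz = 32.13) {
  stats::setNames(ppm_to_hz(peaks$shift_ppm, ref_ppm, f0_mhz), peaks$name)
}
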