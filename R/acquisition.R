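#' Acquisition parameters of the phase-encoded FIDCSI sequence
#'
#' Defaults reproduce a single-slice 2D FIDCSI acquisition: 16 x 16
#' matrix over a 60 mm FOV, 8 mm slice, 256 spectral points at 5 kHz
#' bandwidth, concentric phase-encode ordering with circularly reduced
#' k-space sampling, a variable flip angle schedule, and a 16 s total
#' acquisition starting 30 s after the start of the injection.
#'
#' The first `n_missing` FID points of every encode are lost to the
#' delay between excitation and the start of data acquisition (default
#' 4 points = 0.8 ms at the 0.2 ms dwell time); they are restored later
#' by backward linear prediction.
#'
#' @param matrix phase-encode matrix size per axis
#' @param fov_mm field of view (mm)
#' @param n_spectral nominal FID length (points)
#' @param spectral_bw_hz spectral bandwidth (Hz); dwell = 1/bandwidth
#' @param slice_mm slice thickness (mm)
#' @param total_time_s total acquisition duration (s)
#' @param n_missing FID points lost to the excitation-acquisition delay
#' @param field_t static field (T)
#' @param f0_mhz 13C carrier frequency (MHz)
#' @param ref_ppm carrier position (ppm; on the pyruvate resonance)
#' @param flip_schedule flip angles in degrees, one per sampled encode;
#'   `NULL` selects the constant-signal schedule
#'   \eqn{\theta_i = \arctan(1/\sqrt{N - i})}
#' @param noise_sigma SD of the i.i.d. circular complex Gaussian noise
#'   added to each sampled k-space point
#' @param acq_start_s delay between bolus start and first excitation (s)
#' @param seed integer seed controlling the noise
#' @return an object of class `acquisition_params`
#' @export
acquisition_params <- function(matrix = 16, fov_mm = 60, n_spectral = 256,
                               spectral_bw_hz = 5000, slice_mm = 8,
                               total_time_s = 16, n_missing = 4,
                               field_t = 3, f0_mhz = 32.13, ref_ppm = 171.0,
                               flip_schedule = NULL, noise_sigma = 0,
                               acq_start_s = 30, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_missing < 0) stop("n_missing must be >= 0")
  enc <- concentric_encodes(matrix)
  n_enc <- nrow(enc)
  if (is.null(flip_schedule)) {
    i <- seq_len(n_enc)
    flip_schedule <- atan(1 / sqrt(n_enc - i)) * 180 / pi
    flip_schedule[n_enc] <- 90
  }
  if (length(flip_schedule) != n_enc)
    stop("flip_schedule must have one angle per sampled encode (",
         n_enc, ")")
  if (any(flip_schedule <= 0 | flip_schedule > 90))
    stop("flip angles must lie in (0, 90] degrees")
  # each encode's readout must fit in its share of the acquisition window
  if (n_spectral / spectral_bw_hz > total_time_s / n_enc)
    stop("readout duration exceeds the per-encode acquisition window")
  structure(list(matrix = as.integer(matrix), fov_mm = fov_mm,
                 n_spectral = as.integer(n_spectral),
                 spectral_bw_hz = spectral_bw_hz, slice_mm = slice_mm,
                 total_time_s = total_time_s,
                 n_missing = as.integer(n_missing), field_t = field_t,
                 f0_mhz = f0_mhz, ref_ppm = ref_ppm,
                 flip_schedule = flip_schedule,
                 noise_sigma = noise_sigma, acq_start_s = acq_start_s,
                 seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Concentric, circularly reduced phase-encode ordering
#'
#' The k-space grid is the half-open integer lattice
#' \eqn{[-N/2, N/2)} per axis with k = 0 at 0-based index N/2.
#' Circular reduction keeps encodes with \eqn{\|k\| \le N/2}
#' (inclusive). Encodes are acquired in order of increasing \eqn{\|k\|}
#' from the k-space center, ties broken by polar angle and then by
#' `k_y`.
#'
#' @param matrix grid size per axis
#' @return tibble with integer columns `k_y`, `k_x` (lattice values),
#'   `iy`, `ix` (1-based grid indices) and `order`
#' @export
concentric_encodes <- function(matrix) {
  n <- as.integer(matrix)
  kv <- seq.int(-n / 2, n / 2 - 1)
  g <- expand.grid(k_y = kv, k_x = kv)
  r <- sqrt(g$k_y^2 + g$k_x^2)
  keep <- r <= n / 2
  g <- g[keep, ]
  r <- r[keep]
  ang <- atan2(g$k_x, g$k_y) %% (2 * pi)
  o <- order(r, ang, g$k_y)
  tibble::tibble(
    k_y = as.integer(g$k_y[o]), k_x = as.integer(g$k_x[o]),
    iy = as.integer(g$k_y[o] + n / 2 + 1),
    ix = as.integer(g$k_x[o] + n / 2 + 1),
    order = seq_along(o)
  )
}

# Times (s after bolus start) at which each encode is excited:
# encodes spread uniformly over the acquisition window.
encode_times <- function(acq) {
  n_enc <- length(acq$flip_schedule)
  acq$acq_start_s + (seq_len(n_enc) - 1) * acq$total_time_s / n_enc
}
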