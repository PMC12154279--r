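#' Raw phase-encoded FIDCSI k-space container
#'
#' Holds the complex raw data as a `[k_y, k_x, t]` array on the full
#' phase-encode grid, together with the boolean sampling mask (circular
#' reduction leaves the grid corners unsampled and exactly zero), the
#' concentric acquisition order and the acquisition parameters.
#'
#' The stored FID is truncated: its first sample corresponds to
#' `t = n_missing * dwell` after excitation, and the time dimension has
#' length `n_spectral - n_missing`. Reconstruction restores the missing
#' early points by backward linear prediction.
#'
#' @param data complex array `[matrix, matrix, n_spectral - n_missing]`
#' @param mask logical matrix of sampled encodes
#' @param encode_order tibble from [concentric_encodes()]
#' @param acq an [acquisition_params()]
#' @return an object of class `kspace_data`
#' @export
kspace_data <- function(data, mask, encode_order, acq) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            is.matrix(mask), is.logical(mask),
            inherits(acq, "acquisition_params"))
  unsampled <- which(!mask)
  if (length(unsampled)) {
    flat <- matrix(data, nrow(mask) * ncol(mask), dim(data)[3])
    if (any(flat[unsampled, ] != 0))
      stop("kspace_data must be exactly zero at unsampled encodes")
  }
  idx <- cbind(encode_order$iy, encode_order$ix)
  if (any(!mask[idx]) || sum(mask) != nrow(encode_order))
    stop("encode_order must cover exactly the sampled encodes")
  structure(list(data = data, mask = mask, encode_order = encode_order,
                 acq = acq),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat("<kspace_data> ", d[1], "x", d[2], " grid, ", sum(x$mask),
      " sampled encodes, ", d[3], " stored FID points (",
      x$acq$n_missing, " missing)\n", sep = "")
  invisible(x)
}

#' Synthesize raw FIDCSI k-space data from a phantom
#'
#' Forward model of the hyperpolarized acquisition. For each concentric
#' phase encode, excited at its scheduled time with its scheduled flip
#' angle, the sampled FID is
#' \deqn{s(t) = \sum_m A_m \sin\theta \; e^{(i 2\pi \Delta f_m - 1/T_{2,m}^*) t}}
#' where \eqn{A_m} is the metabolite magnetization of the voxel at the
#' encode's excitation time, depleted by \eqn{\cos\theta} at every
#' previous excitation (hyperpolarized magnetization is consumed, never
#' recovered). Spatial encoding evaluates the centered discrete Fourier
#' transform of the voxel image at the encode's lattice point. The
#' first `n_missing` FID points are discarded, and i.i.d. circular
#' complex Gaussian noise of SD `noise_sigma` is added to every stored
#' sample of every sampled encode.
#'
#' @param phantom a [build_phantom()] result
#' @param acq an [acquisition_params()]; its `matrix` must equal the
#'   phantom grid
#' @param peaks peak table as from [default_peaks()]
#' @param bolus a [bolus_input()]
#' @return a [kspace_data()] object
#' @export
synthesize_kspace <- function(phantom, acq = acquisition_params(),
                              peaks = default_peaks(),
                              bolus = bolus_input()) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(acq, "acquisition_params"))
  validate_peaks(peaks)
  n <- acq$matrix
  if (nrow(phantom$label_map) != n)
    stop("phantom grid must match the acquisition matrix")
  enc <- concentric_encodes(n)
  n_enc <- nrow(enc)
  L <- acq$n_spectral - acq$n_missing
  dwell <- 1 / acq$spectral_bw_hz

  # metabolite dynamics per compartment, sampled at the encode times
  t_enc <- encode_times(acq)
  timebase <- sort(unique(c(seq(0, max(t_enc) + 1, by = 0.1), t_enc)))
  dyn <- compartment_dynamics(phantom, bolus, timebase)
  metabs <- c("pyruvate", "lactate", "bicarbonate", "alanine")
  # M[label, metabolite, encode]
  labs <- names(phantom$kinetics_by_label)
  M <- array(0, c(length(labs), length(metabs), n_enc),
             dimnames = list(labs, metabs, NULL))
  ti <- match(t_enc, timebase)
  for (l in labs) for (m in metabs) M[l, m, ] <- dyn[[l]][[m]][ti]

  # spatial structure factor of each compartment at every encode point
  idx <- cbind(enc$iy, enc$ix)
  Kl <- vapply(labs, function(l) {
    ind <- matrix(0, n, n)
    ind[phantom$label_map == phantom$labels[[l]]] <- 1
    fft2_centered(ind)[idx]
  }, complex(n_enc))                     # [encode, label]
  if (is.null(dim(Kl))) Kl <- matrix(Kl, nrow = n_enc)

  # RF depletion: remaining longitudinal fraction before each encode
  th <- acq$flip_schedule * pi / 180
  dep <- c(1, cumprod(cos(th)))[seq_len(n_enc)]
  w <- sin(th) * dep                     # transverse weight per encode

  # per-encode complex amplitude of each metabolite:
  # amp[m, j] = w_j * sum_l M[l, m, j] * Kl[j, l]
  amp <- matrix(0 + 0i, length(metabs), n_enc)
  tKl <- t(Kl)                           # [label, encode]
  for (mi in seq_along(metabs)) {
    Mm <- matrix(M[, mi, ], nrow = length(labs))
    amp[mi, ] <- w * colSums(Mm * tKl)
  }

  # FID basis per metabolite on the stored (truncated) timebase
  offs <- peak_offsets_hz(peaks, acq$ref_ppm, acq$f0_mhz)
  t_fid <- (acq$n_missing + seq_len(L) - 1) * dwell
  present <- intersect(metabs, peaks$name)
  basis <- vapply(present, function(m) {
    r <- peaks$t2star_s[peaks$name == m]
    exp((2i * pi * offs[[m]] - 1 / r) * t_fid)
  }, complex(L))                         # [t, metabolite]
  if ("pyruvate_hydrate" %in% peaks$name) {
    # hydrate: fixed fraction of the pyruvate pool, non-enzymatic
    r <- peaks$t2star_s[peaks$name == "pyruvate_hydrate"]
    basis <- cbind(basis,
      pyruvate_hydrate = exp((2i * pi * offs[["pyruvate_hydrate"]] - 1 / r) * t_fid))
    amp <- rbind(amp, 0.08 * amp[match("pyruvate", metabs), ])
    present <- c(present, "pyruvate_hydrate")
  }
  amp <- amp[match(present, c(metabs, "pyruvate_hydrate")), , drop = FALSE]

  fid_mat <- basis %*% amp               # [t, encode]

  flat <- matrix(0 + 0i, n * n, L)
  flat[(enc$ix - 1) * n + enc$iy, ] <- t(fid_mat)
  data <- array(flat, c(n, n, L))

  mask <- matrix(FALSE, n, n)
  mask[idx] <- TRUE
  ks <- kspace_data(data, mask, enc, acq)
  if (acq$noise_sigma > 0) ks <- add_kspace_noise(ks) else ks
}

# Add i.i.d. circular complex Gaussian noise (SD acq$noise_sigma per
# real/imaginary component) to every stored sample of every sampled
# encode, reproducibly under acq$seed.
add_kspace_noise <- function(ks) {
  acq <- ks$acq
  if (acq$noise_sigma <= 0) return(ks)
  n <- nrow(ks$mask)
  L <- dim(ks$data)[3]
  n_enc <- nrow(ks$encode_order)
  set.seed(acq$seed)
  noise <- acq$noise_sigma *
    (matrix(stats::rnorm(L * n_enc), L, n_enc) +
       1i * matrix(stats::rnorm(L * n_enc), L, n_enc))
  flat <- matrix(ks$data, n * n, L)
  rows <- (ks$encode_order$ix - 1) * n + ks$encode_order$iy
  flat[rows, ] <- flat[rows, ] + t(noise)
  ks$data <- array(flat, c(n, n, L))
  ks
}

#' Noise level giving a target pyruvate k-space SNR
#'
#' SNR is defined as the peak magnitude of the noiseless k-space
#' center (DC) FID — dominated by the pyruvate resonance — divided by
#' the per-sample complex noise SD.
#'
#' @param phantom,acq,peaks,bolus forward-model inputs as in
#'   [synthesize_kspace()]
#' @param snr target peak-signal-to-noise ratio
#' @return noise SD (a.u.) to pass as `noise_sigma`
#' @export
noise_sigma_for_snr <- function(phantom, acq, snr,
                                peaks = default_peaks(),
                                bolus = bolus_input()) {
  acq0 <- acq
  acq0$noise_sigma <- 0
  ks <- synthesize_kspace(phantom, acq0, peaks, bolus)
  n <- acq$matrix
  dc <- ks$data[n / 2 + 1, n / 2 + 1, ]
  max(Mod(dc)) / snr
}
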