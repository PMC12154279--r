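# Shared fixtures, built once per test run and cached across files.
# Everything is generated in code; no data files.

.shared <- new.env(parent = emptyenv())

get_shared <- function(name, build) {
  if (!exists(name, envir = .shared)) assign(name, build(), envir = .shared)
  get(name, envir = .shared)
}

default_phantom <- function(injured = TRUE) {
  get_shared(paste0("phantom_", injured), function()
    build_phantom(phantom_spec(injured = injured)))
}

# noiseless raw data for the default injured / uninjured phantom
base_kspace <- function(injured = TRUE) {
  get_shared(paste0("ks0_", injured), function()
    synthesize_kspace(default_phantom(injured), acquisition_params()))
}

# noiseless reconstructed subject, reused by recon and quantify tests
noiseless_subject <- function(injured = TRUE) {
  get_shared(paste0("sub0_", injured), function()
    suppressWarnings(simulate_subject(injured = injured, snr = Inf,
                                      seed = 1,
                                      base_kspace = base_kspace(injured))))
}

# FWHM of a peak by linear interpolation of the half-maximum crossings
measure_fwhm <- function(y, x) {
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- max(which(y[1:imax] <= half))
  right <- imax - 1 + min(which(y[imax:length(y)] <= half))
  xl <- x[left] + (x[left + 1] - x[left]) *
    (half - y[left]) / (y[left + 1] - y[left])
  xr <- x[right - 1] + (x[right] - x[right - 1]) *
    (half - y[right - 1]) / (y[right] - y[right - 1])
  xr - xl
}

# spectrum of an FID under the package's spectral convention
# (forward DFT, fftshift, half first point), used as a test oracle
# independent of the reconstruction chain
fid_spectrum <- function(fid, bw, zf = 8) {
  fid[1] <- fid[1] * 0.5
  fid <- c(fid, complex((zf - 1) * length(fid)))
  n <- length(fid)
  sp <- stats::fft(fid)
  sp <- sp[c((floor(n / 2) + 1):n, 1:floor(n / 2))]
  list(spec = sp, freq = (seq_len(n) - 1 - floor(n / 2)) * bw / n)
}
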