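# FFT helpers shared by synthesis and reconstruction.
#
# Conventions (fixed so golden tests are bit-exact):
#  * grids store k = 0 / x = 0 at 0-based index N/2 (1-based N/2 + 1);
#  * fftshift moves the DFT origin to that index, ifftshift undoes it;
#  * the spatial transform k -> image is the centered unitary inverse
#    DFT; the spectral transform FID -> spectrum is the forward DFT
#    followed by fftshift so frequency increases left to right.

fftshift_vec <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1):n], x[1:floor(n / 2)])
}

ifftshift_vec <- function(x) {
  n <- length(x)
  c(x[(ceiling(n / 2) + 1):n], x[1:ceiling(n / 2)])
}

# Apply fftshift / ifftshift along the first two dims of a matrix.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2))
  i2 <- c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))
  m[i1, i2, drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((ceiling(n1 / 2) + 1):n1, 1:ceiling(n1 / 2))
  i2 <- c((ceiling(n2 / 2) + 1):n2, 1:ceiling(n2 / 2))
  m[i1, i2, drop = FALSE]
}

# Centered unitary forward 2D DFT (image -> k-space).
fft2_centered <- function(img) {
  n <- nrow(img) * ncol(img)
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(n)
}

# Centered unitary inverse 2D DFT (k-space -> image).
ifft2_centered <- function(k) {
  n <- nrow(k) * ncol(k)
  fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(n)
}

# fftshifted frequency axis (Hz) for n points at bandwidth bw.
freq_axis_hz <- function(n, bw) {
  (seq_len(n) - 1 - floor(n / 2)) * bw / n
}
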