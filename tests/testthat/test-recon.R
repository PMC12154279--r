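test_that("spatial Hanning apodization weights the sampled radius", {
  ks <- base_kspace()
  ka <- apodize_spatial(ks)
  # center encode untouched (weight 1)
  expect_equal(ka$data[9, 9, ], ks$data[9, 9, ])
  # encode on the sampled-radius edge is zeroed (weight 0)
  expect_true(all(ka$data[1, 9, ] == 0))  # k_y = -8, k_x = 0
  # energy never increases
  expect_lte(sum(Mod(ka$data)^2), sum(Mod(ks$data)^2))
  # unsampled corners stay zero
  flat <- matrix(ka$data, 256, dim(ka$data)[3])
  expect_true(all(flat[!as.vector(ka$mask), ] == 0))
})

test_that("spatial zero-filling embeds the grid centered", {
  ks <- base_kspace()
  expect_identical(zero_fill_spatial(ks, 1), ks)
  k2 <- zero_fill_spatial(ks, 2)
  expect_equal(dim(k2$data)[1:2], c(32, 32))
  # k = 0 stays on the documented center convention
  expect_equal(k2$data[17, 17, ], ks$data[9, 9, ])
  # zero padding adds nothing to the k-space sum (DC image value)
  expect_equal(apply(k2$data, 3, sum), apply(ks$data, 3, sum))
  expect_error(zero_fill_spatial(ks, 1.5), "positive integer")
})

test_that("backward linear prediction restores truncated exponentials", {
  cfg <- recon_config(lp_order = 4, lp_basis_points = 64)
  n <- 0:127

  # identity at n_missing = 0
  x <- exp((2i * pi * 0.1 - 0.02) * n)
  expect_identical(backward_linear_predict(x, 0, cfg), x)

  # single damped exponential, order 1: exact one-pole extension
  z <- exp(2i * pi * 0.07 - 0.015)
  full <- z^(0:131)
  trunc <- full[5:132]
  out <- backward_linear_predict(trunc, 4,
                                 recon_config(lp_order = 1,
                                              lp_basis_points = 32))
  expect_lt(max(Mod(out[1:4] - full[1:4]) / Mod(full[1:4])), 1e-8)
  expect_identical(out[5:132], trunc[5:132 - 4])

  # sums of up to 4 damped exponentials, order >= component count
  set.seed(11)
  for (p in 1:4) {
    zs <- exp(2i * pi * runif(p, -0.4, 0.4) - runif(p, 0.005, 0.03))
    amps <- runif(p, 0.5, 2) * exp(2i * pi * runif(p))
    full <- vapply(0:135, function(k) sum(amps * zs^k), complex(1))
    out <- suppressWarnings(
      backward_linear_predict(full[5:136], 4,
                              recon_config(lp_order = 8,
                                           lp_basis_points = 64)))
    expect_lt(max(Mod(out[1:4] - full[1:4])) / max(Mod(full[1:4])), 1e-8)
  }

  expect_error(backward_linear_predict(x[1:10], 2, cfg),
               "shorter than lp_basis_points")
})

test_that("Voigt apodization follows the linewidth convention", {
  dwell <- 1 / 5000
  n <- 256
  t <- (0:(n - 1)) * dwell

  # zero linewidths: identity
  fid <- exp(2i * pi * 100 * t - pi * 20 * t)
  expect_equal(apodize_voigt(fid, 0, 0, dwell), fid)

  # -5 Hz Lorentzian component narrows a 20 Hz line to 15 Hz FWHM;
  # use a fully decayed FID so truncation ringing does not bias the
  # width measurement
  tl <- (0:4095) * dwell
  fid20 <- exp(-pi * 20 * tl)
  nar <- apodize_voigt(fid20, 0, -5, dwell)
  sp <- fid_spectrum(nar, 5000, zf = 4)
  bin <- 5000 / length(sp$spec)
  expect_lt(abs(measure_fwhm(Re(sp$spec), sp$freq) - 15), bin + 0.05)

  # the in vivo setting (G 25, L -5) on a 20 Hz Lorentzian gives a
  # Voigt line of (G = 25, L = 15); oracle: Olivero-Longbothum
  # closed-form Voigt FWHM, accurate to ~0.02%
  voigt <- apodize_voigt(fid20, 25, -5, dwell)
  spv <- fid_spectrum(voigt, 5000, zf = 4)
  fL <- 15; fG <- 25
  expected <- 0.5346 * fL + sqrt(0.2166 * fL^2 + fG^2)
  expect_lt(abs(measure_fwhm(Re(spv$spec), spv$freq) - expected),
            bin + 0.1)
})

test_that("spectral zero-filling interpolates without adding energy", {
  fid <- exp(2i * pi * 60 * (0:255) / 5000 - (0:255) / 50)
  expect_identical(zero_fill_spectral(fid, 1), fid)
  expect_length(zero_fill_spectral(fid, 8), 2048)
  # magnitude-spectrum integral over the line is invariant
  area <- function(zf) {
    sp <- fid_spectrum(fid, 5000, zf = zf)
    sum(Mod(sp$spec)[abs(sp$freq - 60) <= 100]) * 5000 / length(sp$spec)
  }
  expect_equal(area(8), area(16), tolerance = 1e-3)
  expect_error(zero_fill_spectral(fid, 0), "positive integer")
})

test_that("the reconstruction chain yields calibrated spectral images", {
  img <- noiseless_subject()$image

  # acquisition 16x16 zero-filled by 2, 256 points zero-filled by 8
  expect_equal(dim(img$spectra), c(32, 32, 2048))
  expect_true(img$phased)
  expect_true(all(diff(img$freq_hz) > 0))

  # whole-chain linearity (noise off)
  ks <- base_kspace()
  ks2 <- ks
  ks2$data <- 2.5 * ks2$data
  img2 <- suppressWarnings(reconstruct(ks2))
  expect_equal(img2$spectra, 2.5 * img$spectra, tolerance = 1e-9)
})

test_that("reconstruction localizes an off-center single-peak voxel", {
  ph <- build_phantom(phantom_spec(injured = FALSE))
  ph$label_map[] <- 0L
  ph$label_map[11, 7] <- phantom_labels()[["vessel"]]
  ph$kinetics_by_label <- list(vessel = kinetic_params(
    k_pl = 0, k_pb = 0, k_pa = 0, perfusion_scale = 1))
  # single off-carrier resonance: the voxel's pyruvate pool placed at
  # the lactate chemical shift
  peaks <- default_peaks()[default_peaks()$name == "pyruvate", ]
  peaks$shift_ppm <- 183.2
  ks <- synthesize_kspace(ph, acquisition_params(), peaks)
  img <- suppressWarnings(
    reconstruct(ks, recon_config(phasing = "none")))
  # brightest voxel maps to the upsampled source location
  prof <- apply(Mod(img$spectra), c(1, 2), max)
  pk <- which(prof == max(prof), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(2 * 11 - 1, 2 * 7 - 1), tolerance = 1)
  # peak frequency at the lactate offset within one bin
  vox <- Mod(img$spectra[21, 13, ])
  f_peak <- img$freq_hz[which.max(vox)]
  offset <- ppm_to_hz(peaks$shift_ppm)
  expect_lt(abs(f_peak - offset), 5000 / 2048 + 1e-9)
})

test_that("the spatial FFT stage is unitary (Parseval)", {
  ks <- apodize_spatial(base_kspace())
  cube <- array(ks$data, c(16, 16, dim(ks$data)[3]))
  out <- hpcsi:::apply_spatial_ifft(cube)
  expect_equal(sum(Mod(out)^2), sum(Mod(cube)^2), tolerance = 1e-10)
})

test_that("swapping the LP and Voigt stages changes the output", {
  # LP coefficients are estimated from the data, so apodizing first is
  # not equivalent; lock the stage order
  fid <- {
    set.seed(3)
    zs <- exp(2i * pi * c(0.05, -0.11) - c(0.01, 0.02))
    vapply(4:131, function(k) sum(c(1, 0.5) * zs^k), complex(1)) +
      0.01 * (rnorm(128) + 1i * rnorm(128))
  }
  cfg <- recon_config()
  dwell <- 1 / 5000
  lp_then_voigt <- apodize_voigt(
    backward_linear_predict(fid, 4, cfg), 25, -5, dwell)
  voigt_then_lp <- backward_linear_predict(
    apodize_voigt(fid, 25, -5, dwell), 4, cfg)
  # compare on the restored points (apodization of the observed tail
  # differs trivially; the restored head is the meaningful part)
  expect_false(isTRUE(all.equal(lp_then_voigt[1:4], voigt_then_lp[1:4],
                                tolerance = 1e-6)))
})

test_that("two peaks 100 Hz apart are resolved after apodization", {
  t <- (0:255) / 5000
  fid <- exp(2i * pi * 0 * t - pi * 20 * t) +
    exp(2i * pi * 100 * t - pi * 20 * t)
  ap <- apodize_voigt(fid, 25, -5, 1 / 5000)
  sp <- fid_spectrum(ap, 5000, zf = 8)
  y <- Re(sp$spec)
  keep <- sp$freq > -60 & sp$freq < 160
  yy <- y[keep]
  n_max <- sum(diff(sign(diff(yy))) == -2)
  expect_gte(n_max, 2)
})

test_that("zero-order phasing recovers known rotations", {
  img <- noiseless_subject()$image

  # already-phased spectrum is a fixed point (0 +/- 1 degree)
  rephase <- phase_correct(img)
  ratio <- rephase$spectra[17, 17, ] / img$spectra[17, 17, ]
  expect_lt(abs(Arg(mean(ratio[Mod(img$spectra[17, 17, ]) > 1e-6]))),
            pi / 180)

  # a known 37-degree rotation is removed
  rot <- img
  rot$spectra <- rot$spectra * exp(1i * 37 * pi / 180)
  rot$phased <- FALSE
  back <- phase_correct(rot)
  expect_equal(back$spectra[17, 17, ], img$spectra[17, 17, ],
               tolerance = 1e-6)

  # the zero-order estimate is absorption-optimal: the phased real
  # integral attains >= 99.9% of the modulus of the complex window
  # integral (the supremum over all zero-order phases) for an
  # isolated noiseless Lorentzian
  t <- (0:2047) / 5000
  lor <- exp(2i * pi * 30 * t - pi * 12 * t) * exp(1i * 1.1)
  sp <- fid_spectrum(lor, 5000, zf = 1)
  win <- abs(sp$freq - 30) <= 60
  phi <- Arg(sum(sp$spec[win]))
  real_int <- sum(Re(sp$spec[win] * exp(-1i * phi)))
  best <- Mod(sum(sp$spec[win]))
  expect_gte(real_int, 0.999 * best)
})
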