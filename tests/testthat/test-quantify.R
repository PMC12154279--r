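test_that("absorption-mode integration matches the Lorentzian closed form", {
  freq <- seq(-2500, 2500 - 5000 / 8192, length.out = 8192)

  # zero spectrum integrates to zero
  expect_equal(integrate_peak(rep(0 + 0i, 8192), freq, 0), 0)

  # unit-area 20 Hz-FWHM Lorentzian: the 44 Hz window captures
  # (2/pi) atan(44/20) of the total area
  gam <- 10
  lor <- (gam / pi) / (gam^2 + freq^2)
  captured <- integrate_peak(lor, freq, 0, window = 44)
  expect_equal(captured, (2 / pi) * atan(44 / 20), tolerance = 0.005)

  # linearity
  expect_equal(integrate_peak(2 * lor, freq, 0, 44), 2 * captured)

  expect_error(integrate_peak(lor, freq, 0, window = 0.1),
               "narrower than one bin")
  expect_error(integrate_peak(lor, freq, 2490), "beyond the frequency axis")
})

test_that("metabolite maps integrate the phased spectra on a 32x32 grid", {
  img <- noiseless_subject()$image
  maps <- compute_metabolite_maps(img)
  expect_s3_class(maps, "metabolite_maps")
  expect_equal(dim(maps$maps$pyruvate), c(32, 32))
  expect_setequal(names(maps$maps),
                  c("pyruvate", "lactate", "bicarbonate", "alanine"))

  # all-zero spectra give all-zero maps
  img0 <- img
  img0$spectra[] <- 0 + 0i
  # (zero input cannot be phased; integrate the phased flag as-is)
  maps0 <- compute_metabolite_maps(img0)
  for (m in maps0$maps) expect_true(all(m == 0))

  # unphased input is rejected
  img$phased <- FALSE
  expect_error(compute_metabolite_maps(img), "phased")

  # overlapping windows are named in the error
  peaks <- default_peaks()
  peaks$shift_ppm[peaks$name == "lactate"] <-
    peaks$shift_ppm[peaks$name == "pyruvate"] + 0.5
  img$phased <- TRUE
  expect_error(compute_metabolite_maps(img, peaks),
               "overlap.*pyruvate.*lactate")
})

test_that("a one-hemisphere metabolite maps to that hemisphere", {
  # vessel compartment relabelled into the left hemisphere only, with
  # all conversion off elsewhere: lactate support must stay left
  ph <- build_phantom(phantom_spec(injured = FALSE))
  none <- kinetic_params(k_pl = 0, k_pb = 0, k_pa = 0)
  ph$kinetics_by_label <- list(
    brain_ipsi = kinetic_params(k_pl = 0.04, k_pb = 0, k_pa = 0),
    brain_contra = none, muscle = none, vessel = none)
  ks <- synthesize_kspace(ph, acquisition_params())
  img <- suppressWarnings(reconstruct(ks))
  maps <- compute_metabolite_maps(img)
  lac <- maps$maps$lactate
  thr <- 0.05 * max(lac)
  support_cols <- which(apply(lac > thr, 2, any))
  # left hemisphere ends at the midline column 17; allow 1 voxel of
  # point spread
  expect_true(all(support_cols <= 18))
})

test_that("ratio maps are masked, floored and scale-invariant", {
  sub <- noiseless_subject()
  maps <- compute_metabolite_maps(sub$image)
  rois <- sub$rois
  rat <- compute_ratio_maps(maps, rois$brain, floor = 1e-9)
  expect_true(all(is.na(rat$maps$bic_pyr[!rois$brain])))
  expect_true(any(is.finite(rat$maps$bic_pyr)))

  # global intensity scaling cancels
  maps10 <- maps
  for (m in names(maps10$maps)) maps10$maps[[m]] <- 10 * maps10$maps[[m]]
  rat10 <- compute_ratio_maps(maps10, rois$brain, floor = 1e-8)
  expect_equal(rat10$maps$lac_pyr, rat$maps$lac_pyr, tolerance = 1e-12)

  # denominator below the floor is undefined, not zero
  big_floor <- max(maps$maps$pyruvate) * 2
  rat_f <- compute_ratio_maps(maps, rois$brain, floor = big_floor)
  expect_true(all(is.na(rat_f$maps$bic_pyr)))

  expect_error(compute_ratio_maps(maps, matrix(FALSE, 32, 32)), "empty")
})

test_that("ROI averaging is linear with CLT noise reduction", {
  sub <- noiseless_subject()
  img <- sub$image
  # single-voxel ROI returns that voxel
  roi1 <- matrix(FALSE, 32, 32)
  roi1[17, 17] <- TRUE
  s1 <- average_roi_spectrum(img, roi1)
  expect_equal(as.vector(s1), img$spectra[17, 17, ])

  # identical voxels average to themselves
  img2 <- img
  flat <- matrix(img2$spectra, 1024, 2048)
  flat <- flat[rep(561L, 1024), ]  # voxel (17, 18): 17 + 17 * 32
  img2$spectra <- array(flat, dim(img2$spectra))
  roi <- matrix(TRUE, 32, 32)
  expect_equal(as.vector(average_roi_spectrum(img2, roi)),
               img$spectra[17, 18, ], tolerance = 1e-12)

  # noise averages down as sigma/sqrt(N)
  set.seed(9)
  sds <- replicate(30, {
    noise <- array(rnorm(16 * 16 * 64), c(16, 16, 64))
    m25 <- matrix(FALSE, 16, 16); m25[1:5, 1:5] <- TRUE
    c(sd(apply(noise, 3, function(sl) mean(sl[m25]))), sd(noise[1, 1, ]))
  })
  expect_equal(mean(sds[1, ]) / mean(sds[2, ]), 1 / 5, tolerance = 0.1)

  expect_error(average_roi_spectrum(img, matrix(FALSE, 32, 32)), "empty")
})

test_that("Gaussian peak fitting recovers parameters and rejects noise", {
  freq <- seq(-500, 500, by = 0.5)

  # exact Gaussian: parameters recovered to high precision
  truth <- 5 * exp(-(freq - 0)^2 / (2 * 10^2)) + 0.2
  ft <- fit_peak_gaussian(truth, freq, 0, search_window = 200,
                          noise_sd = 0.01)
  expect_equal(ft$amplitude, 5, tolerance = 1e-6)
  expect_equal(ft$sigma, 10, tolerance = 1e-6)
  expect_equal(ft$center, 0, tolerance = 1e-6)
  expect_equal(ft$area, 5 * 10 * sqrt(2 * pi), tolerance = 1e-6)
  expect_false(ft$rejected)

  # SNR 20: median area error below 5% over 50 noise draws
  set.seed(21)
  errs <- replicate(50, {
    y <- truth + rnorm(length(freq), sd = 5 / 20)
    f <- fit_peak_gaussian(y, freq, 0, search_window = 200,
                           noise_sd = 5 / 20)
    abs(f$area - 5 * 10 * sqrt(2 * pi)) / (5 * 10 * sqrt(2 * pi))
  })
  expect_lt(median(errs), 0.05)

  # pure noise: rejected by the 3-sigma amplitude rule
  set.seed(22)
  rejections <- replicate(20, {
    f <- fit_peak_gaussian(rnorm(length(freq), sd = 1), freq, 0,
                           search_window = 200, noise_sd = 1)
    f$rejected
  })
  expect_gt(mean(rejections), 0.9)
})

test_that("ROI quantification recovers compartment ratios", {
  sub <- noiseless_subject()
  # integral-map and ROI-fit estimates of Bic/Pyr agree within 15%
  maps <- compute_metabolite_maps(sub$image)
  roi <- sub$rois$contra
  map_ratio <- sum(maps$maps$bicarbonate[roi]) / sum(maps$maps$pyruvate[roi])
  rt <- roi_ratio_table(sub$quant)
  fit_ratio <- rt$bic_pyr[rt$roi == "contra"]
  expect_equal(fit_ratio, map_ratio, tolerance = 0.15)

  # a noisy subject at SNR 30 recovers the noiseless ratio within 10%
  noisy <- suppressWarnings(simulate_subject(injured = TRUE, snr = 30,
                                             seed = 77,
                                             base_kspace = base_kspace()))
  rtn <- roi_ratio_table(noisy$quant)
  expect_equal(rtn$bic_pyr[rtn$roi == "contra"],
               rt$bic_pyr[rt$roi == "contra"], tolerance = 0.10)

  # missing required ROI errors
  expect_error(quantify_rois(sub$image, sub$rois[c("ipsi", "contra")]),
               "muscle")
})

test_that("a metabolite absent from the brain is flagged rejected", {
  ph <- build_phantom(phantom_spec(injured = FALSE))
  # no alanine production anywhere
  for (nm in names(ph$kinetics_by_label)) {
    k <- ph$kinetics_by_label[[nm]]
    ph$kinetics_by_label[[nm]] <- kinetic_params(
      k_pl = k$k_pl, k_pb = k$k_pb, k_pa = 0,
      perfusion_scale = k$perfusion_scale)
  }
  acq <- acquisition_params(noise_sigma = 0)
  ks <- synthesize_kspace(ph, acq)
  ks$acq$noise_sigma <- max(Mod(ks$data[9, 9, ])) / 30
  ks <- hpcsi:::add_kspace_noise(ks)
  img <- suppressWarnings(reconstruct(ks))
  q <- quantify_rois(img, phantom_rois(ph, 2))
  expect_true(all(q$rejected[q$metabolite == "alanine"]))
  expect_true(all(is.na(q$area[q$metabolite == "alanine"])))
})

test_that("increasing lesion k_PB monotonically raises recovered Bic/Pyr", {
  # noise off; whole-brain k_PB scaled over a grid
  vals <- vapply(c(0.004, 0.007, 0.010, 0.013, 0.016), function(kpb) {
    ph <- build_phantom(phantom_spec(injured = FALSE))
    for (nm in c("brain_ipsi", "brain_contra")) {
      ph$kinetics_by_label[[nm]] <- kinetic_params(k_pb = kpb)
    }
    ks <- synthesize_kspace(ph, acquisition_params())
    img <- suppressWarnings(reconstruct(ks))
    q <- quantify_rois(img, phantom_rois(ph, 2))
    rt <- roi_ratio_table(q)
    rt$bic_pyr[rt$roi == "contra"]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
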