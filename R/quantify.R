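#' Integrate an absorption-mode peak
#'
#' Sums the real part of a phased spectrum over the bins whose centers
#' lie within `[center - window/2, center + window/2]` and scales by
#' the bin width, approximating the absorption-mode integral in
#' signal units x Hz. The default 44 Hz window captures
#' \eqn{(2/\pi)\arctan(44/20) \approx 0.728} of a 20 Hz-FWHM
#' Lorentzian line.
#'
#' @param spectrum complex or real spectrum
#' @param freq_hz frequency axis (Hz), same length, monotone
#' @param center window center (Hz)
#' @param window window width (Hz); must exceed the bin width
#' @return integrated area (a.u.)
#' @export
integrate_peak <- function(spectrum, freq_hz, center, window = 44) {
  stopifnot(length(spectrum) == length(freq_hz))
  df <- freq_hz[2] - freq_hz[1]
  if (window <= df) stop("integration window narrower than one bin")
  if (center - window / 2 < freq_hz[1] ||
      center + window / 2 > freq_hz[length(freq_hz)])
    stop("integration window extends beyond the frequency axis")
  inwin <- freq_hz >= center - window / 2 & freq_hz <= center + window / 2
  sum(Re(spectrum[inwin])) * df
}

#' Metabolite maps by absorption-mode peak integration
#'
#' Produces one real-valued map per metabolite by integrating the
#' phased spectra within a 44 Hz window around each peak. Peak centers
#' are referenced globally: the pyruvate peak is located in the
#' highest-SNR voxel (maximum magnitude within a search window around
#' the nominal pyruvate offset) and the other centers are placed at
#' fixed chemical-shift offsets from it — a per-voxel search would fail
#' on low-SNR bicarbonate.
#'
#' @param img a phased [spectral_image()]
#' @param peaks peak table as from [default_peaks()]
#' @param window integration window width (Hz)
#' @param search_window width (Hz) of the global pyruvate search
#' @return an object of class `metabolite_maps`: list of per-metabolite
#'   matrices plus the window, the resolved centers and a noise
#'   estimate per map
#' @export
compute_metabolite_maps <- function(img, peaks = default_peaks(),
                                    window = 44, search_window = 100) {
  stopifnot(inherits(img, "spectral_image"))
  if (!img$phased) stop("spectra must be phased before integration")
  validate_peaks(peaks)
  offs <- peak_offsets_hz(peaks, img$acq$ref_ppm, img$acq$f0_mhz)
  ord <- order(offs)
  gaps <- diff(offs[ord])
  if (any(gaps < window)) {
    i <- which(gaps < window)[1]
    stop("integration windows overlap for ",
         names(offs)[ord][i], " and ", names(offs)[ord][i + 1])
  }

  # global frequency reference from the max-SNR pyruvate voxel
  pyr_off <- offs[["pyruvate"]]
  insearch <- abs(img$freq_hz - pyr_off) <= search_window / 2
  d <- dim(img$spectra)
  flat <- matrix(img$spectra, d[1] * d[2], d[3])
  sub <- Mod(flat[, insearch, drop = FALSE])
  vox <- which.max(apply(sub, 1, max))
  ref_center <- img$freq_hz[insearch][which.max(sub[vox, ])]
  centers <- ref_center + (offs - pyr_off)

  df <- img$freq_hz[2] - img$freq_hz[1]
  maps <- lapply(stats::setNames(names(offs), names(offs)), function(m) {
    inwin <- abs(img$freq_hz - centers[[m]]) <= window / 2
    matrix(rowSums(Re(flat[, inwin, drop = FALSE])) * df, d[1], d[2])
  })
  noise_sd <- spectral_noise_sd(img) * df *
    sqrt(sum(abs(img$freq_hz - centers[[1]]) <= window / 2))
  structure(list(maps = maps, window = window, centers = centers,
                 noise_sd = noise_sd, fov_mm = img$acq$fov_mm),
            class = "metabolite_maps")
}

#' @export
print.metabolite_maps <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat("<metabolite_maps> ", paste(names(x$maps), collapse = ", "),
      " on a ", d[1], "x", d[2], " grid (", x$window,
      " Hz windows)\n", sep = "")
  invisible(x)
}

#' Tidy a set of metabolite or ratio maps
#'
#' @param x a `metabolite_maps` object
#' @param ... unused
#' @return tibble with columns `y`, `x`, `metabolite`, `value`
#' @exportS3Method generics::tidy
tidy.metabolite_maps <- function(x, ...) {
  purrr::imap_dfr(x$maps, function(m, nm) {
    tibble::tibble(y = rep(seq_len(nrow(m)), ncol(m)),
                   x = rep(seq_len(ncol(m)), each = nrow(m)),
                   metabolite = nm, value = as.vector(m))
  })
}

#' Masked voxelwise metabolite ratio maps
#'
#' Computes Lac/Pyr, Bic/Pyr, Bic/Lac and Ala/Pyr within a brain mask.
#' Voxels whose denominator falls below the floor (default 3x the map
#' noise SD, estimated from background voxels) are set to `NA` —
#' undefined, not zero — and are excluded from any downstream summary.
#' Ratios are invariant under global intensity scaling.
#'
#' @param maps a [compute_metabolite_maps()] result
#' @param brain_mask logical matrix matching the map grid
#' @param floor denominator floor (a.u.); `NULL` uses 3x the map noise
#' @return a `ratio_maps` object (list of matrices with `NA` where
#'   undefined)
#' @export
compute_ratio_maps <- function(maps, brain_mask, floor = NULL) {
  stopifnot(inherits(maps, "metabolite_maps"))
  if (!any(brain_mask)) stop("brain mask is empty")
  if (is.null(floor)) floor <- 3 * maps$noise_sd
  if (floor < 0) stop("floor must be >= 0")
  pairs <- list(lac_pyr = c("lactate", "pyruvate"),
                bic_pyr = c("bicarbonate", "pyruvate"),
                bic_lac = c("bicarbonate", "lactate"),
                ala_pyr = c("alanine", "pyruvate"))
  pairs <- purrr::keep(pairs, ~ all(.x %in% names(maps$maps)))
  ratio <- lapply(pairs, function(p) {
    num <- maps$maps[[p[1]]]
    den <- maps$maps[[p[2]]]
    r <- num / den
    r[!brain_mask | den < floor] <- NA_real_
    r
  })
  structure(list(maps = ratio, floor = floor, window = maps$window,
                 fov_mm = maps$fov_mm),
            class = c("ratio_maps", "metabolite_maps"))
}

#' ROI-averaged complex spectrum
#'
#' @param img a [spectral_image()]
#' @param roi logical matrix matching the spatial grid
#' @return complex vector (mean spectrum over the ROI voxels) with the
#'   frequency axis attached as attribute `freq_hz`
#' @export
average_roi_spectrum <- function(img, roi) {
  stopifnot(inherits(img, "spectral_image"))
  d <- dim(img$spectra)
  if (!is.matrix(roi) || any(dim(roi) != d[1:2]))
    stop("ROI mask must match the spatial grid")
  if (!any(roi)) stop("ROI is empty")
  flat <- matrix(img$spectra, d[1] * d[2], d[3])
  s <- colMeans(flat[as.vector(roi), , drop = FALSE])
  attr(s, "freq_hz") <- img$freq_hz
  attr(s, "n_voxels") <- sum(roi)
  s
}

#' Gaussian fit of a single metabolite peak
#'
#' Nonlinear least squares of
#' \eqn{A \exp(-(f - c)^2 / 2\sigma^2) + b}
#' over a search window of the real (absorption-mode) spectrum,
#' initialized from the window maximum and second moment. The fitted
#' area is \eqn{A \sigma \sqrt{2\pi}}. Fits with amplitude below 3x the
#' spectral noise SD are rejected (`area = NA`); non-convergence is
#' flagged, never thrown.
#'
#' @param spectrum complex or real phased spectrum
#' @param freq_hz frequency axis (Hz)
#' @param center nominal peak center (Hz)
#' @param search_window fit window width (Hz)
#' @param noise_sd spectral noise SD used for the 3-sigma rejection
#'   rule; `NULL` estimates it from the band edges
#' @return one-row tibble of class `peak_fit`: `center`, `amplitude`,
#'   `sigma`, `area`, `baseline`, `rmse`, `converged`, `rejected`
#' @export
fit_peak_gaussian <- function(spectrum, freq_hz, center,
                              search_window = 80, noise_sd = NULL) {
  stopifnot(length(spectrum) == length(freq_hz))
  y <- Re(spectrum)
  if (is.null(noise_sd)) {
    nf <- length(y)
    edge <- c(seq_len(ceiling(nf * 0.05)), (nf - ceiling(nf * 0.05) + 1):nf)
    noise_sd <- stats::sd(y[edge])
  }
  inwin <- abs(freq_hz - center) <= search_window / 2
  f <- freq_hz[inwin]
  yy <- y[inwin]
  b0 <- stats::median(yy)
  a0 <- max(yy) - b0
  c0 <- f[which.max(yy)]
  wpos <- pmax(yy - b0, 0)
  s0 <- sqrt(sum(wpos * (f - c0)^2) / max(sum(wpos), 1e-12))
  if (!is.finite(s0) || s0 <= 0) s0 <- search_window / 8

  row <- tibble::tibble(center = NA_real_, amplitude = NA_real_,
                        sigma = NA_real_, area = NA_real_,
                        baseline = NA_real_, rmse = NA_real_,
                        converged = FALSE, rejected = TRUE)
  residual <- function(p) {
    yy - (p[1] * exp(-(f - p[2])^2 / (2 * p[3]^2)) + p[4])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a0, c0, s0, b0), fn = residual,
      lower = c(-Inf, min(f), 1e-3, -Inf),
      upper = c(Inf, max(f), search_window, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info == 0 || fit$info == 9) {
    class(row) <- c("peak_fit", class(row))
    return(row)
  }
  p <- fit$par
  row$center <- p[2]
  row$amplitude <- p[1]
  row$sigma <- p[3]
  row$baseline <- p[4]
  row$rmse <- sqrt(mean(residual(p)^2))
  row$converged <- TRUE
  row$rejected <- !is.finite(p[1]) || p[1] < 3 * noise_sd
  if (!row$rejected) row$area <- p[1] * p[3] * sqrt(2 * pi)
  class(row) <- c("peak_fit", class(row))
  row
}

#' Quantify metabolites in hemisphere and muscle ROIs
#'
#' Averages the phased spectra over each ROI, fits each metabolite
#' peak with [fit_peak_gaussian()] (peak centers referenced globally as
#' in [compute_metabolite_maps()]) and tabulates the fitted areas.
#'
#' @param img a phased [spectral_image()]
#' @param rois named list of logical ROI masks; must include `ipsi`,
#'   `contra` and `muscle`
#' @param peaks peak table
#' @param subject,group identifiers copied into the table
#' @param search_window fit window width (Hz)
#' @return tibble (class `roi_quant`) with one row per ROI x
#'   metabolite: `subject`, `group`, `roi`, `metabolite`, `area`,
#'   `amplitude`, `sigma`, `center`, `rmse`, `rejected`
#' @export
quantify_rois <- function(img, rois, peaks = default_peaks(),
                          subject = "s1", group = "naive",
                          search_window = 80) {
  stopifnot(inherits(img, "spectral_image"))
  if (!all(c("ipsi", "contra", "muscle") %in% names(rois)))
    stop("rois must include ipsi, contra and muscle")
  validate_peaks(peaks)
  offs <- peak_offsets_hz(peaks, img$acq$ref_ppm, img$acq$f0_mhz)

  # global reference from the whole-image max-SNR pyruvate voxel
  mm <- compute_metabolite_maps(img, peaks, search_window = search_window)
  centers <- mm$centers

  rows <- purrr::imap_dfr(rois[c("ipsi", "contra", "muscle")],
                          function(roi, roi_name) {
    s <- average_roi_spectrum(img, roi)
    freq <- attr(s, "freq_hz")
    nf <- length(s)
    edge <- c(seq_len(ceiling(nf * 0.05)), (nf - ceiling(nf * 0.05) + 1):nf)
    nsd <- stats::sd(Re(s)[edge])
    purrr::imap_dfr(centers, function(ctr, metab) {
      ft <- fit_peak_gaussian(s, freq, ctr, search_window, noise_sd = nsd)
      tibble::tibble(subject = subject, group = group, roi = roi_name,
                     metabolite = metab, area = ft$area,
                     amplitude = ft$amplitude, sigma = ft$sigma,
                     center = ft$center, rmse = ft$rmse,
                     rejected = ft$rejected)
    })
  })
  class(rows) <- c("roi_quant", class(rows))
  rows
}

#' Derived ratio metrics from an ROI quantification table
#'
#' Computes, per subject and hemisphere ROI, the product-substrate and
#' product-product ratios Lac/Pyr, Bic/Pyr, Bic/Lac and Ala/Pyr, plus
#' metabolite signals normalized to the fitted muscle alanine
#' (`X/Ala_muscle`), an internal reference that cancels receive gain
#' and polarization differences between subjects. Ratios are `NA`
#' where the denominator fit was rejected or non-positive; a missing
#' muscle alanine fit leaves the normalized columns `NA` with a
#' warning.
#'
#' @param quant a [quantify_rois()] table (several subjects may be
#'   row-bound together)
#' @return tibble with one row per subject x hemisphere ROI and
#'   columns `lac_pyr`, `bic_pyr`, `bic_lac`, `ala_pyr`,
#'   `pyr_ala_muscle`, `lac_ala_muscle`, `bic_ala_muscle`,
#'   `ala_ala_muscle`
#' @export
roi_ratio_table <- function(quant) {
  stopifnot(is.data.frame(quant))
  wide <- quant |>
    dplyr::select(dplyr::all_of(c("subject", "group", "roi",
                                  "metabolite", "area"))) |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "area")
  for (m in c("pyruvate", "lactate", "bicarbonate", "alanine"))
    if (!m %in% names(wide)) wide[[m]] <- NA_real_

  ala_muscle <- wide |>
    dplyr::filter(.data$roi == "muscle") |>
    dplyr::select(dplyr::all_of(c("subject", "alanine"))) |>
    dplyr::rename(ala_muscle = "alanine")
  if (any(!is.finite(ala_muscle$ala_muscle)))
    warning("muscle alanine fit missing for some subjects; ",
            "normalized columns undefined there")

  safe_ratio <- function(num, den) ifelse(is.finite(den) & den > 0,
                                          num / den, NA_real_)
  wide |>
    dplyr::filter(.data$roi %in% c("ipsi", "contra")) |>
    dplyr::left_join(ala_muscle, by = "subject") |>
    dplyr::mutate(
      lac_pyr = safe_ratio(.data$lactate, .data$pyruvate),
      bic_pyr = safe_ratio(.data$bicarbonate, .data$pyruvate),
      bic_lac = safe_ratio(.data$bicarbonate, .data$lactate),
      ala_pyr = safe_ratio(.data$alanine, .data$pyruvate),
      pyr_ala_muscle = safe_ratio(.data$pyruvate, .data$ala_muscle),
      lac_ala_muscle = safe_ratio(.data$lactate, .data$ala_muscle),
      bic_ala_muscle = safe_ratio(.data$bicarbonate, .data$ala_muscle),
      ala_ala_muscle = safe_ratio(.data$alanine, .data$ala_muscle)
    )
}
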