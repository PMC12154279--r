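#' Specify a digital ferret-head phantom
#'
#' The phantom emulates the anatomy seen in an axial hyperpolarized
#' 13C slice through the ferret brain: an elliptical brain split into
#' ipsilateral and contralateral hemispheres, a surrounding muscle/scalp
#' layer (which contributes strong alanine signal), a vascular pool and,
#' for injured subjects, a focal lesion in the ipsilateral hemisphere
#' with reduced oxidative (Pyr->Bic) conversion.
#'
#' All geometry is symmetric about the midline except the lesion, so an
#' uninjured phantom is exactly mirror-symmetric.
#'
#' @param matrix grid size (native acquisition matrix, >= 8)
#' @param fov_mm field of view (mm)
#' @param injured include the lesion compartment?
#' @param lesion_side `"left"` (ipsilateral default) or `"right"`
#' @param lesion_radius_mm lesion radius (mm)
#' @param lesion_center_mm lesion center as c(x, y) in mm for the left
#'   side; mirrored in x for `lesion_side = "right"`
#' @param kpb_lesion_factor multiplicative reduction of `k_pb` in the
#'   lesion (default 0.5: oxidative conversion halved)
#' @param kinetics optional named list of [kinetic_params()] overriding
#'   the per-compartment defaults (names among `brain_ipsi`,
#'   `brain_contra`, `lesion`, `muscle`, `vessel`)
#' @return a `phantom_spec` list understood by [build_phantom()]
#' @export
phantom_spec <- function(matrix = 16, fov_mm = 60, injured = TRUE,
                         lesion_side = c("left", "right"),
                         lesion_radius_mm = 5,
                         lesion_center_mm = c(-8, 4),
                         kpb_lesion_factor = 0.5,
                         kinetics = list()) {
  lesion_side <- match.arg(lesion_side)
  if (matrix < 8) stop("phantom matrix must be >= 8")
  structure(list(matrix = as.integer(matrix), fov_mm = fov_mm,
                 injured = injured, lesion_side = lesion_side,
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_center_mm = lesion_center_mm,
                 kpb_lesion_factor = kpb_lesion_factor,
                 kinetics = kinetics),
            class = "phantom_spec")
}

#' Integer codes of phantom compartments
#' @export
phantom_labels <- function() {
  c(background = 0L, brain_ipsi = 1L, brain_contra = 2L,
    lesion = 3L, muscle = 4L, vessel = 5L)
}

default_compartment_kinetics <- function(kpb_lesion_factor = 0.5) {
  brain <- kinetic_params(k_pl = 0.02, k_pb = 0.010, k_pa = 0.002)
  list(
    brain_ipsi = brain,
    brain_contra = brain,
    lesion = kinetic_params(k_pl = 0.02, k_pb = 0.010 * kpb_lesion_factor,
                            k_pa = 0.002),
    muscle = kinetic_params(k_pl = 0.012, k_pb = 0.002, k_pa = 0.012,
                            perfusion_scale = 0.7),
    vessel = kinetic_params(k_pl = 0, k_pb = 0, k_pa = 0,
                            perfusion_scale = 3)
  )
}

#' Build a labeled compartment phantom
#'
#' Deterministic: the same spec always yields the same label map.
#' The midline voxel column (x = 0, on the DFT center) belongs to
#' neither hemisphere, so the ipsi and contra labels are disjoint
#' mirror images: flipping the lesion side reflects the label map
#' about the center column exactly.
#'
#' @param spec a [phantom_spec()]
#' @return an object of class `phantom` with fields `label_map`
#'   (integer matrix, rows = y, cols = x), `labels`, `kinetics_by_label`
#'   and `grid_fov_mm`
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$matrix
  vox <- spec$fov_mm / n
  # voxel-center coordinates; x = 0 sits on the DFT center voxel
  # (0-based index n/2), matching the k-space center convention, so a
  # symmetric phantom stays symmetric through the Fourier chain
  coord <- (seq_len(n) - 1 - n / 2) * vox
  xs <- matrix(coord, n, n, byrow = TRUE)   # x varies along columns
  ys <- matrix(coord, n, n, byrow = FALSE)  # y varies along rows
  lab <- matrix(phantom_labels()[["background"]], n, n)

  # muscle/scalp: elliptical annulus around the brain (semi-axes in mm)
  head_ellipse <- (xs / 25)^2 + (ys / 22)^2 <= 1
  brain_ellipse <- (xs / 17)^2 + (ys / 14)^2 <= 1
  lab[head_ellipse & !brain_ellipse] <- phantom_labels()[["muscle"]]
  # the ipsilateral (lesion-bearing) hemisphere is on lesion_side
  side <- if (spec$lesion_side == "left") -1 else 1
  lab[brain_ellipse & side * xs > 0] <- phantom_labels()[["brain_ipsi"]]
  lab[brain_ellipse & side * xs < 0] <- phantom_labels()[["brain_contra"]]

  # vascular pool: small disc below the brain (sagittal sinus / jugular)
  vessel <- (xs^2 + (ys + 26)^2) <= 4.2^2
  lab[vessel] <- phantom_labels()[["vessel"]]

  if (isTRUE(spec$injured)) {
    cx <- side * abs(spec$lesion_center_mm[1])
    cy <- spec$lesion_center_mm[2]
    hemi_width <- 17  # brain semi-axis in x (mm)
    if (abs(cx) + spec$lesion_radius_mm > hemi_width)
      stop("lesion extends beyond the hemisphere")
    les <- ((xs - cx)^2 + (ys - cy)^2) <= spec$lesion_radius_mm^2
    lab[les & lab == phantom_labels()[["brain_ipsi"]]] <-
      phantom_labels()[["lesion"]]
  }

  kin <- default_compartment_kinetics(spec$kpb_lesion_factor)
  for (nm in names(spec$kinetics)) {
    if (!nm %in% names(kin)) stop("unknown compartment in kinetics: ", nm)
    stopifnot(inherits(spec$kinetics[[nm]], "kinetic_params"))
    kin[[nm]] <- spec$kinetics[[nm]]
  }
  if (!isTRUE(spec$injured)) kin$lesion <- NULL

  structure(list(label_map = lab, labels = phantom_labels(),
                 kinetics_by_label = kin, grid_fov_mm = spec$fov_mm,
                 spec = spec),
            class = "phantom")
}

# Logical mask of the voxels carrying a given compartment label.
phantom_mask <- function(phantom, compartment) {
  phantom$label_map == phantom$labels[[compartment]]
}

#' Derive hemisphere and muscle ROI masks from a phantom
#'
#' Mirrored hemispheric ROIs are taken from the phantom labels (the
#' ipsilateral ROI includes the lesion voxels). To match a zero-filled
#' reconstruction grid the phantom geometry is re-rasterized at the
#' finer resolution (same millimetre shapes, `factor` times the
#' matrix), which keeps the ipsi and contra masks exact mirror images
#' on the reconstruction grid.
#'
#' @param phantom a [build_phantom()] result
#' @param factor integer upsampling factor (e.g. the spatial
#'   zero-filling factor of the reconstruction)
#' @return named list of logical matrices: `ipsi`, `contra`, `muscle`,
#'   `brain`
#' @export
phantom_rois <- function(phantom, factor = 1) {
  stopifnot(inherits(phantom, "phantom"))
  if (factor > 1) {
    spec <- phantom$spec
    spec$matrix <- spec$matrix * as.integer(factor)
    phantom <- build_phantom(spec)
  }
  ipsi <- phantom_mask(phantom, "brain_ipsi")
  if ("lesion" %in% names(phantom$kinetics_by_label))
    ipsi <- ipsi | phantom_mask(phantom, "lesion")
  rois <- list(ipsi = ipsi,
               contra = phantom_mask(phantom, "brain_contra"),
               muscle = phantom_mask(phantom, "muscle"))
  rois$brain <- rois$ipsi | rois$contra
  rois
}
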