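---
title: "Methods: simulating and analysing hyperpolarized 13C pyruvate FIDCSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing hyperpolarized 13C pyruvate FIDCSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hpcsi` implements a complete analysis chain for single-time-point 2D
phase-encoded FIDCSI of hyperpolarized [1-13C]pyruvate in the injured
brain: a synthetic-data generator that emulates the acquisition, the
spectral-image reconstruction, metabolite-map and ROI quantification,
and the hemisphere/group statistics. Because hyperpolarized animal
data are rarely deposited, the generator is a first-class, tested
module: every downstream stage is validated against phantoms whose
ground truth is known by construction.

# Forward model

## Kinetics

Each tissue compartment follows unidirectional precursor–product
exchange. With delivery rate $u(t)$ (a gamma-variate bolus),

$$\frac{dM_P}{dt} = u(t) - (r_{1,P} + k_{PL} + k_{PB} + k_{PA})\,M_P,
\qquad
\frac{dM_X}{dt} = k_{PX} M_P - r_{1,X} M_X$$

for $X \in \{L, B, A\}$ (lactate via LDH, bicarbonate via PDH,
alanine via ALT). The $r_1$ rates are *apparent* longitudinal decay
constants lumping T1 with polarization loss; magnetization never
recovers. Bidirectional (Bloch–McConnell) exchange, B0/B1 maps and
arterial dispersion are deliberately out of scope.

Defaults (chosen once as typical in-vivo scale values for brain
hyperpolarized pyruvate studies and not revisited): brain
$k_{PL} = 0.02\,\mathrm{s^{-1}}$, $k_{PB} = 0.010\,\mathrm{s^{-1}}$,
$k_{PA} = 0.002\,\mathrm{s^{-1}}$; muscle has higher $k_{PA}$
(0.012 s$^{-1}$) and lower perfusion (0.7); the vascular pool converts
nothing and is perfusion-dominated (scale 3); all apparent $r_1$ are
0.04 s$^{-1}$ (effective T1 about 25 s). The lesion halves $k_{PB}$ —
a focal oxidative (PDH) deficit — leaving glycolytic conversion
untouched. The bolus is a gamma-variate with shape 3 and scale 4 s
(peak at 12 s, essentially complete by ~25 s, matching a slow hand
injection), and the acquisition starts 30 s after bolus start.

## Phantom

The 16 x 16 label map holds an elliptical brain split into mirrored
hemispheres, a muscle/scalp annulus (the dominant alanine source), a
small vascular pool and, for injured subjects, a disc-shaped lesion in
the ipsilateral hemisphere. Voxel centers put $x = 0$ on the DFT
center voxel (0-based index $N/2$), the same convention the k-space
grid uses. This matters: it makes an uninjured phantom *exactly*
mirror-symmetric through the whole Fourier chain, so hemispheric
null tests are clean. The midline voxel column belongs to neither
hemisphere.

## Acquisition

The sequence emulated is a 2D FIDCSI: 60 mm FOV, 16 x 16 encodes, 256
spectral points at 5 kHz, 8 mm slice, 16 s total. Encodes are ordered
concentrically (increasing $\|k\|$, ties by angle then $k_y$) on the
half-open lattice $[-N/2, N/2)$ with circular reduction
$\|k\| \le N/2$ (195 encodes at $N = 16$). Each encode $j$ is excited
at its scheduled time with flip $\theta_j$; the remaining longitudinal
pool has been depleted by $\prod_{i<j}\cos\theta_i$, and the default
schedule $\theta_i = \arctan(1/\sqrt{N_{enc} - i})$ keeps the
transverse signal constant across encodes for a non-recovering
magnetization. The voxel FID is

$$s(t) = \sum_m A_m \sin\theta_j\,
 e^{(i 2\pi \Delta f_m - 1/T_{2,m}^*)t},$$

spatially encoded by the centered DFT at the encode's lattice point.
The first `n_missing = 4` points (0.8 ms at the 0.2 ms dwell) are
discarded, modelling the excitation–acquisition delay; the raw
container stores the truncated FID plus `n_missing` as metadata.
Independent circular complex Gaussian noise is added per stored
sample; SNR is quoted as the peak modulus of the noiseless k-space
center FID over the per-sample noise SD.

Chemical shifts (configurable): Pyr 171.0, Lac 183.2, Ala 176.5,
Bic 161.1, pyruvate-hydrate 179.5 ppm, carrier on Pyr, converted to Hz
with $f_0 = 32.13$ MHz at 3 T. $T_2^*$ defaults to 20 ms (≈16 Hz
Lorentzian linewidth) for all species. Pyruvate-hydrate is off by
default and, when enabled, is simulated as a fixed 8% shadow of the
local pyruvate pool — an optional confounder, not a kinetic pool.

# Reconstruction

The chain applies, in a fixed order: spatial Hanning apodization
(separable per-axis weights $w(k) = (1+\cos(\pi k/k_{max}))/2$, 1 at
the center and 0 at the sampled radius), spatial zero-filling by 2
(16 x 16 to 32 x 32), per-encode backward linear prediction of the 4
missing points, Voigt apodization, spectral zero-filling by 8
(256 to 2048 points), then the centered unitary inverse spatial FFT
and the forward spectral FFT (fftshifted, frequency increasing left to
right). In the implementation the spatial FFT runs at native spectral
length before the spectral zero-fill/FFT; both transforms are linear
and voxel/bin-separable, so this commutes exactly with the stated
order and only saves memory traffic.

Numerical choices worth stating:

* **Backward LP** (order 8, basis 64 early samples): each observed
  sample is regressed on the 8 samples that follow it and the
  recursion is iterated backward. When the normal equations are
  ill-conditioned — guaranteed for noiseless synthetic FIDs, whose
  pole count is below the model order — the solver falls back to the
  minimal-norm least-squares solution via truncated SVD, which is
  exact for consistent systems; the reconstruction summarises these
  fallbacks in a single warning. Observed samples are never modified.
* **Voigt convention**: the envelope is
  $\exp(-\pi L t)\exp(-(\pi G t)^2/(4\ln 2))$, so each component
  alone adds exactly its FWHM to the line. The in vivo setting is
  $G = 25$ Hz, $L = -5$ Hz: the negative Lorentzian term amplifies
  the late FID (resolution enhancement), narrowing a 20 Hz line to
  15 Hz.
* **Spectral FFT**: the first (LP-restored) FID point is halved
  before the transform, the standard correction that keeps the
  absorption-mode baseline flat.
* **Phasing**: per-voxel zero-order on the pyruvate peak — the phase
  of the complex 44 Hz window integral is removed, which maximizes
  the real integral. Voxels whose reference signal is below
  `snr_floor` (default 5) times the spectral noise inherit the phase
  of the nearest above-floor voxel, so noise never drives the phase
  map. First-order phasing is not applied; with a 0.8 ms delay fully
  restored by LP, residual first-order phase is negligible in this
  model.

# Quantification

Metabolite maps integrate the real (absorption-mode) spectrum over a
44 Hz window at each peak, with all centers referenced globally from
the pyruvate peak of the highest-SNR voxel — per-voxel peak searches
would fail on low-SNR bicarbonate. Window centers are separated by at
least 96 Hz at the default shifts, so windows never overlap. Ratio
maps (Lac/Pyr, Bic/Pyr, Bic/Lac, Ala/Pyr) are masked to the brain and
voxels whose denominator falls below a floor (default 3 x the map
noise SD) are *undefined*, never zero.

ROI quantification averages the complex spectra over mirrored
hemispheric ROIs and a muscle ROI (re-rasterized from the phantom
geometry at the reconstruction resolution), then fits each peak with
a Gaussian plus constant baseline by Levenberg–Marquardt, initialized
from the window maximum and second moment. Fitted area is
$A\sigma\sqrt{2\pi}$; fits with amplitude under 3 x the spectral noise
SD are rejected and propagate as missing values. Both estimators of
the same quantity — window integrals and fitted areas — are exposed,
and agree within 15% for isolated peaks; fits are the default for ROI
ratios. Muscle alanine serves as the internal reference
(`X/Ala_muscle`), cancelling receive gain and polarization
differences.

# Statistics

Hemisphere comparisons use two-sided paired t-tests; zero-variance
paired differences report p = 1 with a warning rather than a spurious
rejection. Group comparisons of naive vs injured are gated: Shapiro–
Wilk per group and Brown–Forsythe (ANOVA on absolute deviations from
group medians) across groups, both at alpha = 0.05; if both pass, a
one-way ANOVA runs, otherwise Kruskal–Wallis with Dunn's tie-corrected
post-hoc comparisons (which reduce to the rank-sum comparison for two
groups). No multiple-comparison correction is applied, matching the
exploratory analysis protocol. The hemispheric effect metric is the
relative difference $(\mathrm{ipsi} - \mathrm{contra})/\mathrm{contra}$;
the per-subject convention (compute per subject, then average) is
primary, and the means-ratio variant is also reported because the two
differ whenever contralateral values vary across subjects.

# What the synthetic data do and do not show

The generator reproduces the acquisition geometry, hyperpolarized
depletion, compartmental contrast, truncation and thermal noise. It
does not model B0/B1 inhomogeneity, chemical-shift displacement,
coil sensitivity profiles, respiratory motion, bidirectional
exchange or partial-volume anatomy beyond the six-compartment map.
Passing tests therefore demonstrate that the *processing chain* is
correct and statistically calibrated under realistic contrast and
noise — not that in vivo effect sizes are reproduced.

Problem sizes used in the validation suite were chosen to exercise
the full default geometry (16 x 16 x 256 raw, 32 x 32 x 2048
reconstructed): parameter-recovery runs use 20 cohorts of 5 injured
subjects plus 20 uninjured subjects at SNR 30, and the statistical
calibrations use 10^4 simulated repetitions at n = 5 per group. The
cohort ground truth is defined as the noiseless forward model run
through the same quantification — the appropriate reference for a
recovery test, since it isolates the effect of noise from the
(deliberate, shared) partial-volume dilution of the 4-6-voxel lesion
in a hemisphere ROI.

# Worked example

```{r, eval = FALSE}
library(hpcsi)

res <- simulate_subject(injured = TRUE, snr = 30, seed = 1)
rt <- roi_ratio_table(res$quant)
rt[, c("roi", "lac_pyr", "bic_pyr", "bic_lac", "ala_pyr")]

relative_difference(rt$bic_pyr[rt$roi == "ipsi"],
                    rt$bic_pyr[rt$roi == "contra"])

maps <- compute_metabolite_maps(res$image)
autoplot(maps)
autoplot(compute_ratio_maps(maps, res$rois$brain))
plot_spectrum(average_roi_spectrum(res$image, res$rois$ipsi))
```

# Known limitations

* The single-time-point acquisition precludes kinetic-model fitting
  ($k_{PL}$, $k_{PB}$ estimation); the kinetic model lives only in
  the generator.
* The per-encode backward LP follows the stated processing order; a
  per-voxel variant (after the spatial FFT) would differ and is not
  implemented.
* The lesion occupies a few voxels of a hemisphere ROI, so
  hemispheric relative differences understate the voxel-level
  deficit — by design, mirroring partial-volume dilution in vivo.
* Containers are serialized as versioned RDS rather than a
  language-neutral binary format; maps are exported as NIfTI and
  tables as CSV/JSON for interoperability.
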