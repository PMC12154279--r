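# hpcsi

Simulation, reconstruction, quantification and statistics for 2D
phase-encoded **hyperpolarized [1-¹³C]pyruvate FIDCSI** of the injured
brain.

Hyperpolarized pyruvate imaging reads out tissue energy metabolism in
vivo: injected [1-¹³C]pyruvate is converted to lactate (Lac, via LDH,
glycolytic flux), ¹³C-bicarbonate (Bic, via pyruvate dehydrogenase,
oxidative flux) and alanine (Ala, via ALT). In traumatic brain injury
the oxidative branch is suppressed, so the **Bic/Pyr** ratio drops on
the injured side; the hemispheric effect metric is the relative
difference (ipsi − contra)/contra. Because the magnetization is
non-recoverable and decays within a minute, acquisitions are
single-shot-per-encode and low-SNR, and the processing chain —
k-space apodization, backward linear prediction of the truncated FID,
Voigt resolution enhancement, absorption-mode integration and fitting
— does real statistical work. `hpcsi` implements that chain end to
end, driven by a synthetic-data generator that emulates the ferret
acquisition (16 × 16 concentric phase encodes over a 60 mm FOV, 256
points at 5 kHz, variable flip angles, 16 s), so every stage is
testable without animal data.

## The model

Per tissue compartment, unidirectional precursor–product exchange:

    dM_P/dt = u(t) − (r1_P + k_PL + k_PB + k_PA) · M_P
    dM_X/dt = k_PX · M_P − r1_X · M_X        X ∈ {L, B, A}

with a gamma-variate bolus u(t) and apparent decay rates r1 lumping
T1 with polarization loss. The injured phantom halves k_PB in a focal
lesion. Reconstruction: spatial Hanning window → spatial zero-fill ×2
(16×16 → 32×32) → backward linear prediction of the FID points lost
to the excitation–acquisition delay → Voigt apodization (25 Hz
Gaussian, −5 Hz Lorentzian) → spectral zero-fill ×8 → centered FFTs →
per-voxel zero-order phasing. Quantification: 44 Hz absorption-mode
window integrals (maps) and Gaussian peak fits on ROI-averaged
spectra (ratios). Statistics: paired hemisphere t-tests and
Shapiro–Wilk/Brown–Forsythe-gated one-way ANOVA vs Kruskal–Wallis
with Dunn's post-hoc.

## Worked example

```r
library(hpcsi)

res <- simulate_subject(injured = TRUE, snr = 30, seed = 1)
rt <- roi_ratio_table(res$quant)
rt[, c("roi", "lac_pyr", "bic_pyr", "bic_lac", "ala_pyr")]
#> # A tibble: 2 × 5
#>   roi    lac_pyr bic_pyr bic_lac ala_pyr
#>   <chr>    <dbl>   <dbl>   <dbl>   <dbl>
#> 1 ipsi     0.286   0.109   0.383  0.0471
#> 2 contra   0.313   0.150   0.480  0.0682

relative_difference(rt$bic_pyr[rt$roi == "ipsi"],
                    rt$bic_pyr[rt$roi == "contra"])
#> [1] -0.2714425
```

One synthetic injured subject at SNR 30: the lesion (pyruvate
dehydrogenase conversion halved in a ~6-voxel disc) depresses the
ipsilateral hemisphere's Bic/Pyr relative to the mirror ROI (−27% in
this noise draw; the noiseless value is −15%, the 50% voxel-level
deficit diluted by the hemisphere ROI, as in real partial-volume
conditions). `autoplot(compute_metabolite_maps(res$image))`
shows the per-metabolite maps; `plot_spectrum(average_roi_spectrum(res$image,
res$rois$ipsi))` the ROI spectrum.

A full cohort (4 naive + 5 injured, distinct seeds) with per-subject
outputs, group statistics and a checksummed run manifest:

```r
run_pipeline(default_pipeline_config(n_naive = 4, n_injury = 5, seed = 1),
             out_dir = "run1")
```

A thin CLI over the same functions is installed at
`system.file("cli/hpcsi.R", package = "hpcsi")`
(`hpcsi.R run|simulate|recon|quantify|stats`).

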