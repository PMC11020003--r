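# drspec

Tissue classification from diffuse reflectance spectroscopy (DRS), end to
end: spectral calibration and preprocessing, shape-based feature
extraction, Boruta feature selection, a five-layer 1D convolutional
network (SpecNet) plus classical baselines under patient-wise stratified
cross-validation, optical probe-tip tracking in video, and a graduated
green-to-pink probability overlay. A synthetic-data module emulates
450–1000 nm colorectal-tissue reflectance spectra and marker-on-tissue
video with known ground truth, so every stage is testable without
clinical data.

## Who this is for

Researchers building or evaluating optical tissue-classification
pipelines — e.g. intraoperative tumour-margin assessment — who need a
tested, reproducible reference implementation of the standard processing
chain and a controllable data generator to probe it with.

## The core methods

**Calibration and preprocessing.** Raw counts are calibrated against
white/dark references, R(λ) = (I−D)/(W−D), resampled to a fixed grid of
1922 equally spaced points over 450–1000 nm, filtered by a median ±
1.5 × MAD rule on per-spectrum mean reflectance (unscaled MAD, strict
inequality, applied within each acquisition group), then
standard-normal-variate normalised: each spectrum to mean 0, sample
sd 1.

**Features.** Per spectrum: intensity and wavelength of the primary and
secondary peaks, mean intensities over 480–550, 580–700 and 450–720 nm,
and the haemoglobin saturation coefficient s = c_HbO₂/(c_HbO₂+c_Hb)
obtained by non-negative least-squares unmixing of −log R over
500–600 nm against oxy/deoxy-haemoglobin extinction curves with a
constant+slope scattering nuisance term.

**SpecNet.** Input (n₁ = 1922 bands) → convolution C1 with 20 kernels of
length k₁ (n₂ = n₁−k₁+1) → max-pool M2 of kernel k₂ (n₃ = ⌊n₂/k₂⌋) →
fully connected F3 (n₄) → softmax output (n₅ = 2). Trainable parameters:
20(k₁+1), (20n₃+1)n₄, (n₄+1)n₅ — with defaults k₁=11, k₂=2, n₄=64 that
is 240, 1,223,744 and 130. Forward pass, backpropagation and Adam are
implemented in the package; training is deterministic given a seed.

**Validation.** Folds are assigned at the *patient* level (greedy
class-balanced packing), so no patient's spectra ever appear on both
sides of a split. Metrics: accuracy, tumour-recall sensitivity,
normal-recall specificity, and trapezoidal-ROC AUC (equal to pairwise
concordance), with fold-mean 95% t-intervals.

**Tracking and overlay.** The green probe marker is segmented by HSV
thresholding + connected components, tracked by a constant-velocity
Kalman filter that coasts through occlusions, and classification sites
are painted with a graduated colourmap from green (0,255,0) at p = 0 to
pink (255,105,180) at p = 1.

## Worked example

```r
library(drspec)

spec <- synthetic_dataset_spec(n_patients = 8, spectra_per_class_per_patient = 25, seed = 42)
raw  <- generate_dataset(spec)           # raw counts + white/dark references
raw
#> <drs_set> 400 spectra x 2048 wavelengths (448.0-1002.0 nm)
#>   labels: normal=200 tumour=200 | patients: 8

proc <- preprocess_set(raw)              # calibrate, resample, MAD-filter, SNV
proc
#> <drs_set> 275 spectra x 1922 wavelengths (450.0-1000.0 nm), SNV
#>   labels: normal=137 tumour=138 | patients: 8
```

Each processed spectrum has exactly 1922 points on 450–1000 nm; the MAD
rule removed 125 of 400 spectra (it trims any residual beyond 1.5
unscaled MADs — an aggressive filter by construction).

```r
feats <- extract_features(proc)
dplyr::select(feats, label, peak1_wavelength, band_mean_580_700, hb_saturation)[1:4, ]
#>   label  peak1_wavelength band_mean_580_700 hb_saturation
#> 1 normal             618.              1.05         0.856
#> 2 normal             611.              1.05         0.853
#> 3 normal             615.              1.05         0.838
#> 4 normal             612.              1.05         0.841
```

The estimated saturations sit near the generator's normal-tissue value
(0.85), recovered by unmixing alone.

```r
fm <- as.matrix(feats[, 3:10]); fm[is.na(fm)] <- 0.5
cv <- cross_validate(cbind(fm, proc$intensities), proc$meta, kind = "rf", k = 4, seed = 1)
tidy(cv)
#>   metric       mean ci_lo ci_hi
#> 1 accuracy        1     1     1
#> 2 sensitivity     1     1     1
#> 3 specificity     1     1     1
#> 4 auc             1     1     1
```

On noise-level default synthetic data the classes are fully separable
under patient-wise CV; permuting labels drops AUC to ≈ 0.5 (see the test
suite). Finally, probabilities map to overlay colours:

```r
probability_to_color(c(0, 0.5, 1))
#>        r   g   b
#> [1,]   0 255   0     # certain normal: green
#> [2,] 128 180  90     # undecided: midpoint
#> [3,] 255 105 180     # certain tumour: pink
```

A complete demo — simulate, preprocess, classify, track a synthetic
marker video, render overlays — runs with
`run_pipeline(demo_config(seed = 7))`, or from a shell via the thin CLI
at `inst/cli/drspec` (`drspec run --seed 7 --out outdir/`).

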