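---
title: "Methods: spectral preprocessing, classification and probe tracking in drspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral preprocessing, classification and probe tracking in drspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(drspec)
```

## The problem

Diffuse reflectance spectroscopy (DRS) probes tissue with broadband light
and records the diffusely reflected spectrum. In the visible and
near-infrared range the spectral shape is dominated by two physical
processes: absorption by haemoglobin (whose oxy and deoxy forms have
distinct extinction spectra between roughly 500 and 600 nm) and elastic
scattering by tissue microstructure (a smooth, monotonically decaying
background). Tumour tissue tends to carry more blood at lower oxygen
saturation than surrounding normal tissue, so a classifier over DRS
spectra can discriminate the two — the basis for intraoperative margin
assessment. `drspec` implements the full chain from raw detector counts
to a per-site tumour probability painted on video of the surgical field,
and ships a synthetic-data module so the whole chain can be exercised and
tested without access to clinical data.

## The generative model behind the synthetic data

`generate_spectrum()` draws from a Beer–Lambert-style approximation:

$$R(\lambda) = A\left(\frac{\lambda}{500}\right)^{-b}
  \exp\!\big\{-\,\mathrm{BVF}\cdot L\,[\,s\,\epsilon_{HbO_2}(\lambda) +
  (1-s)\,\epsilon_{Hb}(\lambda)]\big\} + \varepsilon,\qquad
  \varepsilon \sim \mathcal N(0,\sigma^2)$$

with scattering amplitude $A$, scattering power $b$, blood volume
fraction BVF, path length $L$ (mm), haemoglobin saturation $s$, and
per-wavelength additive Gaussian noise. This is not photon-transport
simulation: there is no wavelength-dependent sampling depth, no specular
glare, no probe-pressure effects. Passing tests on this generator
demonstrates that the pipeline's operations are correct, not that the
defaults match any particular instrument.

The bundled haemoglobin extinction curves
(`hb_extinction_synthetic()`) are a smooth closed-form *synthetic*
approximation — Gaussian bands on an exponentially decaying base — that
reproduces the canonical qualitative features (the HbO$_2$ 542/577 nm
doublet, the single broad Hb 555 nm peak, the Hb 760 nm band, an
isosbestic-like crossing near 800 nm). Digitised laboratory tables would
be preferable; since the same curves drive both the generator and the
saturation estimator, parameter-recovery tests are self-consistent by
construction, and that is all they claim.

Default class parameters (tumour: BVF 0.04, saturation 0.60; normal: BVF
0.015, saturation 0.85, with slightly stronger tumour scattering) were
chosen once to make the classes clearly separable in the mean but
overlapping spectrum-by-spectrum under the default noise
($\sigma = 0.01$ reflectance units). Per-patient multiplicative
log-normal jitter (sdlog 0.2) on BVF and scattering amplitude makes
spectra cluster by patient, which is what gives patient-wise
cross-validation something real to protect against. A cohort defaults to
200 spectra per tissue class per patient, a typical acquisition session
size.

## Calibration, resampling, SNV

Raw counts are calibrated against a white reflectance standard and a dark
field, $R = (I - D)/(W - D)$, per wavelength. Values outside $[0,1]$
produced by noise are deliberately kept: SNV later removes scale and
offset, and clipping would bias shape features.

Calibrated spectra are linearly interpolated onto the fixed analysis grid
of **1922 equally spaced points over 450–1000 nm** (spacing
$550/1921 \approx 0.286$ nm, endpoints inclusive, no extrapolation, no
pre-smoothing). Standard normal variate (SNV) normalisation then centres
each spectrum to mean zero and unit *sample* standard deviation (divisor
$n-1$); constant spectra are a degenerate-input error.

## Outlier rejection: the MAD rule, taken literally

Each spectrum is summarised by one residual — its mean calibrated
reflectance — and flagged when it lies strictly more than `mad_factor`
(default 1.5) times the **unscaled** median absolute deviation from the
median of the residuals. The 25th/75th percentiles are computed and
reported but play no part in the rule. Two consequences of taking the
rule literally are worth knowing:

* For any continuous residual distribution the rule trims aggressively —
  for Gaussian residuals roughly 31% of spectra sit beyond
  1.5 × MAD (unscaled MAD of a Gaussian is $0.674\sigma$). This is the
  rule's behaviour, not a bug, but users wanting a gentler filter should
  raise `mad_factor`.
* The rule is not idempotent on continuous data: re-running it on the
  survivors rescales to the trimmed spread and flags again. It is
  idempotent only when the surviving residuals are tightly clustered
  (MAD 0), which is how the property is tested.

`preprocess_set()` applies the rule **within each (patient, label)
acquisition group** rather than across the pooled set. The artefacts the
rule targets — air gaps, probe lift-off, detector saturation — corrupt
individual acquisitions within a session; pooled application would
instead flag legitimate inter-patient variability, removing whole
patients. `group_by = NULL` restores pooled behaviour. The pipeline
order is calibrate → resample → outlier-reject → SNV, so outliers are
judged on physical reflectance before SNV erases scale.

## Shape features and haemoglobin saturation

Nine features per spectrum: intensity and wavelength of the two dominant
peaks, mean intensities over 480–550, 580–700 and 450–720 nm, and the
haemoglobin saturation coefficient. Peak detection runs on a 15-point
(~4.3 nm) moving average to suppress per-point noise — reported
intensities are read from the unsmoothed spectrum — and the secondary
peak must lie at least 20 nm from the primary so one haemoglobin lobe is
not counted twice. Both window sizes are arguments. A spectrum with no
local maximum falls back to its global maximum and is flagged
`peak_degenerate`.

Saturation is estimated by linear unmixing rather than photon-transport
lookup: $-\log R$ over 500–600 nm is decomposed by non-negative least
squares into HbO$_2$ and Hb extinction contributions plus an
unconstrained constant + slope nuisance term standing in for the smooth
scattering background (the nuisance coefficients are split into signed
parts so only pigment loadings are sign-constrained); saturation is
$c_{HbO_2}/(c_{HbO_2}+c_{Hb})$, undefined below a total-pigment floor of
$10^{-3}$. Noise-free recovery error across generating saturations
0.1–0.9 is below 0.01 in the test suite. Because SNV values can be
negative, the unmixing consumes the calibrated reflectance that
`snv_normalize()` carries alongside the normalised values; an SNV set
without that companion yields `NA` with `hb_sat_undefined`.

## Boruta

`boruta_select()` implements the all-relevant selection loop from
scratch: per iteration, every feature gets an independently permuted
shadow copy, a random forest is fitted on the doubled matrix, and a
feature scores a hit when its importance exceeds the best shadow
importance. A two-sided exact binomial test against $p = 0.5$
(Bonferroni-adjusted across features by default) turns hit counts into
confirmed / rejected / tentative decisions; zero iterations leave
everything tentative.

The importance measure is ranger's **scaled out-of-bag permutation
importance**, not in-sample impurity gain. This was a deliberate design
choice after measurement: deep forests overfit chance-correlated noise
features in-sample, so impurity gain ranks them consistently above
shadows and the procedure confirms them far more often than its nominal
error rate; OOB permutation importance measures generalisation and keeps
the null calibrated. Note that a finite sample from a null process can
still contain genuinely associated features (a chance correlation of
0.14 at $n = 500$ is a $p \approx 0.002$ association *in that sample*);
occasional confirmations on null data are correct behaviour of an
all-relevant method, not false positives in the sample's terms.

## SpecNet and the baselines

SpecNet is a five-layer 1D CNN over the 1922-band spectrum: input →
convolution C1 with 20 kernels of length $k_1$ (valid, stride 1,
$n_2 = n_1 - k_1 + 1$) → max-pool M2 of kernel $k_2$
($n_3 = \lfloor n_2/k_2\rfloor$; the floor covers non-divisible $k_2$) →
fully connected F3 of width $n_4$ → softmax output of $n_5 = 2$ nodes.
Trainable parameters per block are $20(k_1+1)$, $(20 n_3 + 1)n_4$ and
$(n_4+1)n_5$; `build_specnet()` reports them and
`specnet_parameter_counts()` confirms the instantiated network holds
exactly those counts. Defaults $k_1 = 11$, $k_2 = 2$, $n_4 = 64$ give
240, 1,223,744 and 130 parameters.

Forward, backward and the Adam optimiser are implemented directly in R
with matrix algebra (im2col convolution, argmax-routed pooling
gradients); ReLU activations, cross-entropy loss, learning rate $10^{-3}$,
batch 32, up to 100 epochs with early stopping on a 10% validation split
(patience 10) — all overridable through `specnet_config()` and all
deterministic given the config seed. Baselines dispatch to established
libraries: ranger (rf), xgboost (xgb), e1071 linear SVM, nnet MLP. No
LightGBM backend exists for R here, so `kind = "lgbm"` raises an
informative error. Following the input-representation question left open
by the method description, the baselines consume the nine shape features
(optionally plus the 1922 intensities, optionally Boruta-filtered), while
SpecNet consumes the raw 1922-point sequence only.

## Patient-wise stratified cross-validation and metrics

`make_patient_folds()` assigns each *patient* to exactly one of $k = 5$
folds: patients are shuffled (seeded), sorted by descending spectrum
count, and greedily placed in the fold minimising the per-class count
spread (total count as tie-break). Exact patient-level stratification is
a bin-packing problem, so stratification is approximate; the
within-±10%-of-global check in the tests is a property of the produced
assignment, verified exhaustively. `cross_validate()` asserts at run
time that train and test patient sets are disjoint in every fold.

Metrics treat `tumour` as the positive class at threshold 0.5:
sensitivity is tumour recall, specificity normal recall, accuracy the
proportion of correctly identified spectra. AUC is trapezoidal ROC
integration with tied scores merged into single threshold steps, which
makes it exactly the pairwise concordance probability with ties counted
½ (tested against brute-force enumeration, and against pROC as an
independent implementation). The cross-validation summary reports
fold-mean ± $t_{0.975,k-1}$ standard-error intervals; with $k = 5$ folds
these intervals are wide and can exceed $[0,1]$ — they are reported
unclipped.

## Marker tracking

Segmentation converts each frame to HSV and thresholds hue 100–140° (of
360), saturation ≥ 0.4, value ≥ 0.3; connected components are labelled
(EBImage) and the largest component of at least 50 px² yields the
centroid. Hue wraparound (`hue_min > hue_max`) is supported by
dual-interval masking.

Tracking is a standard constant-velocity Kalman filter on state
$(x, y, v_x, v_y)$ with discretised white-acceleration process noise
($q = 1$ px²/frame²) and isotropic measurement noise ($r = 2$ px²),
updated in Joseph form so the covariance stays symmetric
positive-definite. The track initialises on the first valid detection
with zero velocity and large uncertainty, coasts through missed
detections, is dropped after 15 consecutive misses and re-initialises on
the next detection. All settings are exposed; none are claimed to match
any particular camera.

## Overlay

`probability_to_color()` maps tumour probability linearly per channel
from green (0, 255, 0) at 0 to pink (255, 105, 180) at 1 (the pink RGB is
a package choice), rounding half up. `render_overlay()` alpha-blends
filled disks (default α = 0.6) in draw order onto a copy of the frame.
Rendering is offline on stored frames: the original live interface is
hardware-bound, but the colourmap semantics are preserved. When several
spectra map to one site the pipeline uses their mean probability — the
method description does not specify this step, so it is a config-level
choice.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use cohorts of 20
patients × 2 classes × 50 spectra for cross-validation checks, a
200-spectrum two-patient set for SpecNet training checks, 1000-trial
randomised oracle comparisons for the MAD rule and AUC, and 50-frame
videos with 10% occlusion for tracking — sizes chosen so each property
is measured with comfortable margin on a single CPU. Tolerances: SNV
mean/sd to $10^{-9}$; AUC against enumeration to $10^{-12}$; Kalman
constant-velocity exactness to $10^{-6}$ px with $q, r = 10^{-12}$;
saturation recovery to 0.05. Ties in the greedy fold packer break toward
the lower fold index after a seeded shuffle; ties in peak detection
resolve to the first grid index; tied AUC scores are merged, never
order-dependent.

## Known limitations

* The synthetic generator is a smooth two-chromophore model; it contains
  no water/lipid absorption, no specular glare, no wavelength-dependent
  sampling volume. Results on it bound nothing about clinical data.
* The extinction curves are synthetic approximations, adequate because
  generator and estimator share them; absolute saturation values against
  real tissue would require measured tables.
* The MAD rule as specified trims ~31% of clean Gaussian data; this is
  faithful to its definition but aggressive.
* `lgbm` is unavailable as a backend; `xgb` covers gradient boosting.
* SVM probability outputs (libsvm's internal Platt scaling) are
  deterministic within a session but are not covered by the cross-call
  determinism contract the other kinds satisfy.
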