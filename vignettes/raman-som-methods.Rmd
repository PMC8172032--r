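---
title: "Classifying mucosal healing from Raman spectra with class-augmented self-organising maps"
author: "RamanSOM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mucosal healing from Raman spectra with class-augmented self-organising maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanSOM)
```

## The problem

Assessing mucosal healing (MH) in inflammatory bowel disease currently
requires endoscopic scoring plus histology. Raman spectroscopy of biopsy
tissue offers a label-free biochemical readout: each spectrum records
inelastic light scattering as intensity over Raman shift (cm^-1), and band
intensities track molecular constituents — 1003 cm^-1 (phenylalanine,
elevated with inflammatory infiltrate), 1252 cm^-1 (amide III / haem),
1304 cm^-1 (phospholipids, elevated in healed mucosa), 1449 cm^-1 (CH
deformation), 1657 cm^-1 (C=C lipid stretch). In the study design this
package reproduces, each patient contributes a 10×10 map scan (100
single-point spectra, 550–1670 cm^-1) with a patient-level class label (MH
vs active inflammation, or pre- vs post-biologic vs healthy control), and a
supervised self-organising map — the SKiNET approach — classifies held-out
spectra and attributes the separation to individual Raman bands through the
SOM discriminant index (SOMDI).

`RamanSOM` implements the full chain: spectral preprocessing, a hexagonal
class-augmented Kohonen map, SOMDI extraction, a repeated
stratified-cross-validated evaluation protocol, and a synthetic spectrum
generator that emulates the study's data structure so that every stage can
be verified against planted ground truth without any external download.

## Data model

A `RamanSpectra` object extends `SummarizedExperiment`: rows are spectral
channels (`rowData(x)$wavenumber`), columns are individual spectra, and
`colData` holds `patient_id`, `class_label` and `spectrum_index`. The
default shared axis is 550–1670 cm^-1 at 1 cm^-1 spacing (1121 channels);
the instrument's true pixel spacing is not dictated by the acquisition
range, so the axis is configurable and external files are linearly
interpolated onto it by `assembleCollection()` (spectra are densely sampled
relative to ~8 cm^-1 band half-widths, so linear interpolation is
innocuous).

## Preprocessing

`runPreprocess()` applies, in fixed order: despiking, baseline subtraction,
cropping to the closed interval [550, 1670], and normalisation. The order
matters: cosmic-ray spikes would corrupt a baseline fit, and a scale
convention is only meaningful after the fluorescence background is gone.

**Despiking.** Cosmic-ray hits are single-channel impulses. A channel is
flagged when the modified z-scores of the two first differences flanking it
both exceed `despikeZThreshold` (default 8) *and* have opposite signs — the
impulse signature; smooth band edges produce runs of same-sign differences
and are never flagged. The z-score scale is the MAD of the difference
series with two guards: a mean-absolute-deviation fallback when the MAD is
exactly zero, and a floor of 1% of the spectrum's intensity range. The
floor gives the detector an explicit detectability limit (impulses below
roughly 12% of the intensity range are not searched for — far below any
real cosmic ray) and keeps noiseless spectra, where every robust scale
estimator collapses, from flagging their own band apexes. Flagged channels
are replaced by the median of unflagged neighbours within `despikeWindow`
(default 7) channels, and the per-spectrum audit log lists every corrected
channel, so the filter is idempotent and auditable.

**Baseline.** Asymmetric least squares (Eilers): the baseline minimises an
asymmetrically weighted least-squares criterion with a second-difference
penalty, weight `baselineLambda = 1e5` and asymmetry `baselineP = 0.01`
over 10 reweighting iterations — the standard Raman chemometrics choice,
implemented with an O(n) pentadiagonal Cholesky solve. Points above the
running baseline (the bands) receive weight `p`, points below `1 - p`, so
the fit hugs the fluorescence background. Corrected spectra may contain
small negative values; Lorentzian tails are partially absorbed into the
baseline, which biases recovered peak heights by a few percent but cancels
in between-class ratios at a band.

**Normalisation.** `vector_l2` (unit Euclidean norm, the default),
`area` (unit trapezoidal integral), or `none`. Whether the original
analysis normalised at all is not recoverable; l2 is the common chemometric
convention and removes per-spectrum intensity scale, which is exactly right
for classification. It is *not* right for recovering amplitudes planted on
a common intensity scale: dividing each class by its own overall norm
(norm ratio ≈ 1.07 for the two UC class templates) algebraically cancels
a planted between-class difference at any band whose class amplitude
ratio is close to that norm ratio — which is the case at 1449 and
1657 cm^-1 in the published UC band table. The package therefore uses the
l2 pipeline for classification experiments and the un-normalised pipeline
for band-recovery experiments, and both modes are exposed.

## The class-augmented SOM

Neurons live on a `rows × cols` hexagonal lattice (default 10×10, in axial
coordinates with the standard hex distance). Each neuron carries a spectral
weight vector and a class weight vector. Training (`trainSOM()`) is online
Kohonen learning: each epoch visits all training spectra in a freshly
shuffled seeded order; for each spectrum the best-matching unit (BMU) is
the Euclidean-nearest neuron *on spectral channels only*, and every
neuron's weights move toward the sample — spectral weights toward the
spectrum, class weights toward the one-hot label — scaled by a learning
rate decaying exponentially from 0.5 to 0.01 over the total step count and
a Gaussian hex-lattice neighbourhood whose radius decays exponentially from
`max(rows, cols)/2` to 1. Excluding class channels from the BMU distance
makes the labels steer the map without letting them short-circuit the
spectral similarity structure; `classWeightScale` (default 1) controls the
label channels' update magnitude. Classification assigns a test spectrum
its BMU's class-weight vector normalised to sum one; ties break to the
first class in sorted order, and all tie-breaks in the package are
lowest-index, for determinism.

Weights are initialised uniformly from the per-channel training-data range;
per-epoch mean quantisation error (distance to BMU at presentation) is
logged. The hot loop runs in single precision with partial-distance
elimination in the BMU search and a 1e-4 cut-off on negligible
neighbourhood factors; none of this changes results beyond floating-point
resolution of the individual update, but note that online SOM training is
trajectory-sensitive: a perturbation that flips one near-tie BMU decision
(for example rescaling all intensities by a non-power-of-two constant)
can reorganise the map layout while leaving its statistical content
intact.

## SOMDI

For class `c`, `computeSOMDI()` returns the mask-weighted *mean* of the
neuron spectral weights, where the mask keeps a neuron's class-`c` weight
only when `c` is that neuron's dominant class. Averaging (rather than
summing) keeps the index independent of how many neurons a class happens
to dominate — a seed-dependent quantity whose variation would otherwise
masquerade as spectral differences. The index is scaled by one *joint*
maximum over all classes (`scaling = "global_max"`), preserving
between-class comparability at every band; per-class unit-max scaling
(`"class_max"`, also available) cancels between-class differences at any
band whose amplitude ratio matches the dominant band's and is only
appropriate for comparing band positions. `topDiscriminatingBands()`
reports the `k` largest local peaks of the absolute between-class SOMDI
difference, greedily selected with a minimum spacing (default 20 cm^-1,
well under the ≥ 50 cm^-1 spacing of reported tissue bands).

## Evaluation protocol

`repeatedEvaluation()` repeats, with run-derived seeds: a stratified 80/20
train/test split, oversampling of training minority classes to the
majority count (sampling with replacement — duplication, not interpolation),
SOM training, classification of the held-out spectra, and confusion-matrix
metrics (sensitivity, specificity, PPV, NPV, accuracy, in percent, with
"active" disease as the positive class by default). Ten runs are reported
as mean and sample standard deviation (n−1). `crossValidate()` provides
the companion stratified 10-fold cross-validation (shuffle each class,
deal round-robin, so per-class fold counts differ by at most one) for
hyper-parameter assessment inside a training pool. Splits default to the
spectrum level, which mirrors pulling a fraction of all spectra at random;
because each patient contributes 100 correlated spectra, spectrum-level
splits let patient identity leak between training and test, so the
patient-level unit (`splitPlan(unit = "patient")`) is provided and
recommended when generalisation to new patients is the question. A metric
whose denominator is zero is reported as `NA` rather than aborting the
run.

## The synthetic generator

`simulateCollection()` draws, for each class and patient, a log-normal
amplitude multiplier (sdlog 0.10 — a plausible inter-patient variability;
the true value is unknowable from published summaries) applied to a class
template of Lorentzian bands (HWHM 8 cm^-1, typical of tissue Raman
bands), plus a fixed quadratic fluorescence-like background, additive
Gaussian channel noise (sd 0.05 against band amplitudes of ~0.7–4), and a
Poisson(0.05)-count of cosmic-ray spikes per spectrum at uniform channels
with uniform height 5–50. The five discriminative bands use the published
per-class relative intensities as template amplitudes
(`defaultUCConfig()`, `defaultCDConfig()`, `defaultThreeClassConfig()`);
ten filler bands at common tissue wavenumbers are identical across classes
so classification cannot succeed on overall intensity alone. Every latent
variable is returned as ground truth and `truthCheck()` scores pipeline
outputs against it.

What the generator does *not* emulate: photon shot noise (noise is
homoscedastic Gaussian), instrument response and wavenumber miscalibration,
fluorescence photobleaching dynamics, within-patient spatial correlation
across the map scan beyond the shared multiplier, and any spectral
structure beyond isolated Voigt-free line shapes. Passing the planted-truth
experiments therefore demonstrates the pipeline's correctness and internal
consistency, not clinical performance on real tissue spectra.

## Experiment sizes and numerical choices

The package's own verification experiments run at the study's cohort
structure — 33 active / 9 MH patients for UC — with 100 spectra per patient
and a 10×10 map trained for 100 epochs in the test suite; the
`scripts/acceptance.R` reproduction script uses 30 spectra per patient for
the spike/amplitude-recovery and classification experiments (and a
25-spectra balanced design for the permutation null) with all other
conditions unchanged, which leaves those conclusions intact while keeping
the script fast. The SOMDI band-coverage experiment keeps the full
100-spectrum map scans: band attribution is read off neuron prototypes,
whose estimation error shrinks with the number of spectra per patient, so
that experiment is meaningful only at its defining scale. "Noiseless" recovery experiments set both the channel
noise and the patient amplitude sd to zero (spikes still planted): with
only nine MH patients, patient-level amplitude sampling alone shifts
class-mean amplitudes by ~3% and would contaminate a 5% recovery bound
with cohort sampling variance that is not pipeline error.

Degenerate inputs are contracts, not surprises: empty collections
round-trip through the on-disk format; a class with too few members for a
split or fold raises a stratification error naming the class; an all-zero
spectrum cannot be normalised and the error names its patient; a neuron
with all-zero class weights classifies as the first class with a uniform
score.

## Known limitations

The SKiNET mechanism here — labels as extra weight channels excluded from
the BMU distance, dominant-class-masked SOMDI — is one concrete,
fully-specified variant of a design whose original implementation details
are not recoverable from published summaries; the masking, scaling and
averaging choices are isolated behind `computeSOMDI()` arguments.
Hyper-parameters of the original analysis (map size, schedules, epochs)
are likewise unpublished; defaults follow standard Kohonen practice and
every one is exposed in `somConfig()`. Published headline metrics for the
real cohorts (e.g. UC accuracy 95.65%) depend on those unknowns and on the
real spectra, so the package's synthetic experiments treat them as design
references, never as expected outputs.
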