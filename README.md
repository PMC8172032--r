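# RamanSOM

Chemometric classification of tissue Raman spectra with class-augmented
self-organising maps (the SKiNET approach), built for the question of
whether spectra from bowel biopsies can separate mucosal healing from
active inflammation in inflammatory bowel disease — and, more generally,
for any labelled collection of single-point Raman spectra.

A Raman spectrum records inelastic light scattering as intensity over
Raman shift (cm⁻¹); band intensities track molecular constituents
(1003 cm⁻¹ phenylalanine, 1252 cm⁻¹ amide III/haem, 1304 cm⁻¹
phospholipids, 1449 cm⁻¹ CH deformation, 1657 cm⁻¹ C=C lipid stretch).
The package implements:

- **Preprocessing** — cosmic-ray despiking (modified z-score impulse
  detector with audit log), asymmetric-least-squares baseline subtraction
  (second-difference penalty λ, asymmetry p), cropping to the 550–1670 cm⁻¹
  fingerprint window, and l2/area normalisation.
- **Class-augmented SOM** — a hexagonal Kohonen lattice whose neurons carry
  spectral weights *w* plus class weights *c*. Online training moves both
  toward each presented sample/one-hot label under a Gaussian lattice
  neighbourhood *h(t) = exp(−d²/2σ(t)²)* with exponentially decaying
  learning rate and radius; class channels are excluded from the
  best-matching-unit distance, which turns the map into a supervised
  classifier: a test spectrum receives its BMU's normalised class weights
  as scores.
- **SOMDI** — the SOM discriminant index: per class, the dominant-class-
  masked weighted mean of neuron spectral weights, scaled to a joint unit
  maximum. It reads like a spectrum whose peaks mark the wavenumbers that
  drive class separation; `topDiscriminatingBands()` turns it into a
  relative-band-intensity table.
- **Evaluation** — stratified 80/20 splits (spectrum- or patient-level),
  minority-class oversampling, stratified 10-fold cross-validation, and a
  10-run repeated protocol reporting sensitivity, specificity, PPV, NPV
  and accuracy as mean ± sd.
- **Synthetic generator** — labelled collections with Lorentzian band
  templates (per-class amplitudes from the published UC/CD band tables),
  fluorescence-like background, log-normal patient amplitude effects,
  Gaussian noise and planted cosmic-ray spikes, with full ground truth for
  closed-loop verification.

Spectra live in a `RamanSpectra` object (a `SummarizedExperiment`:
channels × spectra, with `patient_id` / `class_label` / `spectrum_index`
in `colData`), so all the usual Bioconductor subsetting applies.

## Worked example

Simulate a UC-like cohort (33 active / 9 mucosal-healing patients, 20
spectra per patient, deliberately noisy), run the default pipeline, and
extract the discriminating bands:

```r
library(RamanSOM)

cfg <- defaultUCConfig(spectraPerPatient = 20L, spectrumNoiseSd = 0.4, seed = 1L)
sim <- simulateCollection(cfg)
sim$spectra
#> RamanSpectra: 840 spectra x 1121 channels (550-1670 cm^-1)
#>   classes: UC_active (660), UC_MH (180)
#>   patients: 42

pp <- runPreprocess(sim$spectra)
report <- repeatedEvaluation(pp$spectra, somConfig(seed = 2L),
                             splitPlan(seed = 3L), nRuns = 10L)
report
#> EvaluationReport: 10 runs, positive class 'UC_active'
#>       metric     mean        sd
#>  sensitivity 99.54545  0.638844
#>  specificity 29.44444 10.654185
#>          ppv 83.84179  2.079750
#>          npv 92.75325 12.942029
#>     accuracy 84.52381  2.556369
```

At this noise level (8× the generator default) the minority
mucosal-healing class is hard to specify — exactly the situation the
protocol's oversampling and the patient-level split option exist to probe.
Band attribution runs on the un-normalised pipeline, because the planted
amplitudes share one intensity scale:

```r
ppRaw <- runPreprocess(sim$spectra, preprocessConfig(normalisation = "none"))
model <- trainSOM(ppRaw$spectra, somConfig(seed = 4L))
somdi <- computeSOMDI(model)
topDiscriminatingBands(somdi, "UC_active", "UC_MH", k = 5)
#>   wavenumber   somdi_a   somdi_b      score
#> 1       1002 0.8253800 0.7113254 0.11405460
#> 2       1254 0.3857134 0.3376450 0.04806833
#> 3       1304 0.3794093 0.4334948 0.05408544
#> 4       1451 0.9520640 0.9115000 0.04056398
#> 5       1661 0.3531164 0.3166352 0.03648114
```

All five planted discriminative bands (1003, 1252, 1304, 1449, 1657 cm⁻¹)
surface within a few cm⁻¹, with the active class higher everywhere except
1304 cm⁻¹ — the phospholipid band that rises with healing. `somdi_a` /
`somdi_b` are the two classes' discriminant-index values at each band on
the joint unit-maximum scale; `score` is their absolute difference, the
ranking criterion.

A YAML-driven orchestration layer (`cmdSimulate()`, `cmdRun()`,
`cmdReport()`, with a thin wrapper in `inst/scripts/raman_som.R`) writes
every artefact — metrics, confusion matrices, SOMDI, band table, neuron
map, despiking audit — as plain CSV/JSON, byte-reproducibly for a given
seed.

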