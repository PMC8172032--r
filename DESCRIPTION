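Package: RamanSOM
Title: Self-Organising Map Classification and Discriminant-Index Analysis of
    Raman Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for chemometric analysis of single-point Raman spectra from
    tissue biopsies: spectral preprocessing (cosmic-ray despiking, asymmetric
    least-squares baseline subtraction, cropping, normalisation), supervised
    classification with a hexagonal-lattice self-organising map carrying
    class-augmented weight channels (the SKiNET approach), extraction of the
    self-organising map discriminant index (SOMDI) that attributes class
    separation to individual Raman bands, and a repeated stratified
    cross-validated evaluation protocol with oversampling and confusion-matrix
    metrics. Includes a synthetic Raman-spectrum generator (Lorentzian bands,
    fluorescence-like baseline, patient-level amplitude variability, cosmic-ray
    spikes) so the full pipeline is testable end to end against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
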