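Package: sersmap
Title: Band-RMS Molecular Mapping for Live-Cell SERS Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hyperspectral surface-enhanced Raman
    scattering (SERS) images of living cells on plasmonic nanostar
    substrates. Implements shared-recipe baseline subtraction (asymmetric
    least squares or anchored polynomial), the per-pixel band-RMS
    statistic normalized by a peak-free noise window, grayscale and
    merged RGB compartment composites on a shared display range, peak
    detection with wavenumber-to-biomolecule assignment, AFM
    scratch-thickness estimation from height-histogram peaks, and a
    ground-truthed synthetic phantom generator (cell geometry, component
    spectra, nanostar hotspot gating, optical blur, fluorescence
    baseline, detector noise) so every stage is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
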