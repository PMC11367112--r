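Package: tevcf
Title: Voltage-Clamp Fluorometry and Membrane Biophysics Analysis for
    Kv1.3 Lipid-Modulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-electrode voltage-clamp fluorometry
    (TEVCF) studies of Kv1.3 gating modulation by membrane sphingolipids,
    together with the accompanying membrane-biophysics assays. Processes
    two-channel voltage-step recordings into leak-corrected currents and
    bleach-corrected dF/F traces; fits Goldman-Hodgkin-Katz x Boltzmann
    current-voltage, Boltzmann fluorescence-voltage and single/double
    exponential activation models; computes TMA-DPH fluorescence anisotropy
    and Laurdan generalized polarization from spectrofluorometer
    intensities; quantifies the di-8-ANEPPS excitation ratio from confocal
    image pairs by seeded-watershed membrane segmentation; and summarises
    cohorts with ANOVA and Tukey HSD comparisons. A synthetic-data module
    generates sweep cohorts, probe intensity sets and ring-cell image pairs
    from known ground truth so that every pipeline stage is verifiable by
    closed-loop parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
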