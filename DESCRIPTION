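Package: epistherm
Title: Thermodynamic Prediction of Epistasis in Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting and measuring epistasis between point
    mutations in a bacterial cis-regulatory element where an RNA
    polymerase-like activator and a repressor compete for overlapping
    binding sites. Implements the Boltzmann-weight occupancy model of
    transcription initiation, closed-form multiplicative epistasis with
    sign analysis across repressor concentration, position-specific
    binding-energy matrices with additive sequence energies, estimation of
    epistasis from replicate fluorescence measurements with error
    propagation and FDR-corrected tests, classification of epistasis types
    (magnitude, sign, reciprocal sign), cohort-level statistics
    (sign-bias chi-squared, genotype-by-genotype-by-environment ANOVA,
    sign-prediction conformity), effective-concentration fitting by
    correlation maximization, and a fully synthetic study generator with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
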