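Package: pipbind
Title: Competitive Binding Analysis of PCNA PIP-Box Interactions by
    Fluorescence Polarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein-peptide interactions at the
    PCNA PIP-Box site from fluorescence polarization (FP) assays: exact
    competitive-binding equilibrium models (direct quadratic, complete
    cubic, and incomplete four-state solvers), anisotropy to fraction-bound
    conversion with quantum-yield correction, Hill and logistic curve
    fitting, classic and FP-modified Cheng-Prusoff inhibition constants,
    Z-prime assay quality control and Grubbs outlier screening. Also
    includes forward/reverse PIP-Box motif scanning over protein sequences
    and trajectory-ensemble analytics (Kabsch superposition, RMSD, RMSF,
    snapshot PCA, Shrake-Rupley solvent-accessible surface area,
    anchor/tether residue classification, hydrogen-bond presence), plus
    synthetic-data generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
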