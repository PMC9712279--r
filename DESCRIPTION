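Package: expansionqc
Title: Isotropy Quantification and Punch-Level Proteomics for
    Hydrogel-Based Tissue Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how isotropically a tissue section expands when
    embedded in a swellable hydrogel, from paired pre- and post-expansion
    brightfield images: landmark-guided similarity (Procrustes)
    registration, cubic B-spline free-form deformation refinement, dense
    deformation vector fields, and root-mean-square length-measurement
    error curves as a function of measurement distance.  Adds the
    microsampling geometry calculus for biopsy-punch microdissection of
    expanded tissue (linear and volumetric expansion factors,
    pre-expansion punch diameter, cylindrical tissue volume and cell-count
    estimates), a punch-level label-free proteomic pipeline (sample QC by
    protein count and pooled-sample coefficient of variation, minimum
    imputation, fold change with missing values omitted, per-protein
    t-tests with Benjamini-Hochberg adjustment, correlation clustering,
    four-parameter logistic identification-saturation fits), spatial
    z-score abundance maps over the tissue image, and ground-truthed
    synthetic generators (image phantoms with planted deformation fields
    and a factorial punch study design with planted fold changes and
    intensity-dependent dropout) so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    EBImage,
    Matrix,
    minpack.lm,
    pheatmap,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
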