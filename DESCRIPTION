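Package: fetalcortex
Title: Histology Reconstruction, Developmental Transcriptomics and
    Allometric Scaling of the Fetal Cortex
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrated analysis of the mid-gestation human
    brain: detection and repair of artifacts in serial Nissl-stained
    histological sections by comparison with label-conditioned synthetic
    predictions and Poisson image editing; graph-based rigid alignment of
    sections into a 3D volume with shape-prior-constrained affine
    refinement and projection of in situ hybridisation data; processing
    of laser-microdissection microarray tables into gene x specimen x
    region x zone expression tensors via differential-stability probe
    selection; per-gene linear models of expression over tissue zone,
    cortical region and gestational timepoint with FDR control;
    vertexwise allometric scaling of cortical surface area across a
    fetal MRI cohort; and association of regional expression with areal
    scaling, with hypergeometric, odds-ratio and permutation-based
    gene-set enrichment statistics. Seeded synthetic-data generators
    with known ground truth are provided for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    igraph,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    png,
    fgsea
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Microarray, Preprocessing,
    Visualization, Spatial
RoxygenNote: 7.3.3
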