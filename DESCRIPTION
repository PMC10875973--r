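Package: fociMCPA
Title: Coordinate-Based Meta-Analysis and Multi-Coordinate Pattern Analysis of Neuroimaging Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing peak-activation coordinates (foci) pooled
    across functional neuroimaging studies. Implements activation likelihood
    estimation (ALE): per-study modelled-activation maps from Gaussian
    kernels, the complement-product ALE union, a permutation null with
    voxel-wise empirical p-values and cluster-level family-wise error
    control, NIfTI export and cluster tables. Also implements
    multi-coordinate pattern analysis (MCPA): one-hot encoding of integer
    millimetre coordinates into per-axis binary blocks, multi-block sparse
    partial least squares discriminant analysis with variable-count
    sparsity tuning, balanced error rates, relevance networks built from
    latent-component association scores, and reconstruction of candidate
    foci from cross-block network triangles. A synthetic foci generator
    with planted spatial clusters supports end-to-end validation, and a
    command-line interface wires the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    RNifti,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
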