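Package: crossmod
Title: Joint Structural-Functional Brain Network Analysis with
    Cross-Modularity Parcellation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multimodal brain connectomes in
    case-control cohorts. Builds hierarchical multimodal parcellations by
    cutting functional and structural dendrograms and scoring the cuts with
    Newman modularity, Sorensen similarity and a cross-modularity index;
    compares inter-module structural degree between groups with
    covariate-adjusted general linear model contrasts and subject-label
    permutation nulls; summarises per-module BOLD dynamics (first principal
    component variance, skewness, kurtosis and point-process peak counts);
    maps module functional networks by per-module PCA plus fixed-point ICA,
    voxel-wise spatial regression, and k-means clustering of spatial maps
    into most representative clusters with Monte-Carlo cluster-extent
    family-wise error correction; scores posturography trajectories
    (inverse path length, directional control) and relates imaging
    descriptors to balance behaviour. A synthetic-cohort generator with
    parameterised planted effects provides a ground-truth surface for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
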