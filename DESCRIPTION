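Package: omicpairs
Title: Phenotype-Dependent Integration of Metabolomic and Transcriptomic
    Profiles
Version: 0.1.0
Author: omicpairs developers
Maintainer: omicpairs developers <omicpairs-dev@example.org>
Description: Integrates a gene expression matrix and a metabolite abundance
    matrix measured on the same samples to find gene-metabolite pairs whose
    association differs between two phenotype groups (for example pig breed,
    or high versus low feed efficiency).  Provides count and abundance
    preprocessing (low-count, relative-standard-deviation and variance
    filters; size-factor normalization; log transforms), per-feature
    covariate adjustment by fixed-effect linear models, an exhaustive
    vectorized per-pair linear model with a gene-by-phenotype interaction
    term, Benjamini-Hochberg false discovery rate control across the full
    family of fitted pairs, per-group Spearman correlations and their signed
    difference, sign-based clustering of significant pairs, hypergeometric
    pathway over-representation with optional relative-betweenness topology
    scoring, and a synthetic data generator with planted interactions so the
    whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, igraph
Suggests: testthat (>= 3.0.0), pheatmap
Config/testthat/edition: 3
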