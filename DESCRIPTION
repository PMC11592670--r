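Package: CRUmesh
Title: Peripheral Ryanodine Receptor Cluster Network Analysis for
    Cardiac Pacemaker Cells
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the three-dimensional network of
    ryanodine receptor (RyR) clusters (calcium release units, CRUs)
    segmented from super-resolution images of sinoatrial node cells.
    Extracts the peripheral cluster network from labeled volumes using
    density-based noise removal (DBSCAN with a MAD-scaled epsilon) and
    an optimized alpha-shape surface, models cluster-size distributions
    with a two-component Gamma mixture selected by BIC, quantifies
    spatial repulsion between neighboring clusters via the power-law
    exponent of the ascending nearest-neighbor-distance histogram, and
    generates CRU networks along a repulsion schedule (uniform random
    to crystal-like) with realistic or identical RyR-count assignment
    under exact total-RyR conservation, for use in pacemaker-cell
    simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, Spatial, Clustering, ImageAnalysis
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'data-io.R'
    'periphery.R'
    'alpha-shape.R'
    'size-mixture.R'
    'spatial-repulsion.R'
    'network-gen.R'
    'synthetic-cell.R'
    'pipeline.R'
    'CRUmesh-package.R'
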