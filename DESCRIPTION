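Package: smlmFields
Title: Quantification of Postsynaptic Receptor Fields from Single-Molecule
    Localization Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying glutamate-receptor fields at the Drosophila
    neuromuscular junction from dSTORM localization data. Reads
    rapidSTORM-style localization tables, applies intensity filtering and
    polygon region-of-interest clipping, extracts localization clusters with
    hierarchical density-based clustering (HDBSCAN) including a two-parameter
    stability sweep, measures cluster areas with two-dimensional alpha shapes
    under a squared-circumradius convention with an automatic alpha selection
    rule, and applies area-based exclusion before summary statistics. A
    companion module computes quantal content, voltage-scaled miniature EPSC
    amplitudes and paired-pulse ratios from two-electrode voltage-clamp
    event-amplitude tables. Synthetic generators for clustered localization
    scenes and for recording tables make every stage testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deldir,
    sp,
    FNN,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    interp,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
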