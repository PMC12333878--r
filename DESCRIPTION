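Package: dfcdist
Title: Topological and Geometric Distance Analysis of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sliding-window dynamic functional connectivity (dFC)
    sequences from regional brain time series and quantifies their temporal
    change with seven distance metrics: Manhattan, Frobenius, Chebyshev,
    nuclear-norm and spectral matrix distances, plus 0- and 1-homology
    Wasserstein distances on graph filtrations of each connectivity matrix.
    Per-subject distance series are reduced to mean and top-5-peak summaries
    and compared between diagnostic groups by sex-stratified, age-residualized
    two-tailed permutation tests with Bonferroni correction. Includes a
    reproducible synthetic-cohort generator with configurable sustained and
    transient (peak) connectivity effects and an age confound, so the whole
    pipeline can be exercised and calibrated without access to restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
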