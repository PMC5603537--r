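Package: methanokin
Title: Stoichiometry, Kinetics and Carbon Balance for Methanogenic Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of anaerobic methanogenesis in
    sealed laboratory microcosms. Builds balanced methanogenic cell-synthesis
    reactions for arbitrary organic substrates via electron-equivalent
    partitioning (fs/fe), computes theoretical methane yields, chemical oxygen
    demand and Owen-style conversion efficiencies; fits modified-Gompertz and
    linear models to cumulative methane time series; speciates dissolved
    inorganic carbon from pH and constructs per-sampling-day carbon mass
    balances with biomass as the closing residual; and generates synthetic
    microcosm datasets so the whole pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
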