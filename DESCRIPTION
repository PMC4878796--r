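Package: wntpetri
Title: Qualitative Petri Net Simulation of Wnt/Beta-Catenin Signaling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and executes qualitative place/transition Petri nets under
    a maximally parallel token game with uniform-random conflict resolution and
    exact fractional arc-weight firing rates (a weight of 0.1 means one token
    transfer per ten firings, realised through exact rational credit
    accumulators). Ships a curated Petri net of the core Wnt/beta-catenin
    signaling pathway (receptor module, signalosome, destruction complex,
    beta-catenin production and degradation, TCF/LEF transcription and AXIN2
    negative feedback) together with campaign drivers for WNT stimulation,
    GSK3 inhibition, APC inactivating mutations and AXIN2 feedback sweeps.
    Results are tidy tibbles with ggplot2 autoplot() methods; nets interchange
    via PNML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
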