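Package: morangame
Title: Finite-Population Moran Evolutionary Games of Pharmaceutical R&D
    Innovation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Frequency-dependent Moran-process evolutionary game between an
    R&D innovation strategy and a non-R&D innovation strategy in a finite
    group of pharmaceutical enterprises, under government tax incentives and
    industry R&D cooperation. Provides exact fixation (rooting) probabilities
    of both strategies by the recursive birth-death formula and by an
    independent tridiagonal linear solve, linear and exponential fitness
    regimes, first-order weak-selection approximations and the 1/N rule,
    invasion analysis with group-size thresholds, a reproducible Monte Carlo
    chain simulator, and deterministic parameter sweeps with CSV and plot
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
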