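Package: iondetail
Title: Ionization Detail Parameters Linking Nanodosimetry to Cell Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing nanodosimetric statistics from ionization
    cluster size distributions (ICSDs) in nanometre-scale targets - the mean
    cluster size M1, cumulative probabilities Fk, and the binomially weighted
    damage statistic R2(p) - together with linear-quadratic cell-survival
    mathematics (iso-survival dose, relative biological effectiveness,
    inactivation cross sections) and a chi-square grid fit of the proportional
    model sigma ~ K * R2(p; d) that connects the two. Includes binomial
    thinning of ICSDs (the detector-efficiency equivalence eta = p), quadratic
    interpolation of nanodosimetric quantities over energy and atomic number,
    and a synthetic track-segment Monte Carlo plus survival-record generator
    with known ground truth for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
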