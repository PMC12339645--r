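Package: ctcal
Title: Stoichiometric CT Number Calibration and Dose-Impact Analysis for
    Tissue-Equivalent Phantom Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how well a tissue-equivalent phantom plug
    represents the tissue it stands in for, and what that mismatch costs in
    radiotherapy dose calculation. Computes power-law effective atomic
    numbers and relative electron densities from elemental mass fractions,
    predicts CT numbers with a two-term stoichiometric calibration model
    (fitted to measured plugs by Nelder-Mead least squares), builds and
    modifies piecewise-linear CT-to-electron-density/mass-density conversion
    tables, simulates phantom CT slices with circular-ROI statistics, and
    extracts cumulative dose-volume-histogram metrics (D2%, D50%, D98%) with
    relative dose-difference reports. Ships the elemental composition of the
    Gammex Brain SR-2 plug alongside the ICRP Publication 110 reference
    brain for direct comparison.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
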