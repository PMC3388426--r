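Package: humcap
Title: Human-Capital Valuation of Premature Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Values premature deaths by the human-capital method: the present
    discounted value of income foregone between the age at death and the
    statutory retirement age. Takes individual-level mortality records through
    working-age filtering, years-to-retirement cohort binning, per-person
    annuity valuation (or externally supplied per-person values), national
    aggregation with currency conversion, cohort percentage shares, and
    budget-share ratios, with discount-rate and retirement-age sensitivity
    sweeps and a friction-cost comparator. Includes a seeded synthetic
    mortality-record generator emulating the cohort structure of a national
    young-stroke mortality costing for Fiji.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
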