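Package: arscore
Title: Annual Risk Scores for Climate-Induced Downside Risk in Crop Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how farmers perceive climate-induced downside
    risk during a growing season. A still-good-yield (sgy) threshold elicited
    from growers separates acceptable from risky seasons; acceptance ranges
    for mid-season crop and soil observations are initialised at Tukey boxplot
    whiskers of simulated growth histories that met the threshold, and each
    new season is scored with binary per-parameter utilities that sum to an
    Annual Risk Score (ARS). Includes a stochastic daily weather generator and
    a lightweight winter-wheat growth simulator for building sowing-date
    what-if grids, mean-standard-deviation risk summaries across climate
    scenarios, survey-based sensitivity typing, year-on-year adaptation of
    acceptance ranges, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
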