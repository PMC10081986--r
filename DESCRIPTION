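Package: ipoctrace
Title: Tracing Sea-Ice Algal Carbon Through Arctic Food Webs with HBI
    Lipid Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts per-sample highly branched isoprenoid (HBI) lipid
    biomarker intensities (IP25, HBI II, HBI III) into the H-Print index
    and calibrated estimates of sea-ice particulate organic carbon (iPOC)
    for marine consumers; classifies samples by carbon source; summarizes
    iPOC by species, habitat and month; fits and ranks ordinary
    least-squares models by AIC; quantifies the robustness of the habitat
    effect to omitted confounders via partial R-squared and robustness
    values; and estimates bioturbation-accessible sea-ice carbon stored in
    dated sediment cores. A synthetic-data generator reproduces the
    statistical structure of Arctic consumer surveys so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
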