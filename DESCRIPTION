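Package: cvdoffset
Title: Cost-Offset Scenario Modelling of Municipal Interventions on
    Cardiovascular Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scenario engine for estimating how municipal ("distal")
    interventions change population cardiovascular risk factors through
    behavioural ("proximal") channels, and for converting those changes into
    avoided acute events, avoided deaths and health-sector cost savings over a
    multi-year horizon. Works on stratified city populations (age band by sex
    cells carrying mean risk-factor levels), scores interventions on six
    assessment metrics, applies sex-specific Framingham-family ten-year risk
    equations at stratum means, and compares baseline against intervention
    scenarios. Ships a synthetic population generator, editable intervention
    fixtures, a plotting and tidying layer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
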