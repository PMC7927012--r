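Package: mortboot
Title: Lee-Carter Mortality Models, Block-Bootstrap Intervals and Functional
    ANOVA of Forecast Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Lee-Carter-family mortality models (one or two bilinear
    age-period terms, and the simplest cohort extension) to an age-by-year
    surface of death probabilities by quasi-binomial maximum likelihood on
    the logit scale, builds block-bootstrap confidence intervals for
    forecast period mortality indicators (life expectancy, modal age at
    death, Gini index of lifespan inequality), and tests model, sample and
    interaction effects on the forecast indicator curves with a
    random-projection functional ANOVA combined by the false discovery
    rate.  A synthetic-data module generates mortality surfaces with known
    Lee-Carter and cohort structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
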