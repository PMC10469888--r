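Package: rmmits
Title: Treatment Episodes, Pregnancy Identification and Interrupted Time
    Series for Retinoid Pregnancy-Prevention-Programme Impact
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate the impact of the 2018 revision of the
    European pregnancy prevention programme for oral retinoids from
    electronic-health-database records. Builds retinoid and contraceptive
    treatment episodes from prescription and dispensing records with a
    permissible-gap rule, identifies pregnancies from four source streams
    with colour-coded date certainty and gestational imputation, detects
    retinoid-pregnancy temporal overlap, computes monthly incidence,
    prevalence, discontinuation, contraception-coverage and
    pregnancy-testing series, and fits segmented generalised least squares
    interrupted time-series models with seasonal adjustment and
    autoregressive errors. A seeded synthetic-data generator emulates the
    common-data-model table layout so the whole pipeline is testable
    without access to the source databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    lmtest,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
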