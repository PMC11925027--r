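Package: vivforecast
Title: Monte Carlo Forecasting of Transcatheter Valve-in-Valve Procedure
    Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-level Monte Carlo simulation of bioprosthetic aortic
    valve failure and its transcatheter treatment in the United States.
    Annual TAVR and bioprosthetic SAVR implant volumes seed synthetic
    patient cohorts; each patient receives an age, a surgical-risk class, a
    valve durability drawn from a truncated normal mixture, and a
    post-procedure survival time. Patients whose valve fails before death
    become valve-in-valve (ViV) candidates; redo-surgery exclusion and a
    year-dependent treatment-penetration schedule then determine annual
    TAVR-in-SAVR and TAVR-in-TAVR procedure counts through 2035. A replicate
    ensemble yields per-year means and standard deviations plus headline
    summaries (2035 total ViV, ViV share of all TAVR, crossover year).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
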