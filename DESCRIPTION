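Package: pescreen
Title: First-Trimester Preeclampsia Screening from Maternal Characteristics,
    Serum Markers and Mean Arterial Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a first-trimester screening pipeline for early- and
    late-onset preeclampsia (EO-PE, LO-PE). Serum markers (PAPP-A, free
    beta-hCG, ADAM12, PlGF) and mean arterial pressure are normalized to
    multiples of the gestation-specific median (MoM) with maternal-weight and
    smoking corrections; prior risks are computed from maternal
    characteristics by logistic regression with backward elimination and a
    chi-square based shrinkage factor; posterior risks combine prior odds
    with Gaussian likelihood ratios on log10 MoMs; performance is summarized
    as detection rates at fixed false-positive rates with bootstrap
    confidence intervals. A seeded synthetic nested case-control cohort
    generator makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
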