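Package: crldating
Title: Gestational Age Dating from Crown-Rump Length under Gestational Age Truncation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building early-pregnancy dating charts (gestational age
    as a function of crown-rump length) when the observed gestational age range
    is truncated by study design, typically to 9+0 to 13+6 weeks. Implements
    fractional-polynomial mean-and-SD centile models on the natural-log scale,
    a lognormal simulation engine driven by a published closed-form dating
    equation, three strategies for handling outcome truncation (low-end
    augmentation with restriction and extrapolation; two-sided augmentation;
    axis interchange of a fitted size chart), and an evaluation layer that
    produces centile comparison tables, tail-coverage counts and agreement
    summaries against a reference dating equation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
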