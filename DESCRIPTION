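Package: lexrisk
Title: Life Expectancy Impacts of Individual Risk Factor Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-risk life-expectancy engine. Given a parameter
    bundle (cause-specific mortality rates, risk-factor exposure
    distributions, relative-risk dose-response functions, mediation factors
    and risk-reversal half-lives) and a personal risk profile, the package
    builds abridged period life tables and computes life expectancy at any
    age, survival curves, horizon-limited cause-group death risks, and
    scenario deltas: single-factor elimination gains, exposure-level sweeps,
    and simultaneous or sequential multi-factor changes with or without a
    lagged (exponential-decay) risk-reversal model. A synthetic parameter
    generator produces miniature, fully valid bundles so the whole pipeline
    is testable without external mortality data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
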