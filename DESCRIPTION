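Package: avrabbit
Title: Bayesian Causal Inference Modeling of Audiovisual Numerosity Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modeling and maximum-likelihood fitting of audiovisual
    numerosity judgments in the sound-induced flash (audiovisual rabbit)
    paradigm. Implements the Bayesian causal inference (BCI) observer model
    with Gaussian sensory noise, a Gaussian numerosity prior, and a causal
    prior over common versus independent causes; its forced-fusion,
    full-segregation, and maximum-likelihood-estimation special cases; and
    three decision strategies (model averaging, model selection, probability
    matching). Provides deterministic quadrature prediction of discrete
    response distributions, multi-start maximum-likelihood fitting with BIC
    model comparison and R-squared goodness of fit, signal-detection and
    behavioral summaries with log-linear correction, a synthetic-data
    generator emulating the factorial flash-by-beep design for parameter- and
    model-recovery studies, and an end-to-end simulate-fit-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
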