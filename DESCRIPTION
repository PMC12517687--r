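Package: neurodisc
Title: Behavioral and Neuronal Discriminability Analysis for Go/No-Go
    Auditory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Go/No-Go auditory discrimination sessions in mice:
    signal-detection behavioral metrics (d-prime, criterion, running d-prime,
    psychometric fits), single-neuron responsiveness and firing properties,
    time-resolved ROC/AUC neurometric discriminability with a shuffle null,
    population decoding by shrinkage linear discriminant analysis with Fisher
    separation and decoding latency, and passive-listening frequency-response
    area tuning metrics. Includes a seeded synthetic-session generator
    (signal-detection behavior plus inhomogeneous-Poisson spike trains with
    planted stimulus and choice signals) so every stage can be validated by
    parameter-recovery tests, and a pipeline that runs all stages on session
    directories stored as plain delimited text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
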