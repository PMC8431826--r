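Package: connectrol
Title: Network Controllability of Anatomical Brain Networks and
    Mixed-Effects Analysis of Language Response Times
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes modal and boundary controllability of nodes in
    weighted, undirected anatomical brain networks under a noise-free
    linear discrete-time dynamics model, including matrix stabilization,
    controllability Gramian diagnostics, modularity maximization across a
    resolution sweep with z-Rand partition similarity and association-matrix
    consensus clustering, and boundary-region ranking.  Couples the network
    measures to trial-level language production data through mixed-effects
    models of log response times (random intercept and trial-order slope per
    subject, Satterthwaite tests), testing whether controllability of a
    target region moderates selection and retrieval costs and the effects of
    inhibitory transcranial magnetic stimulation.  A synthetic-data module
    generates modular weighted connectomes and behavioral trial tables with
    the same statistical structure, so the full pipeline is testable without
    access to diffusion-imaging or behavioral recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
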