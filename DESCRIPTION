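Package: evinet
Title: Temporal Evidence Networks for Treatment Regimen Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, scores, and visualizes network meta-analytic multigraphs of
    treatment regimens from a registry of randomized controlled trials. Vertices
    are substantively identical regimens and parallel edges are head-to-head
    trial comparisons. Each regimen is valued by a win/lose/tie contest scheme
    weighted by outcome quality (weak surrogate, strong surrogate, overall
    survival) and scaled by the logarithm of the patients contributing evidence.
    Yearly snapshots evolve under a recency (alpha opacity) model with decay,
    refresh on new evidence, and cascade refresh when a regimen's classification
    flips between superior and inferior. Includes a transcribed chronic
    myelogenous leukemia trial registry with clearly labelled synthetic outcome
    annotations, a synthetic trial-stream generator with recoverable latent
    regimen qualities, Kamada-Kawai layouts warm-started across years, and
    SVG/PNG/GraphML/GML export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
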