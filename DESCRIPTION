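Package: alignersim
Title: Staged Clear-Aligner Biomechanics for Premolar Distalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reduced-order quasi-static simulation of staged clear-aligner
    premolar distalization in a parametric right maxillary quadrant. Teeth are
    rigid bodies supported by a linear elastic (Winkler) periodontal-ligament
    foundation sampled on the root surfaces; the aligner is a rigid frame
    carrying per-tooth sockets with unilateral mesial/distal walls under three
    trimline designs (conventional, second-molar half-wrap, all-molar
    half-wrap). The engine solves coupled tooth/aligner equilibrium with
    active-set contact, runs an iterative bone-remodeling loop through a
    10-step x 0.2 mm staging protocol with skeletal-anchorage traction, and
    reports tooth displacements and rotations in per-tooth local frames
    together with distalization efficiency and molar anchorage loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
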