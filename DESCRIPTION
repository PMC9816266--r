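Package: mirrorcue
Title: Colour-Symmetric Pattern Generation, Holographic Goodness, and
    Simulated Symmetry-Detection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mirror-symmetry detection in colour patterns.
    Generates wedge and random-dot stimuli under the colour-symmetry conditions
    used in two-interval forced-choice (2IFC) symmetry detection experiments
    (segregated, nonsegregated, antisymmetric and colour-grouped arrangements,
    plus matched random foils), scores any pattern with the holographic model
    of regularity (perceptual goodness W = E/N, the number of mirror-symmetric
    element pairs over the total number of elements), simulates a parametric
    2IFC observer with positional encoding noise and feature-based attention
    to colour, builds complete blocked experiment designs with cue-validity
    accounting and performance-based exclusion rules, and analyses single-trial
    accuracy with binomial mixed-effect models using backward elimination by
    likelihood-ratio tests, multiplicity-adjusted post hoc contrasts and
    standardized odds-ratio effect sizes. Patterns can be rendered to PNG
    images and serialized to versioned JSON manifests; a small command-line
    interface covers generation, scoring, design export, simulation and
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    ggplot2
Config/testthat/edition: 3
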