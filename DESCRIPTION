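Package: jawspace
Title: Morphofunctional Morphospace and Disparity Analysis of Lower Jaws
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative functional morphology of vertebrate
    lower jaws, built around lever-theory biomechanics. Computes
    mechanical-advantage indices and standardized morphofunctional
    characters from raw mandibular measurements, builds a Euclidean
    principal-coordinate morphospace, tests group separation with
    permutational multivariate analysis of variance (one-way and
    pairwise, with Bonferroni and Benjamini-Hochberg correction),
    quantifies disparity as sum of variances with bootstrap intervals
    and permutation tests, classifies feeding guilds with jackknifed
    linear discriminant analysis, and compares individual morphological
    and functional metrics across clades and guilds. Includes a
    seeded synthetic-assemblage generator encoding feeding-guild
    archetypes so the whole pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
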