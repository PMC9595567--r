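Package: altcolony
Title: Spatial Individual-Based Simulation of the Evolution of Altruism
    with Emergent Colony-Level Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic individual-based model of a motile population in a
    periodic one- or two-dimensional habitat in which organisms carry a single
    heritable altruism trait. Altruists pay a reproductive cost to provide a
    saturating, kernel-smoothed public good to their neighbourhood, while all
    individuals compete for resources over a longer spatial scale. Under
    suitable length scales the population self-organizes into colonies that
    reproduce by fission and die, and the package provides the full analysis
    stack for that process: per-step Price-equation decomposition of trait
    change into selection, drift, and mutational bias; automated recognition
    and lineage tracking of colonies with hysteresis thresholds; multilevel
    selection decompositions (MLS 1 and MLS 2) with a death/birth split of
    colony-level selection; an inclusive-fitness (Queller partial-regression)
    analysis; linear stability analysis of the homogeneous state; and spatial
    pattern statistics (radial distribution functions, smoothed-density
    variance, dominant Fourier mode, hexagonal lattice-constant estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
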