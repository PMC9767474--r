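Package: allelewave
Title: Spatiotemporal Inference of Beneficial Allele Spread from Ancient Genomes
Version: 0.1.0
Authors@R:
    person("Allelewave", "Developers", email = "allelewave@example.org",
           role = c("aut", "cre"))
Description: Fits wave-of-advance models for the geographic spread of a
    beneficial allele to time-stamped ancient and present-day genotype data.
    A two-dimensional diffusion-advection-reaction partial differential
    equation is solved on a geographic grid with a land/water mask to obtain
    the allele-frequency surface p(x, y, t); genotype likelihoods, hard
    diploid genotypes, and pseudohaploid calls are evaluated against that
    surface; and selection, diffusion, advection, and allele-origin
    parameters are estimated by maximum likelihood (Latin hypercube
    multistart, simulated annealing, and bounded quasi-Newton refinement)
    with asymptotic confidence intervals from the observed Fisher
    information. Includes deterministic-surface sampling designs and a
    spatially explicit individual-based forward simulator for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
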