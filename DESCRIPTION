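Package: porelink
Title: Driven Translocation of Polycatenanes and Ring Polymers Through
    Crystalline Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin dynamics of mechanically interlocked
    ring polymers (poly[4]catenanes) and simple ring polymers driven through
    a cylindrical pore carved in an FCC crystal slab, together with the
    translocation statistics needed to characterise the process: first-passage
    (irreversible) and instantaneous-census (reversible) translocation
    profiles, waiting times, knot (Hopf-link) passage events, in-pore ring
    orientation via SVD plane fitting, and Shannon entropies of orientation
    distributions. Includes an engine-free synthetic-trajectory generator with
    ground-truth annotations for validating every analysis stage, and a
    replica-sweep pipeline that aggregates seeded replicas into means with 95%
    confidence intervals, including the pore-radius dependence of the total
    translocation time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
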