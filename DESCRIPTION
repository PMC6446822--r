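Package: whackamole
Title: Stochastic Metapopulation Simulation of Bt Resistance Management
    with Self-Limiting Insect Releases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, discrete-generation simulation of Cry1Ac
    resistance evolution in caged metapopulations of the diamondback moth
    under the high-dose/refuge strategy, with mass release of female-lethal
    (fsRIDL) self-limiting transgenic males. Tracks two unlinked loci (a
    biallelic resistance locus and a dominant, tetracycline-repressible,
    female-specific lethal construct) through random mating, egg allocation
    to refuge and toxin diets, viability selection, pupal dispersal among
    subpopulations, and homogeneous ("everywhere") or spatially targeted
    ("whack-a-mole") release policies. Includes a deterministic
    infinite-population recursion used as a verification oracle, the two
    standard resistance readouts (toxin survivors in cage and diagnostic-dose
    bioassay), and a light statistics layer (arc-sine quadratic trend fits,
    lag-1 autocorrelation of detrended series, permutation treatment tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
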