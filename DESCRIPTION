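Package: popselscan
Title: Multilocus Selection Scans from Candidate and Reference Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects natural selection on candidate genes by contrasting
    them against neutral reference loci sequenced from the same samples.
    Provides per-locus diversity statistics (segregating sites, Watterson's
    theta, nucleotide diversity, Tajima's D, divergence to an outgroup,
    Hudson's FST with permutation tests), standard neutral coalescent
    simulation in fixed-theta and fixed-S modes for null distributions,
    a reference-calibrated diversity/site-frequency outlier scan, a
    between-species pi_T-S differentiation test, the multilocus HKA
    goodness-of-fit test with a parametric-bootstrap p-value, maximum
    likelihood HKA with per-locus selection factors and likelihood-ratio
    tests, and hierarchical Bayesian McDonald-Kreitman Poisson random
    field estimation of population-scaled selection coefficients
    (gamma = 2*Ne*s). A synthetic two-species + outgroup data generator
    with known truth supports end-to-end validation without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
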