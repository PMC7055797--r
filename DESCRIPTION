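Package: snapdup
Title: Simulation and Detection of Chromosomal Duplication Dynamics During
    Niche Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the population dynamics of selection during niche
    adaptation (SNAP), in which bacterial gene-order rearrangements arise from
    selected chromosomal duplications followed by reciprocal inactivation of
    essential genes in the two copies. Provides a resource-limited (Monod)
    batch-growth integrator, a serial-transfer simulator with Monte Carlo
    mutant appearance and bottleneck dilution for the wild-type/duplication/
    single-inactivation/double-inactivation strain model, a read-depth scanner
    that detects duplicated chromosomal segments and diverging duplicated
    copies (~50% alternate-allele sites) from coverage and pileup tables with
    variant-effect classification against a CDS annotation, and a synthetic
    sequencing-data generator (negative-binomial depth, binomial allele
    counts) that produces all scanner inputs together with truth files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'strain_model.R'
    'growth.R'
    'passage.R'
    'coverage_scan.R'
    'effect.R'
    'synthetic.R'
    'io.R'
    'cli.R'
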