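Package: popldiv
Title: Diversity, Linkage Disequilibrium and Linkage-Phase Persistence in
    Structured Random-Mating Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of within- versus across-population genetic
    diversity for panels of open-pollinated populations (landraces) genotyped
    at bi-allelic SNPs: folded site-frequency spectra with the neutral
    coalescent expectation, proportion of polymorphic markers, per-marker
    nucleotide diversity, sliding-window haplotype heterozygosity,
    Weir-Cockerham inbreeding coefficients with permutation tests,
    distance-based AMOVA and variance-capture resampling, modified Rogers'
    distances with neighbor joining, principal coordinate analysis, Mantel and
    Procrustes comparisons, LD pruning, pairwise r/r2 with Hill-Weir decay
    fitting and decay distances, sampling-design experiments for germplasm
    panels, and persistence of linkage phase between populations. Includes a
    forward Wright-Fisher generator of structured random-mating populations
    with known truth so every statistic is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    optparse
Config/testthat/edition: 3
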