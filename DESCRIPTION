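Package: musadiv
Title: Marker Diversity, Population Structure and Volatile Profiling for
    Banana Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of dominant DNA-fingerprint data (RAPD, ISSR and
    band-scored SSR) for mixed-ploidy banana (Musa spp.) germplasm panels:
    per-primer informativeness statistics (PIC, effective allele number,
    Shannon index, expected and unbiased heterozygosity, resolving power,
    marker index), Dice shared-band similarity with UPGMA dendrograms and
    Newick export, principal coordinates analysis, one-level AMOVA with
    permutation-tested Phi-ST and pairwise differentiation, Evanno delta-K
    summarisation of Bayesian clustering runs, and GC-MS volatile-profile
    analytics with Kovats retention-index calibration. Includes seeded
    Balding-Nichols generators of structured dominant fingerprints,
    clustering-run summaries and volatile tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    ape,
    vegan,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
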