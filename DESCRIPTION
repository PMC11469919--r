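Package: dcsminer
Title: Genome Mining for Fused Bifunctional Diterpene Cyclase/Synthases
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects fused bifunctional diterpene cyclase/synthase (DCS)
    genes in bacterial proteomes by intersecting an alpha-domain terpene
    synthase screen with a gamma-beta-didomain diterpene cyclase screen,
    classifies Class I / Class II aspartate-rich catalytic motifs
    (DxDD, DDxxD, NSE and their aberrant variants), splits candidate
    fusions into independently testable cyclase and synthase constructs,
    applies anchored in-silico mutagenesis with product-outcome rules for
    the CPS-KS lineage, and places sequences by progressive alignment,
    Poisson-corrected distances and neighbor joining. Ships a seedable
    synthetic-proteome generator with planted domain architectures so the
    whole screen runs and is validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    ape,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
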