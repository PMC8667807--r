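Package: ringcharge
Title: Charge-Permeability Modelling of AMPA and NMDA Receptor Channels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary ion permeability of ionotropic glutamate
    receptor (AMPA/NMDA) channels from subunit composition. The selectivity
    filter is modelled as a ring of charge contributed by the pore-lining
    M2 residue of each subunit; an entering ion permeates when it is both
    attracted to the ring and able to displace the resident ion. The
    package ships a registry of rat GluN1, GluN2A-D, GluN3A/B and
    GluA1-4 subunits (including the Q/R-edited GluA2 form), computes ring
    charges for arbitrary assemblies and point mutants, derives channel-level
    steady-state selectivity classes from pore occupancy-state dynamics,
    anchors the filter residue in user-supplied sequences by pairwise
    global alignment, and generates seeded synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
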