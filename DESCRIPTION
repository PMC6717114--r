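Package: tiplinkmech
Title: Tip-Link Mechanics from Single-Molecule Force Spectroscopy, smFRET,
    and Force-Propagation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the mechanics of the hair-cell tip-link
    (the Cdh23-Pcdh15 adhesion complex) studied at the single-molecule
    level. Provides kinetic Monte Carlo generators for AFM force-ramp
    curves with freely-jointed-chain (FJC) tether mechanics and Bell
    rupture kinetics, single-molecule FRET trace simulation and
    efficiency/distance analysis, FJC fitting and classification of
    specific unbinding events, Bell-Evans regression of most-probable
    rupture force against log loading rate, and dynamic network analysis
    of residue trajectories (contact/correlation graphs, Girvan-Newman
    communities, optimal and suboptimal force-propagation paths,
    RMSF and interdomain angles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
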