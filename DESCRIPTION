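Package: cprmd
Title: Reweighted Accelerated-MD Analysis of Redox-Coupled Domain Motion
    in Cytochrome P450 Reductase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying the coupling between redox state
    and interdomain open-close motion in cytochrome P450 reductase (CPR)
    from molecular-dynamics snapshot ensembles.  Implements the
    accelerated-MD (aMD) boost potential and its exponential snapshot
    reweighting to the canonical ensemble, distance-based structural
    observables (interdomain and inter-cofactor alloxazine-ring distances,
    and an FMN-to-heme distance predicted by Kabsch superposition onto a
    CPR-heme-oxygenase complex reference), two-dimensional free-energy
    landscapes, and principal component analysis of C-alpha thermal
    fluctuations.  Ships a toy Langevin simulator on analytic potentials
    and synthetic-ensemble generators so every stage of the pipeline is
    testable at desk scale without all-atom trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
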