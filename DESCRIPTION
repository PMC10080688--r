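Package: phquench
Title: pH-Dependent Protonation, Conformational, and Charge-Transfer
    Quenching Analysis for Light-Harvesting Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline turning constant-pH and enhanced-sampling
    molecular dynamics output into pH-sensing and quenching observables for
    light-harvesting complexes such as LHCSR1: titration curves with Hill
    fits, pKa values and blocked-bootstrap errors; protonation-microstate
    Markov networks over coupled acidic residues; tICA projection,
    density-based clustering and second-order cumulant reweighting of
    boosted free-energy landscapes; chlorin-frame geometry metrics and
    bond-length alternation; TrEsp point-charge excitonic couplings; and
    Marcus charge-separation rates with a coarse-grained excitation
    lifetime model. A synthetic-data module generates every input with
    known ground truth in place of cluster-scale trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    deSolve
Config/testthat/edition: 3
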