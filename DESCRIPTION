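Package: protchase
Title: Cycloheximide Chase Degradome Analysis for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of cycloheximide (CHX) chase label-free quantification
    (LFQ) proteomics experiments for targeted protein degradation studies.
    Reads MaxQuant-style protein-groups tables, applies decoy/contaminant
    filtering, replicate-completeness screening and left-censored
    missing-value imputation, transforms intensities to
    protein-fraction-remaining profiles, fits first-order decay kinetics to
    estimate protein half-lives, selects candidate degrader targets with an
    S0-moderated permutation-FDR differential test, verifies them by
    degradation kinetics and proteasome-inhibition rescue, and ranks
    degradomes by half-life reduction. Includes a steady-state
    protein-turnover simulator that generates chase datasets with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
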