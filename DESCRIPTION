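Package: degronmap
Title: Mapping Degrons from Substitution Arrays, Simulated Trajectories,
    and Binding and Turnover Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for dissecting short degradation motifs (degrons)
    recognized by E3 ubiquitin ligase substrate receptors. Implements
    parent-normalized analysis of positional substitution and truncation
    peptide arrays with Tukey-adjusted significance calls and
    essential-residue classification; Kabsch-superposed RMSD stability
    series, trial-averaged residue contact-frequency maps and pose ranking
    for multi-trial molecular dynamics trajectory ensembles, plus van der
    Waals overlap contact detection on static structures; one-site
    saturation fits of reference-subtracted surface plasmon resonance
    isotherms; and protein turnover quantification from densitometry,
    including cycloheximide-chase half-life estimation. A seeded
    synthetic-data generator emulates each assay with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
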