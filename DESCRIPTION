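Package: fluorelease
Title: Scoring Fluoride-Mediated Release of Organophosphates from Protein Adducts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale, structure-based assessment of how easily
    a fluoride ion displaces an organophosphate from its covalent adduct on
    butyrylcholinesterase or human serum albumin. Provides geometric placement
    of a fluoride probe in line with the P=O bond, productive-conformation
    filtering of docking poses, distance/residence/hydration analysis of
    multi-model PDB trajectories, a screened-Coulomb electrostatic barrier
    score (the difference between the P-O and P-F interaction energies) that
    ranks adducts by reactivation difficulty, and seeded synthetic generators
    (active-site fragments, tethered-ion trajectories, charge tables) so the
    whole pipeline is testable without molecular dynamics or quantum-chemistry
    software.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
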