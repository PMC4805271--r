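Package: confkeys
Title: Key Positions Sustaining Protein Conformational Diversity from
    Elastic Network Mode Subspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies residues that sustain the conformational diversity a
    protein needs for ligand binding. Builds chemically weighted C-alpha
    elastic network models for ligand-free/ligand-bound conformer pairs,
    selects the normal-mode subspace most involved in the binding
    conformational change via mode participation numbers, simulates point
    mutations as local spring perturbations, and scores each residue by the
    Gramian similarity between unperturbed and perturbed mode subspaces.
    Residues with the lowest standardized scores are reported as key
    positions. Includes Henikoff-weighted sequence conservation scoring from
    multiple alignments, characterization analyses (amino-acid and
    secondary-structure incidence, inter-element inertial-axis angle changes,
    active-site distances, accessibility and contact correlates), and a
    synthetic-fixture generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
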