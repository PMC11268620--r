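Package: kinconform
Title: Geometric Classification and Analysis of Protein Kinase
    Conformational Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the conformational landscape of protein
    kinase domains. Reads kinase-domain structures (PDB/mmCIF), locates the
    catalytic DFG, HRD, alphaC-Glu and beta3-Lys motifs, and classifies each
    structure into six DFG/alphaC-helix conformational states (CIDI, CIDO,
    CODI, CODO, DFGinter, Unassigned) from Calpha pseudo-dihedrals and
    anchor-atom distances, together with the activation-loop extended/folded
    state. Aggregates calls into per-stratum distributions and compares them
    with multinomial bootstrap rank-sum tests, Fisher's exact and
    Chi-squared tests with Bonferroni correction, and paired and one-sample
    t-tests; counts conformations predicted by structure predictors but
    unobserved experimentally at per-residue confidence (pLDDT) thresholds;
    scores model-versus-experiment similarity with TM-scores using the
    model as reference and a DFG-motif gate; and evaluates
    virtual-screening enrichment curves and AUCs from docking score tables.
    A synthetic-data module generates kinase Calpha traces with prescribed
    geometry, model manifests over MSA depths, and active/decoy score
    tables with known ground truth.
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
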