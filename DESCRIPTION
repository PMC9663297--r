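Package: af2conf
Title: Confidence-Aware Analysis of AlphaFold2 Predicted Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the confidence estimates that accompany
    AlphaFold2-style predicted protein structures. Reads models (pLDDT stored
    in the B-factor field), predicted-aligned-error (PAE) matrices and
    multiple sequence alignments; segments models into high-confidence units
    and domain-like regions by smoothed pLDDT; scores per-residue intrinsic
    disorder from pLDDT and relative solvent accessibility with ROC
    evaluation; maps structures into a discrete shape-mer space via
    rotation-invariant moments, TFIDF weighting and non-negative matrix
    factorization topic models; extracts rigid domains from PAE matrices by
    community clustering and prepares trimmed cores for molecular
    replacement; generates pLDDT-weighted adaptive (top-out) distance and
    torsion restraints against a reference model; performs homo-oligomer
    state-scan bookkeeping with worst-of-models pTM aggregation; and scores
    predicted binding pockets by the confidence of their associated residues.
    A synthetic-data module generates models, PAE matrices, alignments, state
    scans and planted binding sites with known ground truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
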