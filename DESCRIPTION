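Package: kitdyn
Title: Model Screening and Conformational Dynamics Analysis for the KIT
    Cytoplasmic Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating full-length structural models
    of receptor tyrosine kinase cytoplasmic domains, developed around the
    KIT kinase insert domain (KID). Implements the hybrid model-screening
    stage (end-to-end distance filtering, score-based ranking,
    secondary-structure-similarity clustering with farthest-point linkage,
    medoid representative selection), the trajectory metric suite (Kabsch
    superposition, per-domain RMSD and RMSF, radius of gyration, RMSD100,
    Ramachandran fractions), a Kabsch-Sander-style secondary-structure
    assigner with timelines and conservation scores, essential-dynamics PCA
    and dynamic cross-correlation maps, conformational k-means clustering
    with Davies-Bouldin and Calinski-Harabasz model selection, change-point
    detection on metric series, and a consensus ranking of candidate models.
    Ground-truth synthetic-data generators (bead proteins, Gaussian and
    two-state trajectories, candidate-model ensembles) make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conformational-clustering.R'
    'consensus.R'
    'domain-scheme.R'
    'essential-dynamics.R'
    'geometry.R'
    'model-screen.R'
    'pdb-io.R'
    'ramachandran.R'
    'secondary-structure.R'
    'synthetic-data.R'
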