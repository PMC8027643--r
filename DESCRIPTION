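Package: pepCross
Title: Cell-Penetrating Peptide Classification from Sequence- and
    Structure-Based Descriptors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify short peptides (5-30 residues) as
    cell-penetrating (CPP) or not. Peptides are read from FASTA or PDB,
    turned into a residue-template molecular graph from which twelve
    structure-based descriptors are computed (MW, tPSA, Fsp3, cLogP, HBA,
    HBD, aromatic rings, rotatable bonds, and charge-group counts), and
    combined with sequence-based blocks (Arg/Lys fractions, dipeptide
    composition, type-1 pseudo-amino acid composition) into four feature
    compositions. A soft-voting ensemble of a multilayer perceptron, a
    Gaussian process classifier and an RBF support vector machine is
    tuned by grid search and evaluated by stratified cross-validation.
    Chemical-space profiling against Lipinski/Veber permeability rules,
    entropy-based grouped feature importance, 3D PCA and Bhattacharyya
    class-overlap analyses, and a seeded synthetic benchmark generator
    are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    kernlab,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ranger
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Proteomics, Cheminformatics, MachineLearning
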