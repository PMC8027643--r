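# pepCross

Classification of cell-penetrating peptides (CPPs) from sequence- and
structure-based descriptors, in R.

CPPs are short peptides (here 5–30 standard residues) that cross the
lipid bilayer and are widely used as drug-delivery vehicles. They are
typically cationic at physiological pH and Arg/Lys-rich — and they sit
well outside the chemical space of the classical oral-drug permeability
rules. `pepCross` provides the full pipeline for telling CPPs and
non-CPPs apart:

* **Peptide IO** — FASTA and PDB readers (SEQRES or C-alpha trace; only
  the sequence is used, never the fold), plus the standard dataset
  filters: 5–30 residue length window, duplicate removal, per-descriptor
  |z| ≥ 3 outlier removal.
* **Descriptors** — a residue-template molecular graph per peptide, from
  which twelve structure-based descriptors are computed: MW, Crippen
  cLogP, Ertl tPSA, Fsp³, rotatable bonds (strict), H-bond donors and
  acceptors, aromatic rings, primary amines (NPA), guanidinium groups
  (NG), negative residues (NNCAA) and the net formal charge at pH 7.4
  (NetC). Sequence-based blocks: f[Arg]/f[Lys], overlapping dipeptide
  composition (DPC), and the 22-component type-1 pseudo-amino-acid
  composition (PseAAC, λ = 2, w = 0.05):

  τ_k = (1 / (L − k)) Σᵢ θ(Rᵢ, Rᵢ₊ₖ),   k = 1..λ
  θ(r, s) = ⅓ [ (H₁(r) − H₁(s))² + (H₂(r) − H₂(s))² + (M(r) − M(s))² ]

  with the vector (f₁..f₂₀, w·τ₁, w·τ₂) jointly normalised to sum 1.
* **Feature compositions** — the four published selections: FC1 (64
  sequence features), FC2 (12 structural), FC3 (76, both), FC4 (43:
  9 structural + 2 AAC + 10 DPC + 22 PseAAC), plus Kendall tau-b
  feature ranking.
* **Model** — a soft-voting ensemble of an MLP (`nnet`), a Gaussian
  process classifier and an RBF-SVM (`kernlab`), each tuned by
  exhaustive grid search under stratified cross-validated accuracy.
  The ensemble probability is the unweighted member mean; the label
  rule is CPP iff p > 0.5. Fully deterministic given one seed.
* **Evaluation** — Sn/Sp/Acc/F1/MCC from the confusion matrix
  (3-decimal truncation helper for comparing against published tables),
  rank-formulation AUC, stratified k-fold CV with per-fold tuning, and
  the Kruskal–Wallis H test.
* **Chemical space** — percentile profiles and Lipinski RO5 / Veber /
  extended-bound rule flags per peptide or per library.
* **Information analysis** — entropy-criterion extremely-randomised-trees
  grouped importance (CIE), 3D PCA with explained variance, and
  per-component Bhattacharyya class overlap.
* **Synthetic benchmark** — a seeded generator of Arg/Lys-rich cationic
  positives (NetC ≥ +2) versus uniform-composition negatives
  (NetC ≤ +1), so the whole pipeline is testable without any external
  dataset.

## Worked example

```r
library(pepCross)

## descriptors of a polycationic peptide
structDescriptors("GRKKRRQRRRPPQ")
#>       MW    cLogP     tPSA     Fsp3      NRB      HBD      HBA      NAR
#> 1719.047  -11.772  904.560    0.700   61.000   45.000   51.000    0.000
#>      NPA       NG     NetC    NNCAA
#>    3.000    6.000    8.000    0.000

permeabilityRuleFlags(structDescriptors("GRKKRRQRRRPPQ"))$RO5
#> $pass
#> [1] FALSE
#> $failing
#> [1] "MW <= 500"  "HBD <= 5"  "HBA <= 10"

## train the voting ensemble on the synthetic benchmark
bench <- makeBenchmark(300, 300, seed = 7)
m <- assembleFeatures(bench$peptides, "FC4")
fw <- trainFramework(m, seed = 7)
fw
#> CPPFramework (FC4, 43 features, seed 7)
#>   ann: size=5, decay=1e-04
#>   gpc: lengthscale=5
#>   svm: C=10, gamma=0.001

predictPeptides(fw, PeptideSet(c(tat = "GRKKRRQRRRPPQ",
                                 inert = "GALFLGFLGAAGSTMGA")))
#>      id probability label
#> 1   tat   0.9649808     1
#> 2 inert   0.1667542     0
```

The descriptor row shows why CPPs break the small-molecule permeability
rules: this 13-mer already exceeds the RO5 bounds on mass and hydrogen
bonding while carrying a +8 net charge. The prediction table gives the
mean probability of the three members and the thresholded label
(1 = CPP for p > 0.5).

A command-line front-end over the same functions ships in
`inst/cli/pepcross` (subcommands `describe`, `train`, `predict`,
`evaluate`, `chemspace`, `analyze`, `synth`).

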