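---
title: "Classifying cell-penetrating peptides: models and methods in pepCross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cell-penetrating peptides: models and methods in pepCross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cell-penetrating peptides (CPPs) are short peptides — here restricted to
5–30 standard residues — able to cross the lipid bilayer. They are
typically cationic at physiological pH and rich in arginine and lysine.
`pepCross` classifies a peptide as CPP or non-CPP from its primary
structure alone, using a combination of physicochemical descriptors
computed on a residue-template molecular graph and sequence-composition
descriptors, fed to a soft-voting ensemble of three probabilistic
classifiers.

A deliberate modelling assumption runs through the whole package: **every
descriptor is a function of the sequence only**. A PDB input contributes
its extracted sequence (SEQRES, or the ordered C-alpha trace); folded
coordinates never influence a feature. This keeps FASTA and PDB inputs on
an identical footing and makes the descriptor layer exactly reproducible.

## The molecular graph and the twelve structural descriptors

`buildPeptideGraph()` condenses per-residue heavy-atom templates with the
loss of one water per peptide bond, yielding the neutral molecule with a
free N-terminal amine and C-terminal carboxylic acid. Hydrogens are
implicit counts on heavy atoms. Aromatic flags cover the Phe/Tyr benzene,
both rings of the Trp indole, and the neutral His imidazole
(N-epsilon-H tautomer, matching common toolkit conventions; the choice
does not affect any descriptor value).

From this graph the package computes:

* **MW** — sum of average atomic weights (H 1.008, C 12.011, N 14.007,
  O 15.999, S 32.067), in g/mol.
* **tPSA** — Ertl fragment contributions per N/O environment, in Å²;
  S and P contribute zero as in the original parameterisation.
* **Fsp³** — sp³ carbons (all single bonds, non-aromatic) over all
  carbons.
* **cLogP** — Wildman–Crippen additive model. Instead of a SMARTS
  engine, the atom-typing rules are written out for the closed universe
  of atom environments that occur in linear peptides of the 20 standard
  residues. The test suite pins the result to an independent
  cheminformatics oracle (frozen reference values for 69 peptides) to
  within 0.01.
* **HBA / HBD** — the Lipinski conventions: N+O count, and hydrogens
  attached to N or O.
* **NAR** — aromatic rings on a smallest-set-of-smallest-rings basis,
  computed as the cycle rank of the aromatic subgraph (Trp counts 2).
* **NRB** — strict rotatable bonds: non-ring single bonds between atoms
  with two or more heavy neighbours, excluding C–N bonds whose carbon
  is double-bonded to O or N. That exclusion covers both amides and the
  Arg guanidine; the guanidine case is not spelled out by the usual
  one-line definition, but it is what the strict convention of the
  reference toolkits implements, and the package matches them exactly.
* **NPA, NG, NNCAA, NetC** — charge-group counts on the sequence:
  primary amines (Lys plus the N-terminal alpha-amine unless the first
  residue is proline), guanidinium groups (Arg), negatively charged
  residues (Asp+Glu), and the net formal charge at pH 7.4 under the
  integer model Arg/Lys = +1, Asp/Glu = −1, His neutral, termini
  cancelling. The integer model is deterministic and testable; a
  Henderson–Hasselbalch fractional mode (`model = "hh"`, EMBOSS-style
  pKa set) is available but off by default.

## Sequence-based descriptors

* **AAC** — only f[Arg] and f[Lys], the fractions that characterise the
  cationic CPP profile.
* **DPC** — overlapping dipeptide counts over L−1 windows. The two
  published correlation-selected lists (40 and 10 dipeptides) are
  hardcoded; `rankFeatures()` can re-select for new data but never
  silently replaces them.
* **PseAAC** — the classic type-1 pseudo-amino-acid composition with
  λ = 2 and weight w = 0.05: twenty composition components plus two
  sequence-order correlation factors built from standardised
  hydrophobicity, hydrophilicity and side-chain mass. The printed
  formulation in the source analysis indexes only correlation terms,
  which contradicts its own account of "twenty components of the
  conventional amino acid composition"; the package adopts the classic
  formulation, which is both self-consistent and what the cited
  descriptor family computes. w is not stated in the source; 0.05 is
  the canonical default of that family. The three property columns ship
  as a CSV resource standardised to mean 0, sample SD 1 over the 20
  residues, and can be swapped by file.

## Feature compositions

Four published compositions are constructed by `featureComposition()`:
FC1 (2 AAC + 40 DPC + 22 PseAAC = 64), FC2 (the 12 structural
descriptors), FC3 (FC2 then the FC1 blocks = 76) and FC4 (9 structural —
all but tPSA, NRB, HBD — + 2 AAC + 10 DPC + 22 PseAAC = 43). The source
text quotes "73 descriptors" for FC3 while its own block enumeration
totals 12+2+40+22 = 76; the enumeration is implemented and the
discrepancy surfaced here rather than silently resolved.

## Dataset preprocessing

`preprocessDataset()` applies, in order: the 5–30 length filter; exact
duplicate removal (case-insensitive, first occurrence kept); and outlier
removal at |z| ≥ 3 per structural descriptor, computed with the sample
standard deviation on the length/duplicate survivors. A record is
removed if *any* of the 12 descriptors trips the threshold — the
conservative reading of "z-score ≥ 3 in peptide features"; whether the
original analysis used structural descriptors only or all features is
not stated, so the choice is isolated behind the `features` argument.
Zero-variance descriptors contribute z = 0. The filter report accounts
for every input record.

## The ensemble

Three probabilistic members are fitted on standardised features (scaler
fitted on training rows only; zero-variance columns get scale 1):

* **MLP** (`nnet`): single hidden layer, logistic activations, entropy
  loss. Default grid: size {5, 15, 30} × weight decay {1e-4, 1e-2},
  maxit 300. `nnet`'s full-batch BFGS makes wide layers prohibitively
  slow (a single size-100 fit on 600 × 43 standardised rows costs on
  the order of two minutes) while sizes 5–30 already separate the
  benchmark perfectly in under five seconds, so the grid was fixed at
  the small end once, before any accuracy thresholds were evaluated.
  A two-hidden-layer point cannot be expressed with `nnet` and was
  dropped rather than emulated.
* **GPC** (`kernlab::gausspr`): RBF kernel parameterised by length-scale
  ℓ ∈ {0.5, 1, 2, 5}, translated to kernel width σ = 1/(2ℓ²).
* **SVM** (`kernlab::ksvm`): RBF with C ∈ {0.1, 1, 10, 100} and
  γ ∈ {0.001, 0.01, 0.1, 1/d}. Platt probability calibration is paid
  only on the final refit; grid evaluation uses hard class predictions.

`kernlab` and `nnet` draw all randomness from the R RNG, which is what
makes the determinism contract achievable: every fit runs under a seed
derived deterministically from the framework seed, and refitting with
the same seed reproduces predictions exactly. (The common alternative
SVM backend calibrates probabilities with a C-level `rand()` stream that
R cannot seed, which is why it is not used here.)

Grid search is exhaustive, scored by stratified k-fold mean accuracy
(ties broken by grid order), with failed grid points recorded and
skipped. The ensemble probability is the unweighted mean of the three
member probabilities — no weight learning — and the label rule is CPP
iff the mean exceeds 0.5, with 0.5 itself mapped to non-CPP.

## Evaluation

`classificationMetrics()` derives Sn/Sp/Acc/F1/MCC from the confusion
matrix, with zero denominators reported as 0 with a warning. Published
tables in this area *truncate* to three decimals (an MCC of 0.8136
prints as 0.813); `truncateDecimals()` reproduces that convention, and
the acceptance tests verify every printed table row from its implied
integer confusion matrix. AUC uses the rank (Mann–Whitney) formulation
with ties counted one half, cross-checked in tests against trapezoidal
ROC integration. Cross-validation is stratified with a seeded shuffle —
stratification is not stated in the source but is required for balanced
folds at n = 600 — and refits the scaler and (by default) the entire
grid search inside each training fold, so nothing leaks from the
held-out fold. Whether the original analysis re-tuned per fold is not
stated; per-fold tuning is the leak-free default, and `tune = "reuse"`
provides the cheaper variant for parity experiments. The Kruskal–Wallis
H test delegates to `stats::kruskal.test` (tie-corrected, chi-square
approximation), with the all-identical-values edge case defined as
H = 0, p = 1.

## Chemical space

`descriptorProfile()` reports min/max/mean and percentiles with linear
interpolation (`quantile` type 7); the method name is recorded in the
report because the original percentile method is unstated.
`permeabilityRuleFlags()` evaluates three rule sets with the quoted
boundary semantics taken literally: Lipinski RO5 (MW ≤ 500, cLogP ≤ 5,
HBD ≤ 5, HBA ≤ 10, all inclusive, conjunction), Veber (NRB ≤ 10 and
tPSA ≤ 140 Å², inclusive) and the extended oral-bioavailability bounds
(NRB < 20 strict; −2 ≤ cLogP ≤ 10). Note that under the literal
conjunction *every* peptide of four or more residues fails RO5 on HBD
alone (a tetrapeptide backbone already donates six hydrogens), which is
precisely the point of the chemical-space analysis: peptides live
outside the small-molecule rules.

## Information analysis

Grouped importance uses an extremely-randomised-trees ensemble written
in the package: at each node, K = √d randomly chosen candidate features
receive one uniformly random cut-point each, and the largest Shannon
information gain wins. Per-feature importances (weighted entropy
decrease) are normalised per tree, averaged over 500 trees (seeded), and
summed within the four descriptor families. The in-package
implementation exists because the available R extra-trees backend scores
importance with Gini impurity rather than the entropy criterion; tests
cross-check that both agree on which feature carries a planted signal.
PCA standardises features first (unstated in the source; recorded
here), takes the top three components with a deterministic sign
convention (largest-magnitude loading positive), and reports explained
variance ratios plus a per-component Bhattacharyya coefficient between
the class-conditional projections. BC is computed on 20 shared
equal-width bins over the pooled range — the "normalised" BC of the
source analysis is not defined there, so the histogram construction and
bin count are recorded parameters.

## The synthetic benchmark

The generator emulates the *shape* of the curated training sets, not
their content: balanced classes, lengths uniform on [5, 30], positives
drawn from an Arg/Lys-enriched composition (sampling mass 0.45 on R+K)
with a rejection step enforcing NetC ≥ +2 and f[Arg]+f[Lys] ≥ 0.3 per
record; negatives uniform-composition with NetC ≤ +1. The class NetC
distributions are therefore disjoint at the decision margin by
construction — the benchmark is a *recovery* test (can the pipeline find
a planted, noiseless cationic signal?), not a claim of biological
realism. Real CPP data contain amphipathic and non-cationic penetrators,
chemically modified residues and label noise; passing the benchmark says
the machinery works, not that real-data accuracies transfer. Rejection
sampling is capped at 10⁴ attempts per record so infeasible
configurations fail fast, and duplicates are re-drawn so every emitted
set is unique.

Problem sizes used throughout the package's own checks: a 300/300
benchmark (seed 7) for pipeline recovery — tenfold cross-validation with
per-fold tuning, a permutation-null run with single-point grids (the
leakage check does not depend on tuning), and 500-tree importance runs —
and 30/30 subsets for unit-level behaviour. These sizes mirror the
600-record training scale of the original study while keeping every
suite runnable on a single CPU in minutes.

## Known limitations

* Chemically modified residues are out of scope; PDB inputs with
  non-standard codes require an explicit mapping (e.g. `MSE → M`).
* cLogP atom typing covers the peptide atom universe only; it is not a
  general small-molecule implementation.
* The published hyperparameter tables of the original framework are not
  in its main text, so the grids here are declared defaults, not
  recovered values; published dataset accuracies are consequently not
  reproduction targets (the curated datasets are not redistributable).
* The fractional-charge mode uses a fixed EMBOSS-style pKa set; no pKa
  prediction is attempted.
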