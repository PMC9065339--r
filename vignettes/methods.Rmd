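---
title: "Methods: binding-site labelling, network features and classifier evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site labelling, network features and classifier evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsite)
```

`drugsite` predicts which residues of a DNA-binding protein contact a
small-molecule drug. This vignette documents the model, its assumptions,
the tunable parameters, the numerical choices, and what the synthetic-data
machinery does and does not establish about real data.

## Geometric site labelling

The ground truth of the whole pipeline is geometric. Given a protein–ligand
complex, heteroatom entities are first *qualified* as ligands:

1. not a water (residue name HOH/WAT/DOD);
2. at least one ligand atom within the contact cutoff (6.5 Å) of a protein
   atom — an entity with no such contact cannot define a site;
3. no ligand–protein atom pair closer than the covalent cutoff (2.0 Å by
   default, a typical upper bound for a covalent bond) — covalently bound
   groups are modifications, not reversible binders.

A residue is then a **binding-site residue** when any of its atoms lies
within 6.5 Å of any atom of a qualified ligand. Three conventions matter
and are tested explicitly:

- the comparison is **inclusive** (a pair at exactly 6.5 Å counts as
  contact), the standard reading of a distance criterion;
- **all atoms** participate, hydrogens included when present — the
  criterion names no element filter;
- a structure with several qualified ligands labels a residue positive if
  *any* ligand contacts it (per-ligand labels combined by logical OR).

Molecular weight is not restricted by default (no published bounds exist
for the "small molecule" clause); `qualify_ligands(mw_range =)` provides an
optional window. Solvent exposure is operationalised entirely by rule 2 —
no solvent-accessible-surface computation is attempted, since the contact
rule is the operative restatement. Alternate locations keep the
highest-occupancy conformer (ties → altloc "A"); only model 1 of
multi-model files is read. Nucleic-acid chains and other non-protein
polymers are excluded from labelling. Parsing is delegated to bio3d
(PDB and mmCIF).

## The residue interaction network

Residues are nodes; an undirected, unweighted edge joins residues whose
C-alpha–C-alpha distance is ≤ 7.0 Å (the common C-alpha RIN convention;
an any-atom mode at 5.0 Å is available). The minimum sequence separation
defaults to 1, i.e. backbone neighbours are connected — the network is
meant to capture the fold, and chain adjacency is part of it. Residues on
different chains face no sequence constraint. A residue without a C-alpha
under C-alpha mode is kept as an isolated node with a warning (configurable
to a hard error) so the node set always equals the residue set.

Seven per-residue descriptors are computed, in a fixed column order:

| column | definition |
|---|---|
| `betweenness` | Σ over pairs {s,t}∌u of σ_st(u)/σ_st, unweighted shortest paths (Brandes) |
| `closeness` | (n_c − 1) / Σ dist(u,v) over u's component of size n_c |
| `eigenvector` | component of the principal adjacency eigenvector, L2-normalised |
| `eccentricity` | max hop distance to any reachable node |
| `degree` | incident edge count |
| `clustering` | edges among neighbours / (d(d−1)/2); 0 when d < 2 |
| `avg_neighbor_degree` | mean degree over neighbours; 0 when isolated |

Numerical and degenerate-input choices:

- **Disconnected graphs.** Closeness uses the component-local form
  (n_c − 1)/Σdist — the natural restriction of the connected-graph formula
  that avoids infinite distances. Eccentricity of an isolated node is 0.
  Betweenness pairs in different components contribute nothing.
- **Eigenvector centrality** is computed per connected component by power
  iteration on the shifted matrix A + I (identical eigenvectors, strictly
  positive spectrum — this removes the oscillation a bipartite component
  would cause), uniform start, tolerance 1e-10, at most 1000 iterations,
  then the spectrally dominant component carries the vector and every other
  node scores 0. When two components tie exactly (isomorphic components do
  occur in sparse graphs), the component containing the earliest node in
  residue order receives the mass; the tie rule is deterministic and
  mirrored by the test oracle.
- Betweenness sums **unordered** pairs and never counts endpoints as
  interior nodes.
- Raw (unnormalised) metric values are emitted; min–max normalisation is a
  separate, explicit analysis step (below), so modelling and presentation
  scales stay distinct.

Every metric is checked against independent brute-force oracles
(adjacency-power path counting, dense eigendecomposition) on random graphs,
and against igraph where it implements the same quantity.

## Sequence profile features

PSI-BLAST ASCII PSSMs (`-out_ascii_pssm`) are parsed directly: the 20
log-odds columns and the query sequence are kept; the weighted-percentage
block and footer statistics are ignored, since the per-position log-odds
row is the 20-dimensional feature. Scores are used **raw** by default —
the minimal assumption — with an optional elementwise logistic squash
1/(1+e^(−P)) into (0,1) for scale-sensitive learners. Single rows (no
window around the position) keep the feature count at 20.

Profile rows are keyed to structure residues by exact positional match
when the sequences agree, otherwise by Smith–Waterman local alignment
(Biostrings, BLOSUM62); an aligned identity below 95% is treated as a
wrong-profile error rather than silently mapping mismatched rows.

## Dataset assembly, split and balancing

The labelled design matrix inner-joins the three per-residue sources on
(structure, chain, number, insertion code); residues missing any source
are dropped with a reported count. Columns are fixed — 20 PSSM columns in
alphabetical residue order, then the 7 network columns — so models are
portable across runs.

Complexes (not residues) are split into training and independent test
sets by uniform sampling without replacement under an explicit seed.
Under-sampling retains every positive and draws round(ratio × positives)
negatives without replacement, 1:1 by default; it is applied to training
data only, so independent evaluation keeps the natural imbalance (about
an order of magnitude more non-binding residues). All randomness flows
from integer seeds.

## Classifier and evaluation

Three learners share one interface: gradient-boosted trees (xgboost; 500
trees, depth 6, learning rate 0.1, single-threaded for determinism), an
RBF-kernel SVM (cost 1, gamma = 1/p) and a CART tree (Gini, cp = 0). No
published hyperparameters exist for this problem, so the defaults are the
libraries' conventional settings, recorded in the model configuration and
overridable. Scores are probabilities; the hard label is score ≥ 0.5, ties
positive.

Evaluation reports ACC, SEN, PRE and MCC in their standard confusion-matrix
forms. Specificity deserves a note: the printed formula in the source
literature for this pipeline divides by TN + FN, which duplicates no known
metric and collides with the precision definition alongside it; the
standard TN/(TN+FP) is therefore the default, with `spe_literal = TRUE`
reproducing the printed variant. Ratios with zero denominators are NaN
with a warning — never a silent 0. AUC uses the Mann–Whitney rank form
(average ranks for ties), which equals the trapezoidal ROC area.

Cross-validation pools out-of-fold predictions, so each row is scored
exactly once and the metrics describe a single pooled confusion matrix.
Folds are stratified by class at residue level; `group_by_complex = TRUE`
assigns whole structures to folds for users worried about same-complex
leakage (residue-level is the default, matching how the balanced table is
usually cross-validated). k = n reduces exactly to the jackknife. A fold
that loses a class is re-drawn once, then errors.

## Distribution and property analyses

`normalize_features()` rescales each feature by min–max over the pooled
(both-class) values — pooled rather than per structure, so the two classes
are compared on one scale and the normalised range is exactly [0,1].
`class_distribution_compare()` reports the class mean difference and a
Wilcoxon rank-sum test (normal approximation with tie correction); no
multiple-testing correction by default, with `p_adjust` available.
`frequency_histogram()` bins pooled values into equal-width bins and
normalises per class. `hqi_proportions()` classifies each binding-site
residue HIGH when its amino-acid index value is at or above the unweighted
mean of the index over the 20 standard amino acids (ties HIGH, matching
"above average" with a documented boundary rule); index tables are user
input, since the HQI1–HQI8 values live in external compilations.

## Synthetic data: what it shows and what it does not

The generators close the loop on every stage without any download:

- `make_complex()` writes a C-alpha-only chain on an ideal helix (1.5 Å
  rise, 100° twist, 2.3 Å radius), an extended chain (3.8 Å spacing) or a
  self-avoiding random coil, and places one ligand atom per requested
  contact residue at 6.5 − offset Å (default offset 1.0) while verifying
  every non-contact residue stays beyond 7.0 Å; infeasible requests error
  rather than silently shifting the ground truth. Extra ligand atoms are
  parked far from the chain. Files are byte-deterministic per seed.
- `make_pssm()` emits a parseable profile with integer log-odds in
  [−10, 12].
- `make_classification_set()` plants a standardised mean shift
  (`effect_size`, in units of the noise SD) in chosen feature columns —
  by default the 7 network columns, emulating the empirical pattern that
  binding sites show elevated betweenness and closeness.

Test and acceptance problem sizes are the package's own choices: 100
random graphs of 10–50 nodes for the metric oracles, 50 helix complexes
for extraction, 500/500 rows for the signalled classification check,
100/100 rows per seed across 50 seeds for the null check (a pooled-AUC
mean within 0.5 ± 0.05), 30/30 rows for the jackknife equivalence.

Passing these checks establishes the *mechanics* — labelling, graph
algebra, bookkeeping, resampling, evaluation — not biological validity:
synthetic backbones have no side chains, rotamers or energetics, the
planted Gaussian class signal is far cleaner than real evolutionary or
topological signal, and no claim about predictive performance on real
DNA-binding protein–drug complexes follows from them. Real-data
performance depends on the curated complex set and on profiles searched
against a current sequence database, both of which are inputs to this
package, not products of it.

## Known limitations

- The contact rule for the network (C-alpha, 7.0 Å) is a convention;
  energy-weighted or atom-contact networks are out of scope.
- PSI-BLAST itself is not run; profile quality is the caller's
  responsibility.
- `read_structure()` trusts the file's chain/residue numbering; no
  renumbering or gap repair is attempted beyond the alignment fallback in
  the PSSM mapping.
- The SVM's probability outputs come from Platt scaling inside e1071 and
  are only seed-deterministic, not cross-platform bit-stable; the
  gradient-boosted learner is the deterministic reference.
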