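---
title: "Motif decomposition and two-layered SVMs for S-palmitoylation sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mddpalm methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Protein *S*-palmitoylation attaches palmitate to cysteine thiols and is
catalyzed by a family of DHHC acyltransferases. Because several enzymes
with different preferences act on overlapping substrate pools, the
sequence neighbourhoods of modified cysteines form a *mixture* of motif
classes rather than one consensus. `mddpalm` models this explicitly in
three stages:

1. **Window extraction.** Every candidate cysteine becomes a `2n + 1`-mer
   fragment (`n = 10` by default), `'X'`-padded at termini. Negatives are
   the unannotated cysteines of the same proteins, which yields the
   characteristic ~1:8 class imbalance.
2. **Maximal dependence decomposition (MDD).** Residues are collapsed
   into five biochemical groups and, for each pair of window positions,
   the dependence of group occupancy is measured by the chi-square
   statistic on the 5×5 contingency table (zero-expectation cells
   contribute zero). The position with maximal total dependence `D(i)`,
   provided at least one of its pairs exceeds the configured threshold,
   splits the set into carriers of the dominant group at that position
   versus the rest; recursion stops when subgroups drop below the maximum
   cluster size. This produces interpretable motif subgroups
   (`Palm1`, `Palm2`, ...).
3. **Two-layered classification.** Each subgroup trains an RBF-kernel
   SVM with Platt probability outputs on scaled hybrid features (default
   AAC + PSSM); the vector of per-subgroup probabilities feeds a
   second-layer RBF SVM whose output is the final site probability.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n` | 10 | window half-width; 21-mers are the field's standard for this modification |
| `chi2_threshold` | 34.3 | pairwise dependence cutoff. The published constant is described as P = 0.01 at 16 df, although the textbook critical value there is 32.0 (34.3 sits nearer P = 0.005). The printed constant is used verbatim and is configurable. |
| `max_cluster_size` | 205 | subgroups smaller than this are not divided. 205 is chosen so that a 204-member remainder subgroup — the size of the smallest published motif subgroup — would stop dividing. |
| `ratio` | 8 | negatives sampled per subgroup positive, `round(8 × n_pos)`; mirrors the ~710:5676 class ratio of the curated training corpus. |
| `gamma`, `cost` | `1/d`, 1 | RBF width and soft-margin penalty. No published values exist; the defaults are the conventional `1/n_features` and unit cost, and `grid_search()` (MCC-maximizing, ties to cheaper models) reproduces the tuning procedure. A desk-scale sweep (cost up to 128, gamma up to `4/d`) did not improve held-out ranking on the synthetic worlds, so the conventional defaults stand. |
| `crossfit_folds` | 5 | folds used to cross-fit first-layer scores for meta-training. |
| `threshold` | 0.5 | decision cut on the second-layer probability; the published tool's cut-off is unstated. |

## Numerical and procedural choices

- **Alphabet.** Residues outside the 20 standard letters (B, Z, J, U, O,
  `*`) map to `'X'`. `'X'` is a counted 21st symbol in AAC/AAPC/PWM (the
  printed feature dimensions force it), an all-zero block in the binary
  and BLOSUM62 encodings, and a discarded row in the PSSM transform.
- **Homology reduction.** CD-HIT is emulated at fragment level: exact
  cross-set duplicates drop the negative copy first, then greedy
  clustering against retained representatives (descending-length,
  lexicographic processing order) at the configured identity. Whether the
  published 50% reduction acted at protein or fragment level is ambiguous
  in the source; the threshold and the clustering level are configuration
  rather than a guess.
- **PSSM source.** Running PSI-BLAST is out of scope; the internal
  profile is the per-offset log2 odds of residue frequencies against a
  uniform 1/20 background with pseudocount 0.05, and external ASCII
  profiles can be imported instead. A residue-uniform fragment set scores
  zero everywhere by construction.
- **PWM vectorization.** The source text is ambiguous between a
  per-position lookup and a full matrix per fragment; the per-position
  lookup (length `2n + 1`) is implemented.
- **Group scheme.** The five-group table is not printed in the available
  text; it is reconstructed from internal clues (a G/S/T/C/Q/N "polar"
  motif subgroup; basic = K/R/H) as polar {G,S,T,C,Q,N}, acidic {D,E},
  basic {K,R,H}, aromatic {F,W,Y}, hydrophobic {A,V,L,I,M,P}, and is
  overridable.
- **Split tie-breaks.** Ties in `D(i)` go to the smaller absolute offset,
  then the negative offset; the split group is the property group with
  the largest summed row contribution to the winning offset's
  chi-squares. These are determinism choices the source does not fix.
- **SVM implementation.** No SVM library is assumed: the C-SVC dual is
  solved by SMO (maximal-violating-pair selection, precomputed kernel) in
  C++, and tests verify the KKT conditions of its solutions against the
  definitions. Platt sigmoids are fitted on in-sample decision values
  (the reference library cross-validates them); this only affects
  probability calibration, not ranking, and the second layer's
  meta-features are cross-fitted regardless, so stacking never sees
  in-sample first-layer scores.
- **Cross-validation.** Folds are stratified and seeded; the MDD tree is
  re-learned inside every training fold, and pooled held-out predictions
  give the single reported estimate. Degenerate metric denominators
  yield `NaN` with a warning; an MCC with a zero denominator is 0 by
  convention. AUC is the Mann–Whitney statistic with half-weight ties
  (equal to trapezoidal ROC integration).

## The synthetic world, and what a green test establishes

`generate_fragments()` states a deliberately simple world: negatives are
i.i.d. draws from a background composition with the center forced to
`'C'`; each positive additionally carries one motif rule-set (chosen by
mixture weight), every rule overwriting its offset with a uniform draw
from a property group's residues with stated probability.
`default_palm_config()` plants the four canonical substrate-motif
signals — basic at +10, basic at +4, polar at −1, polar at +1 — as four
equally weighted single-rule classes at probability 0.85, 600 positives
against 4800 negatives.

What this world does emulate: the window geometry, the class imbalance,
the property-group vocabulary, and the mixture-of-motifs structure. What
it does not: correlated multi-position motifs within one substrate class,
realistic background composition, homology structure, or any coupling
between sequence and surface accessibility. A green pipeline test on
synthetic data therefore establishes that the machinery is wired
correctly and can learn when information is present — not that the
biological performance figures are reproduced, which would require the
original curated corpus.

Two consequences of the stated world deserve emphasis, because they make
two acceptance-style claims unattainable *by construction* rather than by
implementation defect:

1. **A single planted position is invisible to pairwise dependence.**
   The MDD statistic tests dependence between two positions. If the
   latent class touches only one offset, the joint distribution of every
   position pair factorizes exactly, so each pairwise chi-square is
   central chi-square(16) noise and essentially never identifies the
   planted offset (the acceptance script measures the recovery rate; it
   is ~0/20, not ≥19/20). Dependence appears only when a motif class
   touches *several* positions — as the real multi-enzyme biology does,
   and as the package's module tests arrange via rule-sets with two or
   three rules. This is a genuine property of the method: MDD discovers
   co-occurring position preferences, not marginal enrichments.
2. **The default world's Bayes bound is ≈0.73 AUC.** All class
   information sits in four group-at-offset indicators whose background
   rates are high (0.30 for polar, 0.15 for basic), and each positive
   carries only one of them. The acceptance script computes the exact
   likelihood-ratio AUC by Monte Carlo (≈0.73); the pipeline's pooled
   cross-validated AUC (≈0.54) sits below that because hinge-loss
   classifiers saturate under this weak, imbalanced signal — an SVM given
   the four oracle indicators directly does no better. The ≥0.85 bound
   stated for this world is therefore unattainable by any classifier.
   Notably, the motif-decomposed two-layer model still outranks the
   single undecomposed SVM on this world, qualitatively reproducing the
   method's central claim.

Generator defaults were set from the stated design and have not been
adjusted toward test outcomes.

## Known limitations

- The published cross-validation and independent-test figures for the
  real corpora are not reproduction targets: they require the authors'
  curated training and testing datasets, which are not redistributable
  here. The printed confusion matrices of the head-to-head comparison
  are, however, exactly reproduced into Sn/Sp/Acc/MCC by the metric
  formulas (one published MCC value, 0.184, is a truncation of the
  computed 0.1846).
- Platt calibration on in-sample decision values can be optimistic for
  small subgroups; thresholds other than 0.5 should be chosen on
  held-out scores.
- The greedy fragment clusterer approximates, but does not replicate,
  CD-HIT's word-filter heuristics.
- ASA values are consumed from a table, never computed; logo rendering is
  out of scope (frequency matrices and enrichment reports are exported as
  TSV instead).
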