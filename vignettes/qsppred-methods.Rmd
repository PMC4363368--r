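---
title: "Methods: models, encodings and design choices in qsppred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, encodings and design choices in qsppred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The classification model

Quorum sensing peptides (QSPs) are short signalling peptides of
Gram-positive bacteria. They differ from generic short peptides in
composition (aromatic enrichment: Trp, Tyr, Phe; depletion of Asp/Glu),
in terminal residue preferences (Ser near the N-terminus, Phe and Cys near
the C-terminus), and in bulk physicochemical properties (short length,
low molecular weight, positive GRAVY tendency). These regularities are the
signal the classifier exploits.

The model is a binary C-classification support vector machine with an RBF
kernel, `k(x, x') = exp(-gamma * ||x - x'||^2)`, fitted by libsvm (through
e1071). Because an SVM needs fixed-length inputs, each variable-length
peptide is first mapped to a fixed-length feature vector by one of the
encodings below, and every feature is min-max scaled to [0, 1] with ranges
learned **on training data only** — scaling ranges learned on a full data
set would leak held-out information into cross-validation, and RBF
distances over mixed-scale hybrid vectors are meaningless without a common
scale.

### Encodings

| scheme | dimension | definition |
|---|---|---|
| AAC | 20 | residue fractions, alphabetical order ACDEFGHIKLMNPQRSTVWY |
| DPC | 400 | overlapping dipeptide fractions, row-major in the same order |
| N5Bin / C5Bin | 100 each | one-hot blocks for the first / last five residues |
| N5C5Bin | 200 | N blocks then C blocks |
| Physico | k (default 10) | per-peptide mean of k AAindex per-residue scales |
| hybrid | sum | concatenation of components in listed order |

Three encoding decisions were genuinely open and were resolved as follows.

* **Physico aggregation.** A 20-value AAindex scale must be reduced to one
  number per peptide. We use the arithmetic mean over residues: it is the
  simplest statistic that is invariant to peptide length, and it makes the
  feature exactly composition-determined (scramble-invariant), which is
  the behaviour the other composition features share.
* **Terminal windows shorter than the peptide.** For peptides shorter than
  10 residues the N- and C-windows of N5C5Bin overlap; we allow the
  overlap rather than padding, because padding would introduce a 21st
  "blank" symbol that no other part of the feature system recognises.
  Peptides shorter than a single window are rejected as unscorable (with
  a per-record reason, never dropped silently).
* **AAindex screening criterion.** `select_top_indices()` ranks each
  complete AAindex scale by the 10-fold cross-validated accuracy of a
  one-dimensional RBF SVM (cost 1, gamma 1) using one fixed fold
  partition, with ties broken by accession string so the ranking is fully
  deterministic. 13 of the 544 bundled indices contain missing residue
  values and are excluded from screening. The twelve secondary-structure
  heavy accessions reported to discriminate QSPs are available as a named
  preset (`qsp_physico_preset()`), but the package re-derives its own
  top-k list from the data by default.

### Model selection and evaluation

Cross-validation is stratified (equal class counts per fold) and seeded.
The (C, gamma) grid defaults to `C = 2^(-5), 2^(-3), ..., 2^15` and
`gamma = 2^(-15), ..., 2^3` in log-2 steps of 2; the selected pair
maximizes pooled CV accuracy at decision threshold 0, with ties broken by
higher MCC, then smaller C, then smaller gamma (preferring the smoother
model). Threshold-dependent metrics are sensitivity, specificity and
accuracy in percent and the MCC on [-1, 1]; when an MCC marginal is zero
the value is reported as 0 with an explicit `mcc_undefined` flag rather
than erroring, so batch runs survive degenerate folds. The
threshold-independent AUC is computed as the Mann-Whitney pair statistic
(ties count one half), which equals trapezoidal integration of the ROC
curve. The default decision threshold is 0; `optimize_threshold()` is
provided for users who prefer an accuracy-maximizing cut, but reported
numbers use threshold 0 unless stated.

### Grouped cross-validation for scrambled negatives

One negative-set strategy scrambles each positive peptide, preserving its
residue multiset. A peptide and its scramble then have *identical*
composition features under *opposite* labels. If the two land in different
CV folds, the model memorizes the training twin's label and systematically
predicts the held-out twin wrong: measured on the synthetic sets, accuracy
falls to 6-29% depending on (C, gamma) — an anti-learning leakage
artifact, not chance behaviour. `qsp_cv()` therefore accepts an explicit
`fold_id` so derived peptides can share a fold with their parent (grouped
cross-validation). Under grouping both twins receive the same score from
the same model, every pair contributes exactly one correct prediction, and
composition-feature accuracy sits at the chance level the scramble design
intends. The acceptance script and tests use grouped folds for this
control.

## Property calculators

All calculators follow ProtParam conventions so that results are
comparable with the ExPASy tool:

* **Aromaticity** — fraction of Phe, Tyr, Trp.
* **Instability index** — `II = (10/L) * sum DIWV(x_i, x_{i+1})` over the
  published Guruprasad 20x20 dipeptide weight table; II < 40 is classed
  stable. II is order-sensitive by construction (the tests carry an
  explicit witness).
* **GRAVY** — mean Kyte-Doolittle hydropathy (1982 scale, bundled
  verbatim).
* **Molecular weight** — sum of *average* residue masses plus one water
  (18.01524 Da); average rather than monoisotopic masses match ProtParam.
* **Isoelectric point** — the root of the Henderson-Hasselbalch net-charge
  function over both termini and the D, E, C, Y, H, K, R side chains with
  the Bjellqvist pK set, including ProtParam's residue-specific terminal
  pK overrides. The charge is strictly decreasing in pH and is positive at
  pH 0 and negative at pH 14 (both termini are always titratable), so
  bisection on (0, 14) converges unconditionally; iteration stops when
  |charge| < 1e-4 (or the bracket narrows below 1e-8 pH units). One
  consequence of the terminal overrides is that pI is
  composition-determined only up to the identity of the two terminal
  residues; the test suite asserts scramble-invariance on sequences whose
  residues carry no terminal override.

Degenerate inputs: empty sequences are rejected everywhere;
single-residue peptides have no dipeptides, so II is reported as `NA` in
the set-level profile and is an error when requested directly.

## Motif scanning and evaluation

Patterns are bracket-class expressions (literal residues and `[..]`
alternatives), parsed into per-position allowed-residue sets and compiled
to a lookahead regular expression so that **overlapping matches are all
reported** with 0-based offsets. Evaluation counts at the peptide level: a
peptide is motif-positive if any pattern matches anywhere, giving
`PPV = TP/(TP+FP)` and `coverage = 100*TP/(TP+FN)`. Peptide-level
counting is the only unit under which PPV is bounded by 1 for realistic
set sizes; occurrence counts are nevertheless reported per pattern, since
"number of motifs" is ambiguous between sequences and occurrences. When no
peptide matches at all, PPV is undefined and flagged rather than silently
zero. Motif *discovery* is out of scope: the nine bundled patterns ship as
a plain pattern file and users may supply their own in the same notation.

## Enrichment analyses

Positional enrichment compares residue frequencies at the first and last
`n` positions (C-terminal positions indexed negatively, -1 = last residue,
to avoid ambiguity across variable lengths) with a two-sided
two-proportion z-test with continuity correction at alpha = 0.05. A
proportion test is the statistically appropriate choice for per-position
residue frequencies; no multiplicity correction is applied by default
(matching common two-sample-logo practice), with a Bonferroni option for
conservative users. Fold changes against a background composition follow
the "depleted by x-fold" convention: every fold is >= 1 and carries a
direction, and the bundled background is the overall Swiss-Prot
composition (release 2015_03 statistics), replaceable by any user table.

## The synthetic generator

`generate_fixture()` emulates the reported statistical structure of
curated QSP / non-QSP sets so the whole pipeline is testable without
external data:

* **Lengths** are truncated-geometric on 5-30 (positives, target mean
  11.5) and 7-77 (negatives, target mean 31.8); the success probability is
  solved numerically from the target mean at construction.
* **Positive composition** is the Swiss-Prot background reweighted by the
  reported QSP fold changes (Cys 3.48x, Trp 3.11x, Phe 2.74x, Asn 1.79x,
  Tyr 1.51x enriched; Asp, Glu, His, Val, Arg, Lys depleted), which
  analytically implies a mean aromaticity near 0.18 against the
  background's 0.08.
* **Terminal preferences** are per-position multiplicative weights (Ser at
  N-positions 1, 2, 3, 5; Gly at 1, 2; Asn/Pro on the N side; Phe at
  C-positions 1, 3, 5; Cys near the C-terminus; Lys/Gln/Trp on the C
  side). Because these windows cover most of a typical 11-mer, naive
  weighting would distort the overall composition; the generator therefore
  calibrates its interior composition by fixed-point iteration so that the
  *expected pooled composition* equals the fold-change target, and the
  terminal weights only redistribute residues within peptides.
* **Negatives** are sampled i.i.d. from the background composition.

What the generator does *not* emulate: real QSP phylogenetic structure and
family redundancy, cyclic or post-translationally modified peptides
(databases store linearized sequences), the charge-residue detail that
fixes real isoelectric points, and any dipeptide-order signal beyond what
terminal weighting induces. Consequently, passing tests demonstrate that
the pipeline recovers planted compositional/positional structure and that
the formulas are correct — not that the classifier generalizes to real
peptides; accuracies measured on synthetic sets characterize the synthetic
task. `make_separable()` is intentionally trivial (one class carries
>= 40% Trp, the other none) and is used only as a positive control and
for permutation nulls.

## Problem sizes and determinism

The test suite and acceptance script run everything at the study's set
sizes (220 + 220 generated peptides; 200p + 200n training split; n = 400
controls) but with reduced (C, gamma) grids — 9-25 combinations rather
than the full 110 — which keeps a complete run to a few minutes while
exercising the same code paths; the full default grid is available to
users. Every stochastic step (generation, splitting, fold assignment,
scrambling, permutation) is seeded, and seeded operations restore the
caller's RNG state, so whole-pipeline runs are bit-reproducible given the
same seed.

## Known limitations

* Predicted secondary-structure fractions (helix/sheet/coil panels of the
  original analysis) are not computed: they require an external structure
  predictor. AAindex secondary-structure propensity scales partially stand
  in through the Physico encoding.
* BLAST-similarity baselines and external peptide-family datasets
  (antiviral, antimicrobial, cell-penetrating) are out of scope; the
  fold-change machinery accepts any user-supplied background instead.
* The SVM decision values are uncalibrated margins, not probabilities.
* Exact duplicate removal is string identity only; no similarity-based
  redundancy reduction is provided.
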