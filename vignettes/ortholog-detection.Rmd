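---
title: "Supervised pairwise ortholog detection with orthopair"
author: "orthopair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised pairwise ortholog detection with orthopair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopair)
```

## The problem

Orthologs are homologous proteins in two species that descend from a
speciation event; paralogs descend from duplications. Between two annotated
proteomes of a few thousand proteins each, the candidate space is the full
cross product — tens of millions of pairs — of which only a few thousand
are curated orthologs, an imbalance ratio (negatives per positive) on the
order of $10^4$. Classical unsupervised detectors such as reciprocal best
hits (RBH) rely on alignment score alone and are easily misled by
duplicates retained after whole-genome duplication ("traps": the paralog
looks like the best partner) and by remote orthologs in the twilight zone
(below 30% pairwise identity). `orthopair` instead treats pairwise ortholog
detection as supervised binary classification over a rich pairwise feature
vector, with explicit imbalance management, and evaluates with metrics that
remain informative at extreme imbalance.

## The 29 pairwise features

Each candidate pair $(x, y)$ receives 29 named similarity features,
partitioned into 5 alignment-based and 24 alignment-free columns
(`featureColumnNames()`).

**Alignment-based.** `nw` and `sw` are the optimal global
(Needleman–Wunsch) and local (Smith–Waterman) affine-gap alignment scores
(BLOSUM62, gap open 10, gap extend 0.5 by default; the scheme is
configurable and the paper-of-record for such pipelines rarely states it —
these are community defaults for yeast-scale divergence). `profile3/5/7`
compare the mean standardized Kyte–Doolittle hydropathy of the two sides of
every gap-free aligned run through sliding windows of width 3, 5, 7:
$1 - \overline{|\bar h_x - \bar h_y|}/D$ with $D$ the range of the
standardized scale, clipped to $[0,1]$, and 0 when no run reaches the
window width. The exact profile formula of the original pipeline is
published only in an earlier paper of its authors; this window-mean form is
our documented reconstruction of it. `length` is
$\min(|x|,|y|)/\max(|x|,|y|)$ — listed with the alignment-free block since
it needs no alignment.

**Alignment-free.** Each protein is first mapped to a descriptor vector per
family; the pair feature is then the significance-gated Pearson similarity

$$S(x, y) = \begin{cases} r(\mathrm{AAX}, \mathrm{AAY}) & p \le 0.05 \\
0 & p > 0.05, \end{cases}$$

where $p$ is the two-sided p-value of $t = r\sqrt{(n-2)/(1-r^2)}$ on
$n - 2$ degrees of freedom ($n$ the descriptor dimension). "No significant
evidence" and "no correlation" are deliberately conflated to 0; significant
negative correlations are kept as negative similarities. The families:

* `aac` — amino acid composition (dim 20);
* `pseaa3/4/10` — Chou's type-1 pseudo amino acid composition at
  $\lambda = 3, 4, 10$, weight $w = 0.05$ (Chou's published default; the
  source pipeline is silent), correlation factors built from standardized
  hydrophobicity, hydrophilicity and side-chain mass;
* `2-mers`, `3-mers` — contiguous word frequencies (dims 400, 8000);
* `2-mers_dc1..3`, `3-mers_dc1..3` — spaced words through binary
  match/don't-care patterns (`101`, `1001`, `10001`; `1101`+`1011`;
  `10011`+`10101`+`11001`; `100011`+`110001`+`101001`+`100101`), multiple
  patterns pooled into one vector with summed window totals;
* `Auto_Geary`, `Auto_Moran`, `Auto_Total` — Geary, Moran and (for the
  total) also Moreau–Broto autocorrelation of seven standardized
  physicochemical scales at lags 1–30 (the PROFEAT-style attribute set and
  maxlag convention; the pipeline does not state them), the concatenated
  total rescaled to unit maximum absolute value;
* `CTD`, `CTD_C`, `CTD_T`, `CTD_D` — composition/transition/distribution
  over three-class encodings of seven attributes (dims 147/21/21/105);
* `QSO_w01_maxlag30`, `QSOCN_maxlag30` — quasi-sequence-order with
  coupling numbers $\tau_d = \sum_i d(R_i, R_{i+d})^2$ up to lag 30,
  $w = 0.1$, under two residue-pair distance matrices (next section);
* `fcm`, `nandy` — spectral moments $\mu_k = \mathrm{tr}(A^k)/n$,
  $k = 1..15$, of row-normalized adjacency matrices of two graphical
  sequence maps.

Finally every feature column is normalized by its maximum absolute value
over the pair set being featurized, so columns peak at 1 (or are all
zero). Train and test matrices are normalized independently, mirroring
per-dataset normalization; this is a documented choice where joint
normalization would also have been defensible.

### Degenerate inputs and numerical choices

A descriptor with an unmet precondition (protein shorter than a maxlag or
$\lambda$, shorter than a spaced pattern) is undefined for that protein;
affected pairs get similarity 0 — consistent with the gate's
"no evidence → 0" semantics — and are logged when `verbose = TRUE`.
Zero-variance descriptor vectors give 0. A physicochemical scale that is
constant along a sequence zeroes that attribute's autocorrelation entries.
An all-zero feature column passes through max-normalization unchanged.
Pair enumeration is lexicographic in (proteome-1 order, proteome-2 order),
making feature tables byte-for-byte reproducible.

### Property tables and distance matrices

The seven per-residue scales (hydrophobicity, normalized van der Waals
volume, polarity, polarizability, charge, helix propensity, solvent
accessibility) are published standard scales, standardized to mean 0 and
sd 1 over the 20 residues before use (`aaPropertyTable()`). The two QSO
distance matrices are built in-package from per-residue scales
(`aaDistanceMatrix()`): the Schneider–Wrede-style matrix as the RMS
difference of standardized hydrophobicity/hydrophilicity/side-chain mass,
and the Grantham matrix from Grantham's composition/polarity/volume
formula with $\rho$ scaled to a mean off-diagonal distance of 100. Both
are symmetric with zero diagonal — the properties the pipeline contracts
actually rely on; no test or headline number depends on their exact
entries.

The two graphical maps are likewise documented reconstructions of
constructions published only inside their original programs, sharing a
4-class residue grouping (nonpolar / polar-uncharged / acidic / basic):
the Cartesian (Nandy-style) map walks east/west/north/south per class and
connects consecutively visited lattice points; the four-colour map lays
the sequence row-wise into a $\lceil\sqrt n\rceil$-wide rectangle and
connects grid neighbours of equal class. Moments are divided by the node
count so proteins of different lengths stay comparable.

## Imbalance management and classifiers

With IR $\sim 10^2$–$10^4$, training needs resampling:

* **RUS** samples majority (non-ortholog) rows without replacement down to
  the minority count — balanced, never duplicates a row;
* **ROS** samples minority rows with replacement until the minority count
  reaches `sizePct`% of the majority (100% balances, 130% overshoots;
  resampling sizes above 100% can further help the minority class) — never
  drops a row.

Both are deterministic given their seed. The classifier contract
(`trainOrthologModel` / `predictOrthologs`) maps the tree hyperparameters
of the large-scale learners this design mirrors — 100 trees, maximum depth
5, minimum 2 instances per node, minimum information gain 0, Gini or
entropy impurity — onto `ranger` (random forest) and `rpart` (decision
tree). `ranger` supports Gini but not entropy for classification, so
entropy requests fall back to Gini with a warning (decision trees honour
both); histogram-style `MaxBins` discretization has no analogue in exact
tree learners and is not reproduced. `svm`, `logreg` and `naive_bayes`
honour the same contract as optional extras. Prediction enforces the
training feature order and errors on the first offending column.
`featureImportance` reports mean-decrease-in-impurity importances
normalized to sum to 1.

## Evaluation

`evaluateOrthologs` reports TP/TN/FP/FN, TPR, TNR, G-Mean
$\sqrt{TPR \cdot TNR}$ and the single-operating-point balanced accuracy
$(TPR + TNR)/2$, here called point-AUC: hard 0/1 predictions admit no
threshold sweep, and a degenerate all-negative classifier correctly shows
G-Mean 0 with point-AUC 0.5. `twilightTpPct` restricts to true ortholog
pairs below 30% global-alignment identity (global identity is the
conservative choice for full-length orthology) and reports the recovered
percentage. `rbhBaseline` implements the unsupervised reference: mutual
unique best Smith–Waterman partners, ties voiding the best hit, with an
optional raw-score threshold standing in for the usual E-value filter
(E-value statistics are out of scope).

## The synthetic proteome-pair generator

`generateProteomePair` is a first-class, tested module, not a test
convenience. A spec (`syntheticPairSpec`) plants

* `nOrthologs` one-to-one pairs: a common ancestor (uniform residues,
  length 80–150) independently mutated on each branch at `mutationRate`
  per site, substitutions drawn from a BLOSUM62-conditional distribution
  $p(b \mid a) \propto 2^{B(a,b)/2}$ so alignment scores degrade the way
  diverging homologs actually do, plus a ±10% length jitter (no explicit
  indel process — the jitter keeps end gaps exercised; an undiverged copy
  is left untouched so zero-rate orthologs are 100% identical);
* background proteins: independent uniform-random sequences;
* `nTraps` paralog traps: a duplicated ancestor whose extra-diverged copy
  (`trapDivergence` additional substitution) lands in proteome 2, labelled
  negative.

The defaults — 15 orthologs, 35 background proteins per side, 5 traps,
mutation rate 0.2 — define the desk-scale study condition used by the
tests and the acceptance script: a 55×55 = 3,025-pair universe with
IR ≈ 200. These sizes keep a full 20-seed end-to-end suite in the
single-digit minutes on one CPU while leaving each seed enough positives
(15) for a stable G-Mean. `twilightSpec` bisects the mutation rate until
the median planted-ortholog identity reaches a target of 25% (safely below
the 30% threshold), which identity's monotone decrease in the rate makes
well-posed.

What the generator does *not* emulate: real indel processes (only length
jitter), domain architecture and repeats, compositional bias of real
proteomes, many-to-many ortholog groups, and synteny (deliberately
excluded — its omission is known not to drive classification performance
in this setting). Passing tests therefore demonstrate the pipeline's
mechanics and its supervised-vs-RBH ordering under controlled divergence,
not yeast-scale absolute numbers: the published benchmark figures
(G-Mean ≈ 0.9977 at IR ≈ 10⁴) require full proteomes, curated gold
groups and ~3×10⁷ alignments, which is an optional workflow, not a test
surface. The exact arithmetic that *is* reproduced at desk scale is the
benchmark imbalance-ratio table recomputed from its printed class counts.

## Worked example

```{r example, eval = FALSE}
gp <- generateProteomePair(syntheticPairSpec(seed = 1))
train <- buildFeatureMatrix(gp$p1, gp$p2, labels = gp$gold)
fit <- trainOrthologModel(train, algorithm = "random_forest",
                          resampling = resamplingSpec("RUS", seed = 1))
gp2 <- generateProteomePair(syntheticPairSpec(seed = 2))
test <- buildFeatureMatrix(gp2$p1, gp2$p2, labels = gp2$gold)
report <- evaluateOrthologs(predictOrthologs(fit, test),
                            pairLabels(test), percentIdentities(test))
report
```

## Known limitations

* The profile, graphical-map and distance-matrix constructions are
  documented reconstructions where the original definitions live in
  unavailable software; their contracts, not their exact values, are load
  bearing.
* Raw alignment scores are max-normalized without bit-scaling; with a
  fixed scoring scheme the two differ only by a column-wise constant.
* No E-value model; the RBH threshold is a raw score.
* Desk-scale defaults trade variance for runtime: per-seed G-Mean at 15
  positives moves in steps of 1/15.
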