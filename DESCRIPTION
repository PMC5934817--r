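Package: orthopair
Title: Supervised Pairwise Ortholog Detection from Annotated Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects ortholog pairs between two annotated proteomes with
    imbalance-aware supervised learning. Each candidate protein pair is
    described by 29 similarity features: alignment-based measures (global
    and local alignment scores, physicochemical profiles of gap-free
    aligned regions, protein length ratio) and alignment-free measures
    obtained as significance-gated Pearson correlations between
    per-protein descriptor vectors (amino acid and pseudo amino acid
    composition, k-mer and spaced-word frequencies, Geary/Moran/
    Moreau-Broto autocorrelation, composition-transition-distribution,
    quasi-sequence-order, and spectral moments of graphical sequence
    maps). Random over- and under-sampling handle the extreme
    ortholog/non-ortholog class imbalance before training random forest
    or decision tree classifiers, which are evaluated with
    imbalance-appropriate metrics (TPR, TNR, G-Mean, balanced accuracy)
    including recovery of remote orthologs in the twilight zone, against
    a reciprocal-best-hits baseline. A deterministic synthetic
    proteome-pair generator with planted orthologs and duplicated
    paralog traps supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ranger,
    rpart
Suggests:
    e1071,
    withr,
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Alignment, Classification
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'property-tables.R'
    'AllClasses.R'
    'AllGenerics.R'
    'proteome-io.R'
    'descriptors.R'
    'align.R'
    'pair-similarity.R'
    'imbalance.R'
    'evaluation.R'
    'synthetic.R'
    'orthopair-package.R'
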