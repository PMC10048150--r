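Package: synthscreen
Title: Predicting DNA Synthesis Difficulty from Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a DNA sequence will be easy or hard to
    synthesize de novo. Computes a fixed, versioned 426-feature descriptor
    per sequence (nucleotide composition, k-mer counts, accumulated
    nucleotide frequencies, electron-ion interaction potential spectra,
    repeat and hairpin statistics, sliding-window GC content,
    nearest-neighbor melting temperatures, motif counts, and restriction
    site counts), reduces it by variance, label-correlation, and
    genetic-algorithm feature selection over a 74-configuration experiment
    grid, and trains a budgeted ensemble classifier over a portfolio of
    base learners with greedy forward ensemble selection. Includes binary
    classification metrics (F1, Matthews correlation coefficient, Cohen's
    kappa), permutation importance, partial dependence, a synthetic
    labeled-sequence generator with planted difficulty determinants, and a
    command-line pipeline from FASTA to prediction report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ranger,
    xgboost,
    rpart,
    e1071,
    class,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'enzymes.R'
    'AllClasses.R'
    'manifest.R'
    'features-windows.R'
    'features-composition.R'
    'features-repeats.R'
    'features-restriction.R'
    'extract.R'
    'selection.R'
    'ga.R'
    'modeling.R'
    'evaluate.R'
    'synthetic.R'
    'cli.R'
    'metrics.R'
    'seqio.R'
    'synthscreen-package.R'
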