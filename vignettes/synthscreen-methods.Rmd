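---
title: "Predicting DNA synthesis difficulty: models, parameters, and design choices"
author: "synthscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA synthesis difficulty: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthscreen)
```

## The problem

De novo gene synthesis assembles a target sequence from chemically
synthesized oligonucleotides. Whether that assembly succeeds cleanly
depends on the sequence itself: stretches of locally skewed GC content
stall chain extension and bias annealing, direct and tandem repeats cause
mispriming, inverted repeats fold into hairpins that block assembly, and
windows with a low melting temperature anneal weakly. synthscreen treats
difficulty prediction as supervised binary classification: a sequence is
labeled `HARD` (difficult to synthesize; the positive class throughout) or
`EASY`, and a classifier is trained on labeled examples to predict the
label of new sequences from a fixed numerical descriptor.

The pipeline is: FASTA input → validation → a 426-feature descriptor per
sequence → min–max normalization fitted on the training split → optional
feature selection (variance filter, label-correlation filter,
genetic-algorithm wrapper, alone or composed) → a budgeted automated model
search with greedy ensembling → evaluation by F1, Matthews correlation
coefficient (MCC) and Cohen's kappa (CK) → a frozen, deployable model
bundle.

## The 426-feature descriptor

`featureManifest()` pins the descriptor: 426 named features in 11 groups
(composition 84, accumulated nucleotide frequency 22, electron–ion
interaction potential 40, k-mer 112, repeat 15, GC 8, melting temperature
3, secondary structure 7, specific motifs 20, restriction sites 114,
length 1). The group totals are the method's contract; the internal
definition of each group is this package's own pinned, versioned choice,
constrained by the group sizes and by the individually named features
(`dGC`, `GC_short_l`, `GC_long_l`, `Tm_low`, the ApaI site). Matrices,
normalizers, masks and model bundles all carry the manifest version and
refuse to mix versions.

Conventions shared by all groups:

* Window features slide by 1 bp. A sequence shorter than a window
  contributes a single whole-sequence window. Window counts use strict
  inequalities (e.g. `GC_long_l` counts 100 bp windows with GC **< 0.30**).
* The long-window low-GC bound is 30%; the high bound is symmetric at
  70%. The 20 bp short-window bounds are 40%/60%, conventional
  synthesis-screening values.
* All internal arithmetic is 0-based half-open; user-facing positions
  (error messages, hairpin coordinates) are 1-based.

Group-specific notes:

* **Composition** — mono/di/trinucleotide frequencies, each k-mer count
  divided by `L - k + 1`, lexicographic order.
* **ANF** — the accumulated nucleotide frequency signal `a(i)` (frequency
  of the base at `i` within the prefix up to `i`) sampled at 20 evenly
  spaced relative positions plus its mean and sample variance.
* **EIIP** — the electron–ion interaction potential mapping (A 0.1260,
  C 0.1340, G 0.0806, T 0.1335); mean, sample variance, and the
  periodogram of the mean-removed signal (power `|X_k|² / L` at frequency
  `k/L`) aggregated into 38 equal-width bins over (0, 0.5] cycles/bp.
* **k-mer** — raw di/trinucleotide counts plus trinucleotide frequencies
  collapsed with their reverse complements (32 canonical pairs).
* **Repeat** — the manifest lists 15 statistics; one (the overall longest
  homopolymer run, the maximum of the four per-base runs) was added by
  this package to complete the printed group size, since only 14 distinct
  statistics were otherwise pinned. Tandem runs report the total length
  of the longest perfectly periodic stretch with unit ≥ 2 bp and at least
  two full copies; a trailing partial copy counts toward the length, and
  primitivity is not required (a period-2 run inside a homopolymer
  counts as a tandem, but not as a *dinucleotide* tandem, which requires
  two distinct bases).
* **Tm** — nearest-neighbor thermodynamics with the unified parameter set,
  at 50 mM Na⁺ (entropic salt correction `0.368 (n−1) ln[Na⁺]`) and
  0.5 µM total strand concentration, with the symmetry correction for
  self-complementary duplexes. `Tm_low`/`Tm_high` are the extremes over
  20 bp windows; `Tm_global` is the whole-sequence duplex Tm. Because
  duplex stability grows with length, `Tm_global` generally exceeds
  `Tm_high` for long sequences — the three features are three views of
  annealing strength, not an envelope.
* **Structure** — hairpins are detected combinatorially, not by free-energy
  folding: a hairpin is a locally maximal stem–loop with an exact
  reverse-complement stem of ≥ 6 bp and a loop of 3–48 bp. "Locally
  maximal" means the stem is extended outward as far as it pairs and the
  loop is as small as the pairing and the 3 bp minimum allow, so each
  physical stem–loop is counted exactly once. A thermodynamic folding
  backend could be plugged in behind the same seven statistics, but exact
  complementarity keeps the feature deterministic and fast.
* **Restriction** — exact-match counts of the recognition sites of a fixed
  panel of 114 common commercial enzymes (`restrictionEnzymes()`), all
  with unambiguous A/C/G/T recognition sequences so a count is a plain
  substring count. Non-palindromic sites pool forward-strand occurrences
  of the site and of its reverse complement, making the count
  strand-symmetric. ApaI (GGGCCC) is in the panel; the other 113 members
  are this package's choice.

`extractFeatures()` is pure and deterministic; under 1 s for sequences up
to a few kb. Sequences below 100 bp are handled best-effort with a
warning; below 40 bp the spectral group is undefined and extraction is an
error.

## Normalization

Min–max normalization maps each feature to `(x − min)/(max − min)` with
the extrema taken from the **training split only**, and is frozen into the
model bundle. Fitting the scaler on the full dataset would leak test-set
information; the training-only variant is the leak-free reading of the
protocol. Constant features map to 0. Unseen values may leave [0, 1] and
are deliberately not clipped — tree learners are unaffected and linear
learners should see the true magnitude.

## Feature selection and the 74-experiment grid

Three reduction methods are provided, composed cheapest-first
(variance → correlation → GA), each stage operating on the survivors of
the previous:

* **Variance filter** — keep features with sample variance ≥ cutoff
  (0.01, 0.02, 0.03, 0.04) on the normalized training matrix.
* **Label-correlation filter** — keep features with |Pearson r| against
  the 0/1 label (HARD = 1) ≥ cutoff (0.1, 0.15, 0.2, 0.3). This is
  feature-versus-label (point-biserial) correlation, not pairwise
  redundancy pruning; with cutoffs in the 0.1–0.3 range that is the
  standard reading.
* **Genetic algorithm** — a wrapper over binary feature masks: population
  50, tournament selection (size 3), one-point crossover (p = 0.8),
  per-bit mutation 1/p, elitism 1. "Rounds" count fitness evaluations,
  not generations. Fitness is the mean 3-fold cross-validated F1 of a
  small reference random forest on the masked features minus a parsimony
  penalty of 10⁻⁴ per kept feature, so ties resolve toward smaller sets.
  Fold assignment is fixed per run and fitness values are memoized by
  mask (cache hits still count toward the round budget), which makes
  10⁴–10⁵-round runs cheap once the population converges. The reference
  forest defaults to 25 trees — large enough to rank masks reliably on
  desk-scale data, small enough that a 10,000-round run takes seconds;
  `gaConfig(refTrees=)` exposes it.

`buildExperimentGrid()` enumerates all 74 combinations: 10 single-method
configurations (4 correlation + 4 variance + 2 GA), 32 pairs
(4×4 + 4×2 + 4×2) and 32 triples (4×4×2). `runExperiments()` scores each
configuration with the repeat protocol below and reports selected-feature
counts and mean/sd of F1, MCC and CK; ties between configurations resolve
by higher mean F1, then fewer features, then grid order.

## Model training

`trainModel()` implements the automated-search contract natively rather
than depending on any particular AutoML product: a fixed 16-candidate
portfolio over eight base-learner families — random forest, extremely
randomized trees, boosted stumps (depth-1 gradient boosting), Gaussian
naive Bayes, decision tree, k-nearest neighbors, linear SVM (with Platt
scaling fitted on the training decision values, which keeps probability
estimates deterministic), and linear discriminant analysis. Candidates
are fitted on an internal 75% stratified fit split and scored on the
remaining 25% validation fold; greedy forward ensemble selection with
replacement over the validation probabilities chooses the members and
weights (selection counts, normalized); the chosen members are refitted
on the full training matrix.

The budget is denominated in candidate evaluations (`iterCap`), which is
exactly reproducible; `budgetSeconds` adds an optional wall-clock stop for
production runs, documented as non-reproducible. Given a seed and
`iterCap` the whole bundle is deterministic. The decision threshold is
0.5 with ties to `HARD` — when the evidence is exactly balanced, the
actionable call is the cautious one. LDA and naive Bayes drop features
that are constant within both classes (they are undefined there); kNN
caps k at the training size.

## Evaluation

Metrics come from the confusion matrix with `HARD` positive:
`F1 = 2TP/(2TP+FP+FN)`,
`MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and
`CK = (Po − Pe)/(1 − Pe)` with `Po = (TP+TN)/N` and
`Pe = ((TP+FN)(TP+FP)+(TN+FP)(TN+FN))/N²`. Degenerate denominators are
defined as 0 with a warning, so repeated evaluation never aborts on an
all-one-class fold. The test suite checks all three formulas against
independent recomputation (F1 via precision/recall, MCC as the Pearson
correlation of the 0/1 vectors, kappa via `e1071::classAgreement`) on
every confusion matrix with N ≤ 12.

`repeatEvaluate()` isolates the randomness of the model search: the 3:1
split (seed 0 by default; 1076 items split 807/269) and the feature
selection stay frozen while the search seed varies across (by default) 10
cycles; mean, sd, min and max per metric are reported.
`permutationImportance()` measures the mean F1 drop over independent
permutations of each selected feature; `partialDependence()` overwrites a
feature column with grid values over its observed raw range and averages
the predicted probabilities.

The package ships a ten-gene *E. coli* MG1655 benchmark
(`validationGenes()`) with experimentally determined synthesis outcomes
and the difficulty calls of this method and of the Synthesis Success
Calculator baseline; scoring them reproduces the worked example (8/10
vs 5/10 correct, accuracy 0.80 vs 0.50).

## The synthetic-data generator

`generateDataset()` emulates labeled training sets without any download.
Background bases are i.i.d. at a target GC (default 0.5; no Markov
structure — the simplest background sufficient for testing planted-signal
recovery). `HARD` sequences carry one planted determinant chosen at
random: a 120 bp patch at 5% GC (driving `dGC` far above background), a
direct repeat of 25 bp with a 30 bp spacer, or an inverted repeat with a
12 bp stem and 8 bp loop. The difficulty rule is a threshold rule on true
determinants: HARD iff `dGC` > 0.35, or longest direct repeat ≥ 20 bp, or
at least one strong (stem ≥ 10) hairpin. Each generated sequence is
checked against the rule *as measured by the extractors* and regenerated
(bounded retries) if measurement and intended class disagree, so at zero
label noise the labels are perfectly predictable from extracted features
by construction. The thresholds sit well above the fluctuations of a
500 bp i.i.d. background (dGC typically ≤ 0.3, longest repeat ≈ 12–14,
strong hairpins ≈ 0.02 expected), so `EASY` rejections are rare.

What the generator does **not** emulate: codon structure, genomic repeat
families, compositional autocorrelation, chemistry-specific error modes.
Passing the planted-recovery tests therefore demonstrates that the
pipeline recovers the determinants it models, not that it attains any
particular accuracy on real synthesis orders.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in minutes on one core: a 400-sequence ×
500 bp synthetic dataset (3:1 split, noise 0) for end-to-end recovery and
the 10-repeat protocol; 100 random sequences of 200–1000 bp for
brute-force oracle equivalence of the combinatorial extractors; 120 × 55
matrices with 5 jointly informative features for 10,000-round GA recovery
over 5 seeds. Jointly informative means the label is a threshold on the
*mean* of the five planted columns: each column alone is weakly
correlated, so the parsimony-penalized GA must keep all five — planting
five interchangeable (individually sufficient) columns would instead make
dropping four of them the optimal solution.

Other pinned numerical choices: sample (n−1) variance everywhere; the
periodogram bin boundary `ceiling(76·f − 10⁻⁹)` guards the exact-boundary
frequencies; Platt scaling uses an unpenalized logistic fit; the split
keeps `floor(n·testFraction)` items for testing.

## Known limitations

* The internal definitions of the descriptor groups are this package's
  pinned choices; another implementation matching the same group totals
  could differ feature-by-feature, so trained bundles are only
  transferable at matching manifest versions.
* Hairpin detection ignores G·U-style wobble, bulges and thermodynamics.
* The restriction panel is fixed at 114 unambiguous-site enzymes;
  degenerate recognition sites (IUPAC codes) are out of scope.
* The ensemble search is a bounded portfolio, not a full hyperparameter
  optimizer; with `budgetSeconds` the result depends on machine speed and
  is not reproducible (use `iterCap` for reproducibility).
* Class imbalance is handled only implicitly (stratified folds, F1);
  heavily imbalanced training sets may need resampling upstream.
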