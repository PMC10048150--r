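#' @include modeling.R
NULL

#' Repeat-evaluation protocol
#'
#' Runs `nRepeats` independent train/evaluate cycles with a fixed
#' train/test split: the split and (optional) feature selection stay
#' frozen, only the model-search seed varies per repeat, isolating the
#' randomness of the automated search. For each metric (F1, MCC, Cohen's
#' kappa) the mean, standard deviation, minimum and maximum over the
#' repeats are reported.
#'
#' @param matrix Raw (unnormalized) [FeatureMatrix] of the full dataset.
#' @param labels EASY/HARD labels for the rows.
#' @param mask Optional [SelectionMask] restricting the features.
#' @param nRepeats Number of cycles (>= 2; the standard protocol uses 10).
#' @param iterCap Model-search iteration cap per cycle.
#' @param seed Base seed; cycle r uses model seed `seed + r`.
#' @param split A [splitSpec()] (default: 3:1 with seed 0).
#' @return List: `summary` (data.frame metric/mean/sd/min/max), `runs`
#'   (nRepeats x 3 matrix of per-cycle metrics), `split` sizes.
#' @export
repeatEvaluate <- function(matrix, labels, mask = NULL, nRepeats = 10L,
                           iterCap = 16L, seed = 0L, split = splitSpec()) {
  stopifnot(is(matrix, "FeatureMatrix"), nRepeats >= 2L)
  ids <- rownames(matrix@values)
  labels <- .align_labels(labels, ids)
  part <- splitDataset(length(ids), split, labels = labels)
  tr_ids <- ids[part$train]; te_ids <- ids[part$test]
  sub <- function(which_ids) new("FeatureMatrix",
                                 values = matrix@values[which_ids, , drop = FALSE],
                                 manifestVersion = matrix@manifestVersion)
  norm <- fitNormalizer(sub(tr_ids))
  tr <- applyNormalizer(norm, sub(tr_ids))
  te <- applyNormalizer(norm, sub(te_ids))
  if (!is.null(mask)) {
    tr <- .mask_matrix(tr, mask)
    te <- .mask_matrix(te, mask)
  }
  runs <- t(vapply(seq_len(nRepeats), function(r) {
    bundle <- trainModel(tr, labels[tr_ids], iterCap = iterCap,
                         seed = seed + r, normalizer = norm, mask = mask)
    pred <- .predict_matrix(bundle, te)
    m <- metricsReport(labels[te_ids], pred$label)
    suppressWarnings(m[c("F1", "MCC", "CK")])
  }, numeric(3)))
  colnames(runs) <- c("F1", "MCC", "CK")
  summary <- data.frame(
    metric = colnames(runs),
    mean = colMeans(runs),
    sd = apply(runs, 2, sd),
    min = apply(runs, 2, min),
    max = apply(runs, 2, max),
    row.names = NULL)
  list(summary = summary, runs = runs,
       split = c(train = length(tr_ids), test = length(te_ids)))
}

#' Permutation feature importance
#'
#' For each feature the trained ensemble uses, the evaluation-set F1 is
#' recomputed after independently permuting that feature's column
#' `nShuffles` times; the importance is the mean decrease relative to the
#' unpermuted F1 (higher = the model depends more on the feature).
#'
#' @param bundle A [ModelBundle].
#' @param matrix Raw [FeatureMatrix] of the evaluation set (all 426
#'   columns).
#' @param labels EASY/HARD labels for the rows.
#' @param nShuffles Permutations per feature (>= 1).
#' @param seed RNG seed.
#' @return data.frame sorted by decreasing importance: `feature`,
#'   `importance` (mean F1 decrease), `sd`, `rank`.
#' @export
permutationImportance <- function(bundle, matrix, labels, nShuffles = 10L,
                                  seed = 0L) {
  stopifnot(is(bundle, "ModelBundle"), is(matrix, "FeatureMatrix"))
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  labels <- .align_labels(labels, rownames(matrix@values))
  masked <- .mask_matrix(applyNormalizer(bundle@normalizer, matrix),
                         bundle@mask)
  X <- masked@values
  truth <- as.character(labels)
  base_f1 <- {
    p <- .bundle_prob(bundle, X)
    suppressWarnings(f1Score(confusionCounts(
      truth, ifelse(p >= 0.5, "HARD", "EASY"))))
  }
  imp <- .with_seed(seed, {
    t(vapply(colnames(X), function(f) {
      drops <- vapply(seq_len(nShuffles), function(s) {
        Xp <- X
        Xp[, f] <- X[sample.int(nrow(X)), f]
        p <- .bundle_prob(bundle, Xp)
        base_f1 - suppressWarnings(f1Score(confusionCounts(
          truth, ifelse(p >= 0.5, "HARD", "EASY"))))
      }, numeric(1))
      c(mean(drops), sd(drops))
    }, numeric(2)))
  })
  out <- data.frame(feature = colnames(X), importance = imp[, 1],
                    sd = imp[, 2], row.names = NULL)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Partial dependence of the ensemble on one feature
#'
#' Standard partial-dependence curve: the selected feature's column is
#' overwritten with each grid value in turn (grid spanning the observed raw
#' range) and the predicted HARD probabilities are averaged over the
#' evaluation rows.
#'
#' @param bundle A [ModelBundle].
#' @param matrix Raw [FeatureMatrix] of the evaluation set.
#' @param feature Name of a feature the bundle's mask keeps.
#' @param gridPoints Number of grid values (default 20).
#' @return data.frame with columns `value` (raw feature value) and
#'   `hard_probability` (mean prediction).
#' @export
partialDependence <- function(bundle, matrix, feature, gridPoints = 20L) {
  stopifnot(is(bundle, "ModelBundle"), is(matrix, "FeatureMatrix"),
            gridPoints >= 2L)
  feats <- keptFeatures(bundle@mask)
  if (!feature %in% feats)
    stop("feature '", feature, "' is not in the bundle's selected set")
  raw_col <- matrix@values[, feature]
  grid <- seq(min(raw_col), max(raw_col), length.out = gridPoints)
  masked <- .mask_matrix(applyNormalizer(bundle@normalizer, matrix),
                         bundle@mask)
  X <- masked@values
  mn <- bundle@normalizer@mins[[feature]]
  mx <- bundle@normalizer@maxs[[feature]]
  norm_grid <- if (mx > mn) (grid - mn) / (mx - mn) else rep(0, gridPoints)
  prob <- vapply(norm_grid, function(g) {
    Xg <- X
    Xg[, feature] <- g
    mean(.bundle_prob(bundle, Xg))
  }, numeric(1))
  data.frame(value = grid, hard_probability = prob)
}
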