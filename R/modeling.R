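#' @include ga.R
NULL

#' Train/test split specification
#'
#' @param testFraction Fraction of items assigned to the test partition
#'   (default 0.25, i.e. a 3:1 split).
#' @param seed Split seed (default 0); the partition is deterministic
#'   given the seed.
#' @return A list of class `splitSpec`.
#' @export
splitSpec <- function(testFraction = 0.25, seed = 0L) {
  stopifnot(testFraction > 0, testFraction < 1)
  structure(list(testFraction = testFraction, seed = as.integer(seed)),
            class = "splitSpec")
}

#' Deterministic train/test partition
#'
#' Splits `n` items (or a [SeqDataset]) into train and test index sets:
#' the test set holds `floor(n * testFraction)` items drawn uniformly under
#' the split seed. Splitting 1076 items at the default 0.25 gives the
#' 807/269 partition used throughout. When labels are supplied and a
#' partition misses a class, a warning is emitted.
#'
#' @param n Number of items, or a [SeqDataset].
#' @param spec A [splitSpec()].
#' @param labels Optional EASY/HARD labels (positional) for the class-
#'   coverage check.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' lengths(splitDataset(1076))  # 807 / 269
#' @export
splitDataset <- function(n, spec = splitSpec(), labels = NULL) {
  if (is(n, "SeqDataset")) {
    if (is.null(labels)) labels <- sequenceLabels(n)
    n <- length(n@sequences)
  }
  stopifnot(n >= 4L)
  n_test <- floor(n * spec$testFraction)
  if (n_test < 1L || n_test >= n)
    stop("testFraction ", spec$testFraction, " yields an empty partition")
  test <- .with_seed(spec$seed, sort(sample.int(n, n_test)))
  train <- setdiff(seq_len(n), test)
  if (!is.null(labels)) {
    labels <- toupper(as.character(labels))
    if (length(unique(labels[train])) < 2L ||
        length(unique(labels[test])) < 2L)
      warning("a partition does not contain both classes; ",
              "consider a different split seed")
  }
  list(train = train, test = test)
}

# --- base-learner portfolio ----------------------------------------------

# each entry: family name + hyperparameters; fit/predict dispatch below
.portfolio <- function() {
  list(
    list(family = "random_forest", num.trees = 200L),
    list(family = "random_forest", num.trees = 500L),
    list(family = "extra_trees", num.trees = 200L),
    list(family = "extra_trees", num.trees = 500L),
    list(family = "boosted_stumps", nrounds = 100L, eta = 0.3),
    list(family = "boosted_stumps", nrounds = 300L, eta = 0.1),
    list(family = "naive_bayes", laplace = 0),
    list(family = "naive_bayes", laplace = 1),
    list(family = "decision_tree", cp = 0.01),
    list(family = "decision_tree", cp = 0.001),
    list(family = "knn", k = 5L),
    list(family = "knn", k = 11L),
    list(family = "knn", k = 21L),
    list(family = "linear_svm", cost = 0.1),
    list(family = "linear_svm", cost = 1),
    list(family = "lda")
  )
}

# columns with nonzero within-group variance (LDA and Gaussian naive
# Bayes cannot use features constant inside both classes)
.varying_columns <- function(X, y01) {
  ok <- vapply(seq_len(ncol(X)), function(j) {
    any(vapply(unique(y01), function(g)
      var(X[y01 == g, j]) > 1e-12, logical(1)))
  }, logical(1))
  colnames(X)[ok]
}

.fit_learner <- function(cand, X, y01, seed) {
  fam <- cand$family
  fit <- switch(fam,
    random_forest = ranger::ranger(
      x = X, y = factor(y01), num.trees = cand$num.trees,
      probability = TRUE, num.threads = 1L, seed = seed),
    extra_trees = ranger::ranger(
      x = X, y = factor(y01), num.trees = cand$num.trees,
      splitrule = "extratrees", probability = TRUE, num.threads = 1L,
      seed = seed),
    boosted_stumps = {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(max_depth = 1L, eta = cand$eta,
                      objective = "binary:logistic", nthread = 1L),
        data = xgboost::xgb.DMatrix(X, label = y01),
        nrounds = cand$nrounds)
    },
    naive_bayes = {
      keep <- .varying_columns(X, y01)
      if (!length(keep)) list(prior = mean(y01))
      else list(nb = e1071::naiveBayes(x = as.data.frame(X[, keep, drop = FALSE]),
                                       y = factor(y01),
                                       laplace = cand$laplace),
                keep = keep)
    },
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = factor(y01), X),
      method = "class", cp = cand$cp),
    knn = list(X = X, y = factor(y01), k = min(cand$k, nrow(X))),
    linear_svm = {
      sv <- e1071::svm(x = X, y = factor(y01), kernel = "linear",
                       cost = cand$cost, scale = FALSE)
      dv <- attr(predict(sv, X, decision.values = TRUE),
                 "decision.values")[, 1]
      # orient decision values toward class 1 and Platt-scale them
      platt <- suppressWarnings(
        glm(y01 ~ dv, family = binomial()))
      list(svm = sv, platt = platt)
    },
    lda = {
      keep <- .varying_columns(X, y01)
      if (!length(keep)) list(prior = mean(y01))
      else suppressWarnings(
        list(lda = MASS::lda(x = X[, keep, drop = FALSE],
                             grouping = factor(y01)),
             keep = keep))
    },
    stop("unknown learner family: ", fam))
  c(cand, list(fit = fit))
}

# probability of the positive (HARD) class for each row of X
.learner_prob <- function(learner, X) {
  fit <- learner$fit
  p <- switch(learner$family,
    random_forest = ,
    extra_trees = predict(fit, data = X, num.threads = 1L)$predictions[, "1"],
    boosted_stumps = predict(fit, xgboost::xgb.DMatrix(X)),
    naive_bayes = {
      if (!is.null(fit$prior)) rep(fit$prior, nrow(X))
      else predict(fit$nb, as.data.frame(X[, fit$keep, drop = FALSE]),
                   type = "raw")[, "1"]
    },
    decision_tree = predict(fit, data.frame(X), type = "prob")[, "1"],
    knn = {
      pr <- class::knn(train = fit$X, test = X, cl = fit$y, k = fit$k,
                       prob = TRUE, use.all = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    linear_svm = {
      dv <- attr(predict(fit$svm, X, decision.values = TRUE),
                 "decision.values")[, 1]
      as.numeric(predict(fit$platt, data.frame(dv = dv),
                         type = "response"))
    },
    lda = {
      if (!is.null(fit$prior)) rep(fit$prior, nrow(X))
      else predict(fit$lda, X[, fit$keep, drop = FALSE])$posterior[, "1"]
    },
    stop("unknown learner family: ", learner$family))
  unname(p)
}

# greedy forward ensemble selection with replacement (Caruana-style):
# repeatedly add the model whose inclusion maximizes validation F1 of the
# weight-averaged probabilities
.greedy_ensemble <- function(val_probs, y_val, max_members = 10L) {
  n_models <- ncol(val_probs)
  counts <- integer(n_models)
  cur_sum <- numeric(nrow(val_probs))
  best_sel <- NULL
  best_f1 <- -Inf
  for (step in seq_len(max_members)) {
    f1s <- vapply(seq_len(n_models), function(m) {
      p <- (cur_sum + val_probs[, m]) / step
      pred <- ifelse(p >= 0.5, "HARD", "EASY")
      suppressWarnings(f1Score(confusionCounts(
        ifelse(y_val == 1, "HARD", "EASY"), pred)))
    }, numeric(1))
    m_best <- which.max(f1s)
    cur_sum <- cur_sum + val_probs[, m_best]
    counts[m_best] <- counts[m_best] + 1L
    if (f1s[m_best] > best_f1) {
      best_f1 <- f1s[m_best]
      best_sel <- counts
    }
  }
  best_sel / sum(best_sel)
}

#' Train the ensemble classifier under a search budget
#'
#' Automated model search over a fixed portfolio of eight base-learner
#' families (random forest, extremely randomized trees, boosted stumps,
#' naive Bayes, decision tree, k-nearest neighbors, linear SVM with Platt
#' scaling, linear discriminant analysis). Candidates are fitted on an
#' internal 75% fit split and scored on the remaining 25% validation fold;
#' greedy forward ensemble selection (with replacement) over the validation
#' probabilities picks the ensemble and its weights; the selected members
#' are then refitted on the full training matrix.
#'
#' The budget is denominated in candidate evaluations (`iterCap`), which is
#' reproducible; `budgetSeconds` adds an optional non-reproducible
#' wall-clock stop for production runs. Given a seed and `iterCap` the
#' result is deterministic.
#'
#' @param matrix Normalized (and optionally masked) training
#'   [FeatureMatrix].
#' @param labels EASY/HARD labels for the rows; both classes required.
#' @param iterCap Maximum candidate evaluations (default: one pass over the
#'   16-candidate portfolio).
#' @param budgetSeconds Optional wall-clock cap; search stops after the
#'   current candidate when exceeded.
#' @param seed RNG seed for the internal split and stochastic learners.
#' @param normalizer,mask Optional [Normalizer] / [SelectionMask] to freeze
#'   into the bundle (required for [predictDifficulty()] on raw sequences).
#' @return A [ModelBundle].
#' @export
trainModel <- function(matrix, labels, iterCap = 16L, budgetSeconds = NULL,
                       seed = 0L, normalizer = NULL, mask = NULL) {
  stopifnot(is(matrix, "FeatureMatrix"))
  if (iterCap < 1L) stop("budget too small: iterCap must be >= 1")
  X <- matrix@values
  y <- .align_labels(labels, rownames(X))
  y01 <- as.integer(y == "HARD")
  if (length(unique(y01)) < 2L)
    stop("training labels contain a single class")
  t0 <- Sys.time()

  bundle_parts <- .with_seed(seed, {
    fold <- .strat_folds(y01, 4L)          # fold 1 = validation (25%)
    val <- fold == 1L
    port <- .portfolio()
    order_idx <- rep_len(sample.int(length(port)), iterCap)
    fitted <- list()
    val_probs <- NULL
    for (i in seq_along(order_idx)) {
      cand <- port[[order_idx[i]]]
      lr <- .fit_learner(cand, X[!val, , drop = FALSE], y01[!val],
                         seed = seed + i)
      pv <- .learner_prob(lr, X[val, , drop = FALSE])
      fitted[[length(fitted) + 1L]] <- cand
      val_probs <- cbind(val_probs, pv)
      if (!is.null(budgetSeconds) &&
          as.numeric(Sys.time() - t0, units = "secs") > budgetSeconds)
        break
    }
    w <- .greedy_ensemble(val_probs, y01[val])
    sel <- which(w > 0)
    # refit selected members on the full training matrix
    learners <- lapply(sel, function(m)
      .fit_learner(fitted[[m]], X, y01, seed = seed + m))
    list(learners = learners, weights = w[sel] / sum(w[sel]))
  })

  new("ModelBundle",
      learners = bundle_parts$learners,
      weights = bundle_parts$weights,
      normalizer = if (is.null(normalizer))
        fitNormalizer(matrix) else normalizer,
      mask = if (is.null(mask))
        .make_mask(matrix, colnames(X), "all", NA) else mask,
      manifestVersion = matrix@manifestVersion,
      metadata = list(seed = seed, iterCap = iterCap,
                      budgetSeconds = budgetSeconds,
                      trainedAt = format(Sys.time(), tz = "UTC"),
                      nTrain = nrow(X)))
}

# weight-averaged HARD probability on a masked, normalized matrix
.bundle_prob <- function(bundle, X) {
  probs <- vapply(bundle@learners, function(l) .learner_prob(l, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1L)
  as.numeric(probs %*% bundle@weights)
}

# predictions from an already masked+normalized FeatureMatrix
.predict_matrix <- function(bundle, matrix) {
  X <- matrix@values
  p <- .bundle_prob(bundle, X)
  data.frame(id = rownames(X),
             label = ifelse(p >= 0.5, "HARD", "EASY"),
             hard_probability = p,
             stringsAsFactors = FALSE)
}

#' Predict synthesis difficulty for sequences
#'
#' Applies the full deployment path of a trained bundle to validated
#' sequences: feature extraction, the frozen normalizer, the frozen
#' selection mask, then the weight-averaged ensemble probability with a
#' 0.5 decision threshold (a probability of exactly 0.5 is called HARD;
#' ties go to the positive class). A sequence that fails extraction gets a
#' per-record error entry without affecting the others.
#'
#' @param bundle A [ModelBundle].
#' @param sequences Named `DNAStringSet` (or [SeqDataset]) of validated
#'   sequences.
#' @return data.frame in input order: `id`, `label` (EASY/HARD or NA on
#'   failure), `hard_probability`, `error` (NA or message), then one column
#'   per selected feature with its raw (unnormalized) value.
#' @export
predictDifficulty <- function(bundle, sequences) {
  stopifnot(is(bundle, "ModelBundle"))
  if (is(sequences, "SeqDataset")) sequences <- sequences@sequences
  if (!identical(bundle@manifestVersion, MANIFEST_VERSION))
    stop("bundle manifest version ", bundle@manifestVersion,
         " does not match this package (", MANIFEST_VERSION, ")")
  chr <- as.character(sequences)
  ids <- names(sequences)
  feats <- keptFeatures(bundle@mask)
  rows <- lapply(seq_along(chr), function(i) {
    fv <- tryCatch(extractFeatures(chr[i]), error = function(e) e)
    if (inherits(fv, "error"))
      return(list(raw = rep(NA_real_, length(feats)),
                  error = conditionMessage(fv)))
    list(raw = fv, error = NA_character_)
  })
  ok <- vapply(rows, function(r) is.na(r$error), logical(1))
  p <- rep(NA_real_, length(chr))
  if (any(ok)) {
    raw <- do.call(rbind, lapply(rows[ok], function(r) r$raw))
    rownames(raw) <- ids[ok]
    fm <- new("FeatureMatrix", values = raw,
              manifestVersion = MANIFEST_VERSION)
    masked <- .mask_matrix(applyNormalizer(bundle@normalizer, fm),
                           bundle@mask)
    p[ok] <- .bundle_prob(bundle, masked@values)
  }
  sel_raw <- do.call(rbind, lapply(rows, function(r) r$raw[feats]))
  out <- data.frame(
    id = ids,
    label = ifelse(is.na(p), NA_character_,
                   ifelse(p >= 0.5, "HARD", "EASY")),
    hard_probability = p,
    error = vapply(rows, function(r) r$error, character(1)),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(sel_raw, optional = TRUE))
}

BUNDLE_FORMAT <- 1L

#' Persist / restore a model bundle
#'
#' The bundle is written as a single versioned RDS archive. Loading checks
#' the archive format and the feature-manifest version and refuses
#' mismatches; a save/load round trip preserves predictions exactly.
#'
#' @param bundle A [ModelBundle].
#' @param path File path.
#' @return `saveBundle` returns `path` invisibly; `loadBundle` the
#'   [ModelBundle].
#' @export
saveBundle <- function(bundle, path) {
  stopifnot(is(bundle, "ModelBundle"))
  saveRDS(list(format = BUNDLE_FORMAT,
               manifestVersion = bundle@manifestVersion,
               bundle = bundle), path)
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt bundle file: ", path,
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, BUNDLE_FORMAT))
    stop("not a synthscreen bundle (or unsupported format): ", path)
  if (!identical(obj$manifestVersion, MANIFEST_VERSION))
    stop("bundle manifest version ", obj$manifestVersion,
         " does not match this package (", MANIFEST_VERSION, ")")
  stopifnot(is(obj$bundle, "ModelBundle"))
  obj$bundle
}
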