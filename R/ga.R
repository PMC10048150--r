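#' @include selection.R
NULL

# evaluate expr with a locally seeded RNG, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Genetic-algorithm configuration
#'
#' Controls the wrapper feature selection of [gaSelect()]. `rounds` counts
#' fitness evaluations (not generations); the experiment grid uses 10000 or
#' 100000. The fitness of a mask is the mean 3-fold cross-validated F1 of a
#' fast reference random forest on the masked features, minus a parsimony
#' penalty per kept feature, so that ties resolve toward smaller feature
#' sets.
#'
#' @param rounds Total fitness evaluations (>= `population`).
#' @param population Population size.
#' @param crossoverProb One-point crossover probability.
#' @param mutationProb Per-bit mutation probability; `NA` (default) means
#'   1 / number-of-features.
#' @param tournamentSize Tournament selection size.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param parsimony Fitness penalty per kept feature.
#' @param refTrees Trees in the reference forest scoring each mask.
#' @param folds Cross-validation folds for the fitness.
#' @param seed RNG seed; the whole run is reproducible given the seed.
#' @return A list of class `gaConfig`.
#' @export
gaConfig <- function(rounds = 10000L, population = 50L,
                     crossoverProb = 0.8, mutationProb = NA_real_,
                     tournamentSize = 3L, elitism = 1L,
                     parsimony = 1e-4, refTrees = 25L, folds = 3L,
                     seed = 0L) {
  stopifnot(rounds >= population, population >= 4L,
            crossoverProb >= 0, crossoverProb <= 1,
            is.na(mutationProb) || (mutationProb >= 0 && mutationProb <= 1),
            tournamentSize >= 1L, elitism >= 0L)
  structure(list(rounds = as.integer(rounds),
                 population = as.integer(population),
                 crossoverProb = crossoverProb,
                 mutationProb = mutationProb,
                 tournamentSize = as.integer(tournamentSize),
                 elitism = as.integer(elitism), parsimony = parsimony,
                 refTrees = as.integer(refTrees), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "gaConfig")
}

# stratified fold assignment, deterministic under the caller's RNG
.strat_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean CV F1 of the reference forest on the masked columns
.cv_f1 <- function(X, y, fold, mask, trees, seed) {
  Xm <- X[, mask, drop = FALSE]
  f1s <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    fit <- ranger::ranger(x = Xm[tr, , drop = FALSE], y = y[tr],
                          num.trees = trees, num.threads = 1L,
                          seed = seed + f)
    pred <- predict(fit, data = Xm[!tr, , drop = FALSE],
                    num.threads = 1L)$predictions
    suppressWarnings(f1Score(confusionCounts(y[!tr], pred)))
  }, numeric(1))
  mean(f1s)
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary feature masks with tournament selection, one-point
#' crossover, per-bit mutation and elitism. Fitness is the mean k-fold
#' cross-validated F1 of a reference random forest on the masked features,
#' minus a small parsimony penalty per feature. Fold assignment is fixed
#' for the whole run and fitness values are memoized by mask, so repeated
#' chromosomes cost no refits (memoized lookups still count toward
#' `rounds`). The best-ever mask is returned; the run is fully reproducible
#' given `config$seed`.
#'
#' @param matrix A normalized [FeatureMatrix] (>= 20 rows).
#' @param labels EASY/HARD labels for the rows; both classes must occur.
#' @param config A [gaConfig()].
#' @return A [SelectionMask] (provenance method `"ga"`).
#' @export
gaSelect <- function(matrix, labels, config = gaConfig()) {
  stopifnot(is(matrix, "FeatureMatrix"), inherits(config, "gaConfig"))
  X <- matrix@values
  if (nrow(X) < 20L) stop("gaSelect requires at least 20 rows")
  y <- .align_labels(labels, rownames(X))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(X)
  pmut <- if (is.na(config$mutationProb)) 1 / p else config$mutationProb

  best <- .with_seed(config$seed, {
    fold <- .strat_folds(as.integer(y == "HARD"), config$folds)
    cache <- new.env(parent = emptyenv())
    evals <- 0L
    fitness <- function(mask) {
      evals <<- evals + 1L
      if (!any(mask)) return(-1)
      key <- paste(which(mask), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      f <- .cv_f1(X, y, fold, mask, config$refTrees, config$seed) -
        config$parsimony * sum(mask)
      cache[[key]] <- f
      f
    }
    pop <- lapply(seq_len(config$population), function(i)
      runif(p) < 0.5)
    fit <- vapply(pop, fitness, numeric(1))
    best_mask <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    while (evals < config$rounds) {
      ord <- order(fit, decreasing = TRUE)
      nextpop <- pop[ord[seq_len(config$elitism)]]
      while (length(nextpop) < config$population) {
        pick <- function() {
          cand <- sample.int(config$population, config$tournamentSize,
                             replace = TRUE)
          pop[[cand[which.max(fit[cand])]]]
        }
        a <- pick(); b <- pick()
        if (runif(1) < config$crossoverProb && p > 1L) {
          cut <- sample.int(p - 1L, 1L)
          child <- c(a[seq_len(cut)], b[(cut + 1L):p])
        } else child <- a
        flip <- runif(p) < pmut
        child[flip] <- !child[flip]
        nextpop[[length(nextpop) + 1L]] <- child
      }
      pop <- nextpop
      fit <- vapply(pop, fitness, numeric(1))
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best_mask <- pop[[gen_best]]
      }
    }
    best_mask
  })
  if (!any(best)) stop("GA selected an empty feature set")
  .make_mask(matrix, colnames(X)[best], "ga", config$rounds)
}
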