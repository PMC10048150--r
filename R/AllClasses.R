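#' @include enzymes.R
NULL

MANIFEST_VERSION <- "1"

#' Labeled DNA sequence dataset
#'
#' Couples a set of validated DNA sequences (a [Biostrings::DNAStringSet]
#' with unique names) with a binary synthesis-difficulty label per sequence.
#' `HARD` is the positive class throughout the package.
#'
#' @slot sequences A named `DNAStringSet`; names are the sequence ids.
#' @slot labels A factor with levels `EASY`, `HARD`, named by sequence id.
#' @export
setClass("SeqDataset",
  representation(sequences = "DNAStringSet", labels = "factor"),
  validity = function(object) {
    ids <- names(object@sequences)
    msgs <- character(0)
    if (is.null(ids) || anyDuplicated(ids))
      msgs <- c(msgs, "sequence ids must be present and unique")
    if (!identical(levels(object@labels), c("EASY", "HARD")))
      msgs <- c(msgs, "labels must be a factor with levels EASY, HARD")
    if (!setequal(names(object@labels), ids) ||
        length(object@labels) != length(ids))
      msgs <- c(msgs, "labels must be named by sequence id, one per sequence")
    if (length(msgs)) msgs else TRUE
  })

#' Feature matrix for a set of sequences
#'
#' Rows are sequences, columns a subset of the versioned 426-feature
#' manifest, kept in manifest order. Produced by [extractFeatureMatrix()];
#' consumed by the normalizer, the selection filters and the models.
#'
#' @slot values Numeric matrix; rownames are sequence ids, colnames are
#'   manifest feature names.
#' @slot manifestVersion Version string of the manifest the columns refer to.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", manifestVersion = "character"),
  validity = function(object) {
    v <- object@values
    msgs <- character(0)
    if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msgs <- c(msgs, "rownames (sequence ids) must be present and unique")
    man <- featureManifest()$name
    if (is.null(colnames(v)) || !all(colnames(v) %in% man))
      msgs <- c(msgs, "colnames must be manifest feature names")
    else if (is.unsorted(match(colnames(v), man)))
      msgs <- c(msgs, "columns must be in manifest order")
    if (length(msgs)) msgs else TRUE
  })

#' Min-max feature normalizer
#'
#' Per-feature minimum and maximum learned from a training [FeatureMatrix].
#' [applyNormalizer()] maps x to (x - min) / (max - min); constant features
#' map to 0. Values from unseen data may leave \[0, 1\] and are not clipped.
#'
#' @slot mins,maxs Named numeric vectors, one entry per trained feature.
#' @slot manifestVersion Manifest version the feature names refer to.
#' @export
setClass("Normalizer",
  representation(mins = "numeric", maxs = "numeric",
                 manifestVersion = "character"),
  validity = function(object) {
    if (!identical(names(object@mins), names(object@maxs)))
      return("mins and maxs must share names")
    if (any(object@maxs < object@mins)) return("max < min for some feature")
    TRUE
  })

#' Feature selection mask
#'
#' A keep/drop flag for every manifest feature, plus the provenance of the
#' selection stages that produced it (method and cutoff/rounds, in
#' application order).
#'
#' @slot keep Named logical vector over all 426 manifest features.
#' @slot provenance data.frame with columns `method` and `param`.
#' @export
setClass("SelectionMask",
  representation(keep = "logical", provenance = "data.frame"),
  validity = function(object) {
    man <- featureManifest()$name
    if (!identical(names(object@keep), man))
      return("keep must be named by the full manifest, in order")
    if (!any(object@keep)) return("mask keeps no features")
    TRUE
  })

#' Trained ensemble model bundle
#'
#' The deployable predictor: fitted base learners with their ensemble
#' weights, the frozen normalizer and selection mask, and training metadata.
#' Created by [trainModel()], applied with [predictDifficulty()], persisted
#' with [saveBundle()] / [loadBundle()].
#'
#' @slot learners List of fitted base-learner objects (internal format).
#' @slot weights Numeric ensemble weights; positive, summing to one.
#' @slot normalizer The [Normalizer] frozen at training time.
#' @slot mask The [SelectionMask] frozen at training time.
#' @slot manifestVersion Manifest version stamp.
#' @slot metadata List: seed, iteration cap, wall budget, timestamp.
#' @export
setClass("ModelBundle",
  representation(learners = "list", weights = "numeric",
                 normalizer = "Normalizer", mask = "SelectionMask",
                 manifestVersion = "character", metadata = "list"),
  validity = function(object) {
    if (length(object@learners) != length(object@weights))
      return("one weight per learner required")
    if (any(object@weights <= 0)) return("weights must be positive")
    if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
    TRUE
  })

setMethod("show", "SeqDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf("SeqDataset: %d sequences (%d EASY, %d HARD), widths %d-%d bp\n",
              length(object@sequences), tab[["EASY"]], tab[["HARD"]],
              min(Biostrings::width(object@sequences)),
              max(Biostrings::width(object@sequences))))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d sequences x %d features (manifest v%s)\n",
              nrow(object@values), ncol(object@values),
              object@manifestVersion))
})

setMethod("show", "SelectionMask", function(object) {
  prov <- if (nrow(object@provenance))
    paste(sprintf("%s(%s)", object@provenance$method,
                  object@provenance$param), collapse = " -> ")
  else "none"
  cat(sprintf("SelectionMask: %d/%d features kept; provenance: %s\n",
              sum(object@keep), length(object@keep), prov))
})

setMethod("show", "ModelBundle", function(object) {
  fam <- vapply(object@learners, function(l) l$family, character(1))
  cat(sprintf(
    "ModelBundle (manifest v%s): %d learners [%s], %d selected features\n",
    object@manifestVersion, length(object@learners),
    paste(unique(fam), collapse = ", "), sum(object@mask@keep)))
})

#' Accessors for synthscreen objects
#'
#' `sequenceIDs()` returns sequence ids; `sequenceLabels()` the EASY/HARD
#' label factor; `featureValues()` the plain numeric matrix inside a
#' [FeatureMatrix]; `keptFeatures()` the names of features a
#' [SelectionMask] retains.
#'
#' @param x A `SeqDataset`, `FeatureMatrix` or `SelectionMask`.
#' @return See each description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
sequenceIDs <- function(x) {
  if (is(x, "SeqDataset")) names(x@sequences)
  else if (is(x, "FeatureMatrix")) rownames(x@values)
  else stop("no sequence ids in an object of class ", class(x))
}

#' @rdname accessors
#' @export
sequenceLabels <- function(x) {
  stopifnot(is(x, "SeqDataset"))
  x@labels
}

#' @rdname accessors
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@values
}

#' @rdname accessors
#' @export
keptFeatures <- function(x) {
  stopifnot(is(x, "SelectionMask"))
  names(x@keep)[x@keep]
}
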