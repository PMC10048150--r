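#' @include features-restriction.R
NULL

#' Extract the full 426-feature descriptor of one sequence
#'
#' Runs every feature group of [featureManifest()] on a validated sequence
#' and returns the values in manifest order. The result is a pure,
#' deterministic function of the sequence. Sequences shorter than 100 bp
#' are handled best-effort with a warning (window features fall back to a
#' single whole-sequence window); sequences shorter than 40 bp cannot
#' support the spectral feature group and are an error.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 426, names equal to
#'   `featureManifest()$name`.
#' @examples
#' v <- extractFeatures(paste(rep("ACGTGCAT", 40), collapse = ""))
#' length(v)  # 426
#' @export
extractFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 40L)
    stop("extractFeatures requires length >= 40 (got ", L, ")")
  if (L < 100L)
    warning("sequence shorter than 100 bp (", L,
            " bp): window features use the whole sequence as one window")
  groups <- list(
    composition = compositionFeatures, anf = anfFeatures,
    eiip = eiipFeatures, kmer = kmerFeatures, `repeat` = repeatFeatures,
    gc = gcFeatures, tm = tmFeatures, structure = structureFeatures,
    specific = specificFeatures, restriction = restrictionFeatures)
  vals <- unlist(lapply(names(groups), function(g) {
    tryCatch(groups[[g]](s),
             error = function(e) stop("feature group '", g, "': ",
                                      conditionMessage(e), call. = FALSE))
  }))
  vals <- c(vals, length = L)
  man <- featureManifest()$name
  out <- vals[man]
  stopifnot(!anyNA(out), all(is.finite(out)))
  names(out) <- man
  out
}

#' Extract a feature matrix for a set of sequences
#'
#' @param sequences A named `DNAStringSet` or a [SeqDataset].
#' @return A [FeatureMatrix] with one row per sequence, 426 columns.
#' @export
extractFeatureMatrix <- function(sequences) {
  if (is(sequences, "SeqDataset")) sequences <- sequences@sequences
  if (length(sequences) == 0L) stop("no sequences to extract")
  chr <- as.character(sequences)
  vals <- t(vapply(chr, extractFeatures, numeric(426L)))
  rownames(vals) <- names(sequences)
  new("FeatureMatrix", values = vals, manifestVersion = MANIFEST_VERSION)
}

#' Fit a min-max normalizer on a training feature matrix
#'
#' Records the per-feature minimum and maximum of the training matrix.
#' Fitting on training data only (rather than the full dataset) keeps the
#' test split leak-free; the fitted normalizer is frozen into the model
#' bundle at training time.
#'
#' @param matrix A [FeatureMatrix] (the training split).
#' @return A [Normalizer].
#' @export
fitNormalizer <- function(matrix) {
  stopifnot(is(matrix, "FeatureMatrix"))
  v <- matrix@values
  if (nrow(v) == 0L) stop("cannot fit a normalizer on an empty matrix")
  new("Normalizer",
      mins = apply(v, 2, min), maxs = apply(v, 2, max),
      manifestVersion = matrix@manifestVersion)
}

#' Apply a fitted min-max normalizer
#'
#' Maps each feature x to (x - min) / (max - min) using the training
#' extrema; features constant in training map to 0. Values from unseen
#' data may fall outside \[0, 1\] and are not clipped.
#'
#' @param normalizer A [Normalizer] from [fitNormalizer()].
#' @param matrix A [FeatureMatrix] whose columns are covered by the
#'   normalizer.
#' @return A normalized [FeatureMatrix].
#' @export
applyNormalizer <- function(normalizer, matrix) {
  stopifnot(is(normalizer, "Normalizer"), is(matrix, "FeatureMatrix"))
  if (!identical(normalizer@manifestVersion, matrix@manifestVersion))
    stop("manifest version mismatch between normalizer and matrix")
  v <- matrix@values
  feats <- colnames(v)
  if (!all(feats %in% names(normalizer@mins)))
    stop("normalizer was not fitted on all features of the matrix")
  mins <- normalizer@mins[feats]
  maxs <- normalizer@maxs[feats]
  rng <- maxs - mins
  out <- sweep(v, 2, mins, "-")
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, const] <- 0
  new("FeatureMatrix", values = out, manifestVersion = matrix@manifestVersion)
}

#' Write / read a feature matrix as tab-separated values
#'
#' The file has a header row (`id` followed by manifest feature names) and
#' one row per sequence.
#'
#' @param matrix A [FeatureMatrix].
#' @param path File path.
#' @return `writeFeatureMatrix` returns `path` invisibly;
#'   `readFeatureMatrix` returns a [FeatureMatrix].
#' @export
writeFeatureMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "FeatureMatrix"))
  df <- data.frame(id = rownames(matrix@values), matrix@values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!identical(colnames(df)[1], "id"))
    stop("feature matrix file must have an 'id' first column")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$id
  new("FeatureMatrix", values = v, manifestVersion = MANIFEST_VERSION)
}

# subset a FeatureMatrix to the features kept by a mask
.mask_matrix <- function(matrix, mask) {
  stopifnot(is(matrix, "FeatureMatrix"), is(mask, "SelectionMask"))
  keep <- intersect(colnames(matrix@values), keptFeatures(mask))
  if (!length(keep)) stop("mask keeps no features present in the matrix")
  new("FeatureMatrix", values = matrix@values[, keep, drop = FALSE],
      manifestVersion = matrix@manifestVersion)
}
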