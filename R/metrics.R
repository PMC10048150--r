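#' @include AllClasses.R
NULL

#' Confusion counts for binary EASY/HARD classification
#'
#' Tallies TP/FP/TN/FN of predictions against truth with respect to a
#' declared positive class (`HARD`, the difficult-to-synthesize class, by
#' default).
#'
#' @param truth,pred Equal-length vectors of labels in `{EASY, HARD}`
#'   (character or factor).
#' @param positive The positive class, `"HARD"` or `"EASY"`.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @examples
#' confusionCounts(c("HARD", "EASY"), c("HARD", "HARD"))
#' @export
confusionCounts <- function(truth, pred, positive = "HARD") {
  truth <- toupper(as.character(truth))
  pred <- toupper(as.character(pred))
  if (length(truth) != length(pred))
    stop("truth and pred differ in length")
  ok <- c("EASY", "HARD")
  if (!all(truth %in% ok) || !all(pred %in% ok))
    stop("labels must be EASY or HARD")
  positive <- match.arg(toupper(positive), ok)
  tpos <- truth == positive
  ppos <- pred == positive
  c(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
    TN = sum(!tpos & !ppos), FN = sum(tpos & !ppos))
}

.check_counts <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)),
            all(counts >= 0), sum(counts) >= 1)
  counts
}

#' F1 score
#'
#' F1 = 2 TP / (2 TP + FP + FN), the harmonic mean of precision and recall.
#' The degenerate case TP = FP = FN = 0 (no positives anywhere) is defined
#' as 0 with a warning.
#'
#' @param counts Named counts as from [confusionCounts()].
#' @return F1 in \[0, 1\].
#' @export
f1Score <- function(counts) {
  counts <- .check_counts(counts)
  denom <- 2 * counts[["TP"]] + counts[["FP"]] + counts[["FN"]]
  if (denom == 0) {
    warning("no positives in truth or prediction; F1 defined as 0")
    return(0)
  }
  2 * counts[["TP"]] / denom
}

#' Matthews correlation coefficient
#'
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any zero
#' factor in the denominator (a row or column of the confusion matrix is
#' empty) gives MCC defined as 0 with a warning.
#'
#' @inheritParams f1Score
#' @return MCC in \[-1, 1\].
#' @export
mccScore <- function(counts) {
  counts <- .check_counts(counts)
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(fac == 0)) {
    warning("degenerate confusion matrix; MCC defined as 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(fac))
}

#' Cohen's kappa
#'
#' CK = (Po - Pe) / (1 - Pe) with observed agreement
#' Po = (TP + TN) / N and chance agreement
#' Pe = ((TP+FN)(TP+FP) + (TN+FP)(TN+FN)) / N^2. The degenerate case
#' Pe = 1 (all mass in one cell of the marginals) is defined as 0 with a
#' warning.
#'
#' @inheritParams f1Score
#' @return Kappa, at most 1.
#' @export
cohensKappa <- function(counts) {
  counts <- .check_counts(counts)
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (pe == 1) {
    warning("chance agreement is 1; kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Full metrics report from labels
#'
#' @inheritParams confusionCounts
#' @return Named numeric vector: `F1`, `MCC`, `CK`, `Po` (accuracy), `Pe`
#'   (chance agreement), plus the four confusion counts.
#' @export
metricsReport <- function(truth, pred, positive = "HARD") {
  counts <- confusionCounts(truth, pred, positive)
  n <- sum(counts)
  pe <- ((counts[["TP"]] + counts[["FN"]]) * (counts[["TP"]] + counts[["FP"]]) +
         (counts[["TN"]] + counts[["FP"]]) * (counts[["TN"]] + counts[["FN"]])) / n^2
  c(F1 = suppressWarnings(f1Score(counts)),
    MCC = suppressWarnings(mccScore(counts)),
    CK = suppressWarnings(cohensKappa(counts)),
    Po = (counts[["TP"]] + counts[["TN"]]) / n,
    Pe = pe,
    counts)
}

#' Ten-gene experimental synthesis benchmark
#'
#' A bundled benchmark of ten genes from *E. coli* MG1655 whose synthesis
#' difficulty was determined experimentally by polymerase cycling assembly
#' followed by PCR and gel electrophoresis, together with the
#' difficulty calls of this method (`our_method`), of the Synthesis Success
#' Calculator baseline (`ssc`), and the DNAWorks score. Scoring the two
#' predictors against the experimental outcome is the package's worked
#' example for the metrics module: the ensemble method calls 8 of 10 genes
#' correctly (accuracy 0.80), the baseline 5 of 10 (accuracy 0.50).
#'
#' @return data.frame with columns `gene`, `dnaworks_score`, `our_method`,
#'   `ssc`, `experimental`.
#' @examples
#' v <- validationGenes()
#' sum(v$our_method == v$experimental)  # 8
#' @export
validationGenes <- function() {
  path <- system.file("extdata", "ecoli_validation_genes.tsv",
                      package = "synthscreen", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 10L)
  df
}
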