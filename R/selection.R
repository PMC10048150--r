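#' @include extract.R
NULL

# lift a keep decision on the matrix's columns to a full-manifest mask
.make_mask <- function(matrix, keep_cols, method, param,
                       parent = NULL) {
  man <- featureManifest()$name
  keep <- setNames(logical(length(man)), man)
  keep[keep_cols] <- TRUE
  prov <- data.frame(method = method, param = as.character(param),
                     stringsAsFactors = FALSE)
  if (!is.null(parent)) prov <- rbind(parent@provenance, prov)
  if (!any(keep))
    stop("selection stage '", method, "' removed every feature")
  new("SelectionMask", keep = keep, provenance = prov)
}

#' Variance feature filter
#'
#' Keeps features whose sample variance over the (normalized) training
#' matrix is at least `cutoff`. Constant features always drop.
#'
#' @param matrix A normalized [FeatureMatrix].
#' @param cutoff Non-negative variance threshold (the experiment grid uses
#'   0.01, 0.02, 0.03, 0.04).
#' @return A [SelectionMask].
#' @export
varianceFilter <- function(matrix, cutoff) {
  stopifnot(is(matrix, "FeatureMatrix"))
  if (cutoff < 0) stop("cutoff must be non-negative")
  v <- apply(matrix@values, 2, var)
  .make_mask(matrix, colnames(matrix@values)[v >= cutoff],
             "variance", cutoff)
}

#' Label-correlation feature filter
#'
#' Keeps features whose absolute Pearson correlation with the binary label
#' (HARD = 1, EASY = 0; the point-biserial correlation) is at least
#' `cutoff`. Features with undefined correlation (constant columns) drop.
#'
#' @param matrix A normalized [FeatureMatrix].
#' @param labels Named or positional EASY/HARD labels, one per row.
#' @param cutoff Threshold on |r| (the experiment grid uses 0.1, 0.15,
#'   0.2, 0.3).
#' @return A [SelectionMask].
#' @export
correlationFilter <- function(matrix, labels, cutoff) {
  stopifnot(is(matrix, "FeatureMatrix"))
  y <- .label01(labels, rownames(matrix@values))
  if (length(unique(y)) < 2L)
    stop("correlation with the label is undefined: only one class present")
  r <- suppressWarnings(as.vector(cor(matrix@values, y)))
  keep <- !is.na(r) & abs(r) >= cutoff
  .make_mask(matrix, colnames(matrix@values)[keep], "correlation", cutoff)
}

# labels (factor/character, named or positional) -> 0/1 with HARD = 1
.label01 <- function(labels, ids) {
  if (!is.null(names(labels)) && !is.null(ids)) {
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("no label for id(s): ", paste(head(missing, 5), collapse = ", "))
    labels <- labels[ids]
  }
  lab <- toupper(as.character(labels))
  stopifnot(all(lab %in% c("EASY", "HARD")))
  as.numeric(lab == "HARD")
}

#' The 74-configuration feature-reduction experiment grid
#'
#' Enumerates every combination of the three selection methods and their
#' cutoffs: correlation cutoffs \{0.1, 0.15, 0.2, 0.3\}, variance cutoffs
#' \{0.01, 0.02, 0.03, 0.04\}, genetic-algorithm rounds \{10000, 100000\}.
#' That is 10 single-method configurations (4 + 4 + 2), 32 two-method
#' combinations (16 + 8 + 8) and 32 three-method combinations (4 x 4 x 2) —
#' 74 in total, in deterministic order (singles, then pairs, then triples).
#'
#' @return data.frame with columns `config_id`, `n_methods`,
#'   `correlation_cutoff`, `variance_cutoff`, `ga_rounds` (NA where a
#'   method is not part of the configuration).
#' @examples
#' nrow(buildExperimentGrid())  # 74
#' @export
buildExperimentGrid <- function() {
  cors <- c(0.1, 0.15, 0.2, 0.3)
  vars <- c(0.01, 0.02, 0.03, 0.04)
  gas <- c(10000L, 100000L)
  row <- function(co = NA_real_, va = NA_real_, ga = NA_integer_)
    data.frame(correlation_cutoff = co, variance_cutoff = va, ga_rounds = ga)
  singles <- rbind(
    do.call(rbind, lapply(cors, function(co) row(co = co))),
    do.call(rbind, lapply(vars, function(va) row(va = va))),
    do.call(rbind, lapply(gas, function(ga) row(ga = ga))))
  pairs <- rbind(
    do.call(rbind, lapply(cors, function(co)
      do.call(rbind, lapply(vars, function(va) row(co, va))))),
    do.call(rbind, lapply(cors, function(co)
      do.call(rbind, lapply(gas, function(ga) row(co = co, ga = ga))))),
    do.call(rbind, lapply(vars, function(va)
      do.call(rbind, lapply(gas, function(ga) row(va = va, ga = ga))))))
  triples <- do.call(rbind, lapply(cors, function(co)
    do.call(rbind, lapply(vars, function(va)
      do.call(rbind, lapply(gas, function(ga) row(co, va, ga)))))))
  grid <- rbind(singles, pairs, triples)
  grid <- cbind(config_id = sprintf("cfg%02d", seq_len(nrow(grid))),
                n_methods = rowSums(!is.na(grid)), grid)
  stopifnot(nrow(grid) == 74L,
            sum(grid$n_methods == 1) == 10L,
            sum(grid$n_methods == 2) == 32L,
            sum(grid$n_methods == 3) == 32L)
  grid
}

#' Apply one experiment configuration
#'
#' Composes the configured selection stages in fixed cheap-to-expensive
#' order (variance, then label correlation, then the genetic algorithm),
#' each stage operating on the survivors of the previous one. An empty
#' survivor set after any stage is an error naming the stage.
#'
#' @param config A one-row slice of [buildExperimentGrid()] (or a list with
#'   elements `variance_cutoff`, `correlation_cutoff`, `ga_rounds`, any of
#'   which may be NA).
#' @param matrix A normalized training [FeatureMatrix].
#' @param labels EASY/HARD labels for the rows of `matrix`.
#' @param gaBase Base [gaConfig()] whose `rounds` is overridden by the
#'   configuration; its seed controls GA reproducibility.
#' @return A [SelectionMask] with full provenance.
#' @export
applyConfig <- function(config, matrix, labels, gaBase = NULL) {
  stopifnot(is(matrix, "FeatureMatrix"))
  va <- config$variance_cutoff
  co <- config$correlation_cutoff
  ga <- config$ga_rounds
  if (all(is.na(c(va, co, ga))))
    stop("configuration selects no method")
  mask <- NULL
  cur <- matrix
  if (!is.na(va)) {
    mask <- varianceFilter(cur, va)
    cur <- .mask_matrix(cur, mask)
  }
  if (!is.na(co)) {
    m2 <- correlationFilter(cur, labels, co)
    mask <- .make_mask(cur, keptFeatures(m2), "correlation", co,
                       parent = mask)
    cur <- .mask_matrix(cur, mask)
  }
  if (!is.na(ga)) {
    cfg <- if (is.null(gaBase)) gaConfig(rounds = ga) else {
      gaBase$rounds <- ga; gaBase
    }
    m3 <- gaSelect(cur, labels, cfg)
    mask <- .make_mask(cur, keptFeatures(m3), "ga", ga, parent = mask)
  }
  mask
}

#' Run feature-reduction experiments over a configuration grid
#'
#' For each configuration: fixed train/test split, normalizer fitted on the
#' training split, configured feature selection on the training split, then
#' `nRepeats` independent train/evaluate cycles of [trainModel()] (the
#' model-search seed varies per repeat; split and selection stay fixed).
#' Reports the selected-feature count and mean/sd of F1, MCC and Cohen's
#' kappa per configuration.
#'
#' @param grid data.frame of configurations (subset of
#'   [buildExperimentGrid()]).
#' @param matrix A raw (unnormalized) [FeatureMatrix] of the full dataset.
#' @param labels EASY/HARD labels for the rows.
#' @param nRepeats Train/evaluate repeats per configuration.
#' @param seed Base seed; repeat r of configuration uses model seed
#'   `seed + r`.
#' @param split A [splitSpec()].
#' @param iterCap Model-search iteration cap passed to [trainModel()].
#' @param gaBase Base [gaConfig()] for GA stages.
#' @return data.frame: config columns, `n_selected`, then
#'   `<metric>_mean` / `<metric>_sd` for f1, mcc, ck.
#' @export
runExperiments <- function(grid, matrix, labels, nRepeats = 10L, seed = 0L,
                           split = splitSpec(), iterCap = 16L,
                           gaBase = NULL) {
  stopifnot(nrow(grid) >= 1L, is(matrix, "FeatureMatrix"))
  ids <- rownames(matrix@values)
  labels <- .align_labels(labels, ids)
  part <- splitDataset(length(ids), split, labels = labels)
  tr_ids <- ids[part$train]; te_ids <- ids[part$test]
  tr_raw <- new("FeatureMatrix", values = matrix@values[tr_ids, , drop = FALSE],
                manifestVersion = matrix@manifestVersion)
  norm <- fitNormalizer(tr_raw)
  tr <- applyNormalizer(norm, tr_raw)
  te <- applyNormalizer(norm, new("FeatureMatrix",
                                  values = matrix@values[te_ids, , drop = FALSE],
                                  manifestVersion = matrix@manifestVersion))
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    cfg <- grid[gi, , drop = FALSE]
    mask <- tryCatch(
      applyConfig(cfg, tr, labels[tr_ids], gaBase = gaBase),
      error = function(e) stop("config ", cfg$config_id, ": ",
                               conditionMessage(e), call. = FALSE))
    mets <- vapply(seq_len(nRepeats), function(r) {
      bundle <- trainModel(.mask_matrix(tr, mask), labels[tr_ids],
                           iterCap = iterCap, seed = seed + r,
                           normalizer = norm, mask = mask)
      pred <- .predict_matrix(bundle, .mask_matrix(te, mask))
      m <- metricsReport(labels[te_ids], pred$label)
      suppressWarnings(m[c("F1", "MCC", "CK")])
    }, numeric(3))
    data.frame(cfg, n_selected = sum(mask@keep),
               f1_mean = mean(mets["F1", ]), f1_sd = sd(mets["F1", ]),
               mcc_mean = mean(mets["MCC", ]), mcc_sd = sd(mets["MCC", ]),
               ck_mean = mean(mets["CK", ]), ck_sd = sd(mets["CK", ]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

.align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("no label for id(s): ", paste(head(missing, 5), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named or match the number of rows")
  }
  out <- factor(toupper(as.character(labels)), levels = c("EASY", "HARD"))
  names(out) <- ids
  out
}

#' Write / read a selection mask
#'
#' Serialized as provenance header lines (`# method<TAB>param`) followed by
#' the kept feature names, one per line.
#'
#' @param mask A [SelectionMask].
#' @param path File path.
#' @return `writeMask` returns `path` invisibly; `readMask` a
#'   [SelectionMask].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SelectionMask"))
  hdr <- sprintf("# %s\t%s", mask@provenance$method, mask@provenance$param)
  writeLines(c(hdr, keptFeatures(mask)), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  prov <- if (any(hdr)) {
    parts <- strsplit(sub("^#\\s*", "", lines[hdr]), "\t")
    data.frame(method = vapply(parts, `[`, "", 1),
               param = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(method = character(0), param = character(0))
  feats <- lines[!hdr & nzchar(lines)]
  man <- featureManifest()$name
  unknown <- setdiff(feats, man)
  if (length(unknown))
    stop("unknown feature name(s) in mask file: ",
         paste(head(unknown, 5), collapse = ", "))
  keep <- setNames(man %in% feats, man)
  new("SelectionMask", keep = keep, provenance = prov)
}
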