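# Shared fixtures, built in code. The labeled dataset and its feature
# matrix are expensive enough to build once and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

# a FeatureMatrix with planted signal among noise columns; column names
# are manifest names so the S4 validity holds.
#
# mode "shift": the first n_inf columns are each shifted by the label
#   (redundant signal; any one suffices) — good for trainability tests.
# mode "additive": the label is a threshold on the mean of the first
#   n_inf columns (jointly informative; dropping one loses signal) —
#   good for feature-recovery tests.
make_planted_matrix <- function(n = 60L, p = 20L, n_inf = 3L, seed = 1L,
                                noise_sd = 0.15, mode = c("shift",
                                                          "additive"),
                                margin = 0.04) {
  mode <- match.arg(mode)
  set.seed(seed)
  man <- featureManifest()$name
  if (mode == "shift") {
    y <- rep(c("EASY", "HARD"), length.out = n)
    X <- matrix(runif(n * p), n, p)
    for (j in seq_len(n_inf))
      X[, j] <- 0.25 + 0.5 * (y == "HARD") + rnorm(n, 0, noise_sd)
    X <- pmin(pmax(X, 0), 1)
  } else {
    X <- matrix(runif(n * p), n, p)
    score <- rowMeans(X[, seq_len(n_inf), drop = FALSE])
    # keep a margin around the decision surface so the rule is learnable
    redo <- which(abs(score - 0.5) < margin)
    while (length(redo)) {
      X[redo, seq_len(n_inf)] <- runif(length(redo) * n_inf)
      score <- rowMeans(X[, seq_len(n_inf), drop = FALSE])
      redo <- which(abs(score - 0.5) < margin)
    }
    y <- ifelse(score > 0.5, "HARD", "EASY")
  }
  ids <- sprintf("r%03d", seq_len(n))
  rownames(X) <- ids
  colnames(X) <- man[seq_len(p)]
  list(matrix = new("FeatureMatrix", values = X, manifestVersion = "1"),
       labels = setNames(factor(y, levels = c("EASY", "HARD")), ids),
       informative = man[seq_len(n_inf)])
}

# small labeled sequence dataset with planted difficulty (cached)
fixture_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generateDataset(40L, difficultyRule(), seed = 42L,
                                       length = 300L)
  .fixture_env$ds
}

fixture_features <- function() {
  if (is.null(.fixture_env$fm))
    .fixture_env$fm <- extractFeatureMatrix(fixture_dataset())
  .fixture_env$fm
}

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
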