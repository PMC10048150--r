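test_that("variance filter keeps high-variance columns and matches direct computation", {
  man <- featureManifest()$name
  X <- cbind(c(0, 0, 1, 1), c(0.5, 0.5, 0.5, 0.5), c(0, 0.1, 0.2, 0.3))
  dimnames(X) <- list(paste0("r", 1:4), man[1:3])
  fm <- new("FeatureMatrix", values = X, manifestVersion = "1")
  mask <- varianceFilter(fm, 0.01)
  v <- apply(X, 2, var)
  expect_identical(keptFeatures(mask), colnames(X)[v >= 0.01])
  expect_false(man[2] %in% keptFeatures(mask))      # constant column drops
  expect_true(man[1] %in% keptFeatures(mask))       # 0/1 column (var 0.333)
  expect_error(varianceFilter(fm, -1), "non-negative")
})

test_that("correlation filter uses point-biserial correlation with HARD=1", {
  man <- featureManifest()$name
  y <- c("EASY", "EASY", "EASY", "HARD", "HARD", "HARD")
  X <- cbind(c(0, 0, 0, 1, 1, 1),          # identical to label, |r| = 1
             rep(0.3, 6),                   # constant, undefined r
             c(0.2, 0.4, 0.3, 0.35, 0.25, 0.4))
  dimnames(X) <- list(paste0("r", 1:6), man[1:3])
  fm <- new("FeatureMatrix", values = X, manifestVersion = "1")
  labels <- setNames(factor(y, levels = c("EASY", "HARD")), rownames(X))
  mask <- correlationFilter(fm, labels, 0.5)
  expect_identical(keptFeatures(mask), man[1])
  # kept set matches hand-computed correlations at a low cutoff
  r3 <- abs(cor(X[, 3], as.numeric(y == "HARD")))
  mask2 <- correlationFilter(fm, labels, min(r3, 0.99) - 1e-9)
  expect_identical(keptFeatures(mask2), man[c(1, 3)])
  expect_error(correlationFilter(fm, setNames(rep("EASY", 6), rownames(X)),
                                 0.1), "one class")
})

test_that("filter cutoffs are monotone and stages compose subset-wise", {
  pl <- make_planted_matrix(n = 40L, p = 15L, seed = 5L)
  k_small <- keptFeatures(varianceFilter(pl$matrix, 0.01))
  k_large <- keptFeatures(varianceFilter(pl$matrix, 0.04))
  expect_true(all(k_large %in% k_small))
  c_small <- keptFeatures(correlationFilter(pl$matrix, pl$labels, 0.1))
  c_large <- keptFeatures(correlationFilter(pl$matrix, pl$labels, 0.3))
  expect_true(all(c_large %in% c_small))

  cfg <- list(variance_cutoff = 0.01, correlation_cutoff = 0.1,
              ga_rounds = NA_integer_)
  mask <- applyConfig(cfg, pl$matrix, pl$labels)
  expect_true(all(keptFeatures(mask) %in% k_small))
  expect_lte(length(keptFeatures(mask)), length(k_small))
  # single-method config identical to the filter alone
  cfg1 <- list(variance_cutoff = 0.01, correlation_cutoff = NA_real_,
               ga_rounds = NA_integer_)
  expect_identical(keptFeatures(applyConfig(cfg1, pl$matrix, pl$labels)),
                   k_small)
  # impossible cutoff errors with the stage name
  cfg2 <- list(variance_cutoff = 10, correlation_cutoff = NA_real_,
               ga_rounds = NA_integer_)
  expect_error(applyConfig(cfg2, pl$matrix, pl$labels), "variance")
})

test_that("experiment grid enumerates 74 configurations as 10 + 32 + 32", {
  grid <- buildExperimentGrid()
  expect_equal(nrow(grid), 74L)
  expect_equal(sum(grid$n_methods == 1), 10L)
  expect_equal(sum(grid$n_methods == 2), 32L)
  expect_equal(sum(grid$n_methods == 3), 32L)
  # pure: two calls agree exactly
  expect_identical(grid, buildExperimentGrid())
  # cutoff sets are the published ones
  expect_setequal(unique(na.omit(grid$correlation_cutoff)),
                  c(0.1, 0.15, 0.2, 0.3))
  expect_setequal(unique(na.omit(grid$variance_cutoff)),
                  c(0.01, 0.02, 0.03, 0.04))
  expect_setequal(unique(na.omit(grid$ga_rounds)), c(10000L, 100000L))
})

test_that("mask files round-trip with provenance", {
  pl <- make_planted_matrix(seed = 6L)
  mask <- varianceFilter(pl$matrix, 0.01)
  p <- tempfile()
  writeMask(mask, p)
  back <- readMask(p)
  expect_identical(keptFeatures(back), keptFeatures(mask))
  expect_identical(back@provenance$method, "variance")
})

test_that("runExperiments reports per-config repeat metrics on separable data", {
  pl <- make_planted_matrix(n = 60L, p = 12L, n_inf = 3L, seed = 7L,
                            noise_sd = 0.02)
  grid <- buildExperimentGrid()[c(5, 1), ]  # one variance, one correlation
  res <- runExperiments(grid, pl$matrix, pl$labels, nRepeats = 2L,
                        seed = 3L, iterCap = 4L)
  expect_equal(nrow(res), 2L)
  expect_true(all(c("n_selected", "f1_mean", "f1_sd", "mcc_mean",
                    "ck_mean") %in% colnames(res)))
  expect_true(all(res$n_selected >= 1))
  expect_true(all(res$f1_mean >= 0.9))  # near-noiseless planted signal
  # identical configs give identical rows under the same seed
  res2 <- runExperiments(grid, pl$matrix, pl$labels, nRepeats = 2L,
                         seed = 3L, iterCap = 4L)
  expect_equal(res, res2)
})
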