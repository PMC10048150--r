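test_that("the manifest pins 426 named features in 11 groups", {
  m <- featureManifest()
  expect_equal(nrow(m), 426L)
  expect_false(anyDuplicated(m$name) > 0)
  sizes <- table(m$group)
  expect_equal(unname(sizes[c("composition", "anf", "eiip", "kmer",
                              "repeat", "gc", "tm", "structure",
                              "specific", "restriction", "length")]),
               c(84L, 22L, 40L, 112L, 15L, 8L, 3L, 7L, 20L, 114L, 1L),
               ignore_attr = TRUE)
  expect_true("site_ApaI" %in% m$name)
  expect_true(all(c("dGC", "GC_short_l", "GC_long_l", "Tm_low") %in% m$name))
})

test_that("extractFeatures is deterministic, complete, and manifest-ordered", {
  s <- oracle_random_seq(300L, 99L)
  v1 <- extractFeatures(s)
  v2 <- extractFeatures(s)
  expect_identical(v1, v2)
  expect_length(v1, 426L)
  expect_identical(names(v1), featureManifest()$name)
  expect_true(all(is.finite(v1)))
  expect_equal(v1[["length"]], 300)

  # count features are non-negative integers; frequency blocks sit in [0,1]
  m <- featureManifest()
  cnts <- v1[m$name[m$group == "restriction"]]
  expect_true(all(cnts >= 0 & cnts == round(cnts)))
  freqs <- v1[m$name[m$group == "composition"]]
  expect_true(all(freqs >= 0 & freqs <= 1))
})

test_that("short sequences warn and fall back to whole-sequence windows", {
  s <- oracle_random_seq(60L, 98L)
  expect_warning(v <- extractFeatures(s), "shorter than 100")
  expect_length(v, 426L)
  expect_error(extractFeatures(oracle_random_seq(39L, 97L)), "length >= 40")
})

test_that("feature matrix extraction, TSV round trip, and id bookkeeping", {
  ds <- fixture_dataset()
  fm <- fixture_features()
  expect_s4_class(fm, "FeatureMatrix")
  expect_identical(sequenceIDs(fm), sequenceIDs(ds))
  expect_equal(dim(featureValues(fm)), c(40L, 426L))

  p <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(fm, p)
  back <- readFeatureMatrix(p)
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-8)
})

test_that("min-max normalization maps training data into [0,1] with constant columns at 0", {
  fm <- fixture_features()
  norm <- fitNormalizer(fm)
  nm <- applyNormalizer(norm, fm)
  v <- featureValues(nm)
  expect_true(all(v >= 0 & v <= 1))
  const <- which(apply(featureValues(fm), 2, function(x) max(x) == min(x)))
  if (length(const))
    expect_true(all(v[, const] == 0))

  # hand-checked 3x2 example
  X <- matrix(c(0, 1, 2, 5, 5, 5), ncol = 2,
              dimnames = list(c("a", "b", "c"),
                              featureManifest()$name[1:2]))
  toy <- new("FeatureMatrix", values = X, manifestVersion = "1")
  tn <- applyNormalizer(fitNormalizer(toy), toy)
  expect_equal(unname(featureValues(tn)[, 1]), c(0, 0.5, 1))
  expect_equal(unname(featureValues(tn)[, 2]), c(0, 0, 0))

  # unseen values outside the training range are not clipped
  X2 <- X; X2[1, 1] <- 4
  toy2 <- new("FeatureMatrix", values = X2, manifestVersion = "1")
  expect_gt(featureValues(applyNormalizer(fitNormalizer(toy), toy2))[1, 1], 1)
})
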