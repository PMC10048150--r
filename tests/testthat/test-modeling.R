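test_that("splitting is deterministic and reproduces the 3:1 sizes", {
  p <- splitDataset(1076L)
  expect_length(p$train, 807L)
  expect_length(p$test, 269L)
  expect_identical(p, splitDataset(1076L))
  expect_length(intersect(p$train, p$test), 0L)

  p4 <- splitDataset(4L)
  expect_length(p4$train, 3L)
  expect_length(p4$test, 1L)
  expect_error(splitDataset(4L, splitSpec(0.01)), "empty partition")
  expect_warning(
    splitDataset(10L, labels = rep(c("EASY", "HARD"), c(9, 1))),
    "both classes")
})

test_that("training yields a valid, deterministic weighted ensemble", {
  pl <- make_planted_matrix(n = 60L, p = 10L, n_inf = 3L, seed = 21L,
                            noise_sd = 0.05)
  b1 <- trainModel(pl$matrix, pl$labels, iterCap = 8L, seed = 1L)
  expect_s4_class(b1, "ModelBundle")
  expect_equal(sum(b1@weights), 1, tolerance = 1e-12)
  expect_true(all(b1@weights > 0))

  b2 <- trainModel(pl$matrix, pl$labels, iterCap = 8L, seed = 1L)
  expect_identical(vapply(b1@learners, `[[`, "", "family"),
                   vapply(b2@learners, `[[`, "", "family"))
  expect_identical(b1@weights, b2@weights)
  p1 <- synthscreen:::.predict_matrix(b1, pl$matrix)
  p2 <- synthscreen:::.predict_matrix(b2, pl$matrix)
  expect_identical(p1, p2)

  one_class <- setNames(factor(rep("EASY", 60), c("EASY", "HARD")),
                        rownames(featureValues(pl$matrix)))
  expect_error(trainModel(pl$matrix, one_class, iterCap = 4L),
               "single class")
  expect_error(trainModel(pl$matrix, pl$labels, iterCap = 0L), "budget")
})

test_that("ensemble prediction equals the weight-averaged member probabilities", {
  pl <- make_planted_matrix(n = 50L, p = 8L, seed = 22L)
  b <- trainModel(pl$matrix, pl$labels, iterCap = 6L, seed = 2L)
  X <- featureValues(pl$matrix)
  member <- vapply(b@learners,
                   function(l) synthscreen:::.learner_prob(l, X),
                   numeric(nrow(X)))
  expect_equal(synthscreen:::.bundle_prob(b, X),
               as.numeric(member %*% b@weights), tolerance = 1e-12)
})

test_that("probability 0.5 is called HARD (tie to the positive class)", {
  pl <- make_planted_matrix(n = 40L, p = 6L, seed = 23L)
  b <- trainModel(pl$matrix, pl$labels, iterCap = 4L, seed = 3L)
  fake <- new("FeatureMatrix",
              values = featureValues(pl$matrix)[1:2, , drop = FALSE],
              manifestVersion = "1")
  pr <- synthscreen:::.predict_matrix(b, fake)
  expect_true(all(pr$label == ifelse(pr$hard_probability >= 0.5,
                                     "HARD", "EASY")))
})

test_that("repeat evaluation reports coherent mean/sd/min/max over cycles", {
  pl <- make_planted_matrix(n = 70L, p = 10L, n_inf = 3L, seed = 24L,
                            noise_sd = 0.05)
  ev <- repeatEvaluate(pl$matrix, pl$labels, nRepeats = 3L, iterCap = 4L,
                       seed = 5L)
  expect_equal(nrow(ev$runs), 3L)
  for (m in c("F1", "MCC", "CK")) {
    row <- ev$summary[ev$summary$metric == m, ]
    expect_lte(row$min, row$mean)
    expect_lte(row$mean, row$max)
  }
  expect_error(repeatEvaluate(pl$matrix, pl$labels, nRepeats = 1L), "2")
})

test_that("bundles survive a save/load round trip bit-for-bit and reject tampering", {
  pl <- make_planted_matrix(n = 40L, p = 6L, seed = 25L)
  b <- trainModel(pl$matrix, pl$labels, iterCap = 4L, seed = 7L)
  path <- tempfile(fileext = ".rds")
  saveBundle(b, path)
  b2 <- loadBundle(path)
  expect_identical(synthscreen:::.predict_matrix(b, pl$matrix),
                   synthscreen:::.predict_matrix(b2, pl$matrix))

  raw <- readRDS(path)
  raw$manifestVersion <- "999"
  tam <- tempfile(fileext = ".rds")
  saveRDS(raw, tam)
  expect_error(loadBundle(tam), "manifest version")
  expect_error(loadBundle(tempfile()), "no such file")
  junk <- tempfile()
  writeLines("not a bundle", junk)
  expect_error(loadBundle(junk), "corrupt|bundle")
})

test_that("permutation importance separates signal from noise features", {
  pl <- make_planted_matrix(n = 80L, p = 8L, n_inf = 2L, seed = 26L,
                            noise_sd = 0.05)
  b <- trainModel(pl$matrix, pl$labels, iterCap = 6L, seed = 8L)
  imp <- permutationImportance(b, pl$matrix, pl$labels, nShuffles = 8L,
                               seed = 1L)
  expect_setequal(imp$feature, colnames(featureValues(pl$matrix)))
  inf_imp <- imp$importance[imp$feature %in% pl$informative]
  expect_gt(max(inf_imp), 0)
  noise <- imp[!imp$feature %in% pl$informative, ]
  expect_true(all(abs(noise$importance) <= pmax(2 * noise$sd, 0.05)))
  imp2 <- permutationImportance(b, pl$matrix, pl$labels, nShuffles = 8L,
                                seed = 1L)
  expect_identical(imp, imp2)
  expect_error(permutationImportance(b, pl$matrix, pl$labels,
                                     nShuffles = 0L), "nShuffles")
})

test_that("partial dependence is monotone for a planted monotone rule", {
  pl <- make_planted_matrix(n = 80L, p = 5L, n_inf = 1L, seed = 27L,
                            noise_sd = 0.02)
  b <- trainModel(pl$matrix, pl$labels, iterCap = 6L, seed = 9L)
  pd <- partialDependence(b, pl$matrix, pl$informative[1], gridPoints = 9L)
  expect_equal(nrow(pd), 9L)
  expect_equal(pd$value[1], min(featureValues(pl$matrix)[, pl$informative[1]]))
  # allow tiny non-monotonic ripples from tree discretization
  expect_gt(pd$hard_probability[9] - pd$hard_probability[1], 0.2)
  expect_true(all(diff(pd$hard_probability) > -0.05))
  expect_error(partialDependence(b, pl$matrix, "site_ApaI"), "selected")
})
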