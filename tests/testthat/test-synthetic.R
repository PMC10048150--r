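test_that("background generation hits the target GC within binomial bounds", {
  spec <- syntheticSpec(500L, targetGC = 0.5, seed = 1L)
  s <- as.character(generateSequence(spec))
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.07)   # 99% binomial bound at n = 500
  # determinism
  expect_identical(as.character(generateSequence(spec)),
                   as.character(generateSequence(spec)))
})

test_that("planted elements appear verbatim and are seen by the extractors", {
  spec <- syntheticSpec(400L, elements = list(
    list(kind = "inverted_repeat", stem = 12L, loop = 5L, at = 100L),
    list(kind = "homopolymer", base = "T", run = 9L, at = 300L)),
    seed = 2L)
  s <- as.character(generateSequence(spec))
  st <- structureFeatures(s)
  expect_gte(st[["hp_longest_stem"]], 12)
  expect_gte(repeatFeatures(s)[["rep_polyT"]], 9)

  spec2 <- syntheticSpec(300L, elements = list(
    list(kind = "motif", motif = "GGGCCC", at = 150L)), seed = 3L)
  s2 <- as.character(generateSequence(spec2))
  expect_identical(unname(substr(s2, 150L, 155L)), "GGGCCC")
  expect_gte(restrictionFeatures(s2)[["site_ApaI"]], 1)
})

test_that("overlapping or oversized elements are rejected", {
  bad <- syntheticSpec(100L, elements = list(
    list(kind = "homopolymer", base = "A", run = 30L, at = 10L),
    list(kind = "homopolymer", base = "C", run = 30L, at = 20L)), seed = 4L)
  expect_error(generateSequence(bad), "overlap")
  toolong <- syntheticSpec(50L, elements = list(
    list(kind = "low_gc_patch", len = 80L, gc = 0.1, at = 1L)), seed = 5L)
  expect_error(generateSequence(toolong), "longer|exceeds")
})

test_that("labeled datasets respect n, balance, noise and the planted rule", {
  expect_error(generateDataset(19L), "n >= 20")
  ds <- fixture_dataset()   # n = 40, balance 0.5, noise 0
  expect_length(ds@sequences, 40L)
  expect_equal(sum(sequenceLabels(ds) == "HARD"), 20L)

  # noise = 0: labels equal the rule evaluated on extracted determinants
  rule <- difficultyRule()
  stats <- vapply(as.character(ds@sequences), synthscreen:::.rule_stats,
                  numeric(3))
  derived <- apply(stats, 2, function(x)
    x[["dGC"]] > rule$dgcOver ||
      x[["longest_direct"]] >= rule$repeatAtLeast ||
      x[["strong_hairpins"]] >= rule$strongHairpins)
  expect_identical(unname(derived),
                   unname(sequenceLabels(ds) == "HARD"))

  # label noise flips roughly the stated fraction
  noisy <- generateDataset(60L, difficultyRule(noise = 0.2), seed = 9L,
                           length = 300L)
  planted <- attr(noisy, "plantedLabels")
  flips <- mean(planted != sequenceLabels(noisy))
  expect_gt(flips, 0.03)
  expect_lt(flips, 0.45)
})

test_that("dataset generation writes consumable FASTA and label files", {
  fa <- tempfile(fileext = ".fasta")
  la <- tempfile(fileext = ".tsv")
  ds <- generateDataset(20L, seed = 11L, length = 250L,
                        fastaPath = fa, labelsPath = la)
  back <- seqDataset(validateSequences(readSequences(fa)), readLabels(la))
  expect_identical(as.character(back@sequences),
                   as.character(ds@sequences))
  expect_identical(sequenceLabels(back), sequenceLabels(ds))
})
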