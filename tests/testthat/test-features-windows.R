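test_that("GC features on homopolymers force every window", {
  v <- gcFeatures(strrep("A", 200))
  expect_equal(v[["GC_global"]], 0)
  expect_equal(v[["dGC"]], 0)
  expect_equal(v[["GC_long_l"]], 101)  # all 101 windows at 0% GC

  v2 <- gcFeatures(strrep("G", 150))
  expect_equal(v2[["GC_global"]], 1)
  expect_equal(v2[["GC_long_l"]], 0)
  expect_equal(v2[["GC_long_h"]], 51)
  expect_error(gcFeatures(""), "empty")
})

test_that("dGC and window counts match a brute-force window scan", {
  for (seed in 1:3) {
    s <- oracle_random_seq(300L, seed + 20L)
    w100 <- oracle_window_gc(s, 100L)
    w20 <- oracle_window_gc(s, 20L)
    expect_length(w100, 201L)  # L - w + 1 windows
    v <- gcFeatures(s)
    expect_equal(v[["dGC"]], max(w100) - min(w100))
    expect_equal(v[["GC_min"]], min(w100))
    expect_equal(v[["GC_max"]], max(w100))
    expect_equal(v[["GC_long_l"]], sum(w100 < 0.30))
    expect_equal(v[["GC_long_h"]], sum(w100 > 0.70))
    expect_equal(v[["GC_short_l"]], sum(w20 < 0.40))
    expect_equal(v[["GC_short_h"]], sum(w20 > 0.60))
  }
})

test_that("sequences shorter than a window yield one whole-sequence window", {
  s <- paste0(strrep("G", 30), strrep("A", 30))  # 60 bp < 100
  v <- gcFeatures(s)
  expect_equal(v[["GC_min"]], 0.5)
  expect_equal(v[["GC_max"]], 0.5)
  expect_equal(v[["dGC"]], 0)
})

test_that("nearest-neighbor Tm matches an independent evaluation of the unified tables", {
  # reference values computed from a published-parameter implementation of
  # the unified nearest-neighbor model at 50 mM Na+, 0.5 uM total strands
  ref <- c(
    "GGCAGGGGGGGGGGGGGGGG" = 72.980934,
    "ATCGGCTAAGCTGGATCCGA" = 58.159548,
    "TTTTAAAATTTTAAAATTTT" = 36.576253,
    "GCGCGCGCATATATATGCGC" = 60.824953,
    "AGCTTAGGCTTAAGGCCTAG" = 53.735571,
    "ACGTACGTACGTACGTACGT" = 57.059546,  # self-complementary duplex
    "ACGGATTTACGGATCCGATGGCATCGATCGGATTACGGCA" = 70.909814)
  for (s in names(ref))
    expect_equal(tmFeatures(s)[["Tm_global"]], unname(ref[s]),
                 tolerance = 0.5 / 60)
})

test_that("Tm window extremes are consistent and GC raises Tm", {
  for (seed in 1:5) {
    s <- oracle_random_seq(120L, seed + 30L)
    v <- tmFeatures(s)
    expect_lte(v[["Tm_low"]], v[["Tm_high"]])
    # duplex stability grows with length, so the whole-sequence Tm sits
    # above the weakest 20 bp window
    expect_gte(v[["Tm_global"]], v[["Tm_low"]])
  }
  # for a 20-mer the window and the sequence coincide
  s20 <- oracle_random_seq(20L, 77L)
  v20 <- tmFeatures(s20)
  expect_equal(v20[["Tm_low"]], v20[["Tm_global"]])
  expect_equal(v20[["Tm_high"]], v20[["Tm_global"]])

  expect_gt(tmFeatures(strrep("G", 40))[["Tm_global"]],
            tmFeatures(strrep("A", 40))[["Tm_global"]])
  expect_error(tmFeatures(strrep("A", 19)), "length >= 20")
})
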