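test_that("repeat statistics match constructed examples", {
  v <- repeatFeatures("AAAACCCGTG")
  expect_equal(v[["rep_polyA"]], 4)
  expect_equal(v[["rep_polyC"]], 3)
  expect_equal(v[["rep_poly_max"]], 4)

  expect_equal(repeatFeatures("ACGTACGTGG")[["rep_longest_direct"]], 4)
  expect_equal(repeatFeatures("AAAAATTTTT")[["rep_longest_inverted"]], 5)

  # tandem: AC repeated 4x inside distinct flanks
  v2 <- repeatFeatures(paste0("GGT", "ACACACAC", "TGG"))
  expect_equal(v2[["rep_longest_tandem"]], 8)
  expect_equal(v2[["rep_dinuc_tandem"]], 8)

  # palindromic site: GAATTC (EcoRI) is its own reverse complement
  v3 <- repeatFeatures("TTGAATTCTT")
  expect_gte(v3[["rep_longest_palindrome"]], 6)
  expect_error(repeatFeatures("ACGTACGTA"), "length >= 10")
})

test_that("repeat features equal brute-force scans on random sequences", {
  for (seed in 1:6) {
    L <- c(60L, 120L, 200L)[(seed %% 3) + 1L]
    s <- oracle_random_seq(L, seed + 40L)
    v <- repeatFeatures(s)
    expect_equal(v[["rep_longest_direct"]], oracle_longest_direct(s))
    expect_equal(v[["rep_longest_inverted"]], oracle_longest_inverted(s))
    expect_equal(v[["rep_inverted10_count"]], oracle_inverted10_count(s))
    ch <- strsplit(s, "")[[1]]
    r <- rle(ch)
    expect_equal(v[["rep_polyrun5_count"]], sum(r$lengths >= 5))
  }
})

test_that("planted hairpin is found exactly once with its stem and loop", {
  s <- paste0(strrep("A", 40), "GGGGGG", "TTTT", "CCCCCC", strrep("A", 44))
  v <- structureFeatures(s)
  expect_equal(v[["hp_count"]], 1)
  expect_equal(v[["hp_longest_stem"]], 6)
  expect_equal(v[["hp_min_loop"]], 4)
  expect_equal(v[["hp_stem_gc_max"]], 1)
  expect_equal(v[["hp_strong_count"]], 0)

  expect_equal(unname(structureFeatures(strrep("A", 100))), rep(0, 7))
  expect_error(structureFeatures(strrep("ACG", 6)), "length >= 20")
})

test_that("hairpin sets equal the definition-level enumeration oracle", {
  for (seed in 1:4) {
    s <- oracle_random_seq(300L, seed + 50L)
    ch <- strsplit(s, "")[[1]]
    comp <- chartr("ACGT", "TGCA", ch)
    mine <- synthscreen:::.enumerate_hairpins(ch, comp)
    mine <- mine[order(mine$start, mine$end), , drop = FALSE]
    theirs <- oracle_hairpins(s)
    expect_equal(unname(as.matrix(mine)), unname(as.matrix(theirs)))
  }
})

test_that("restriction counts match the overlap-aware regex oracle", {
  expect_equal(restrictionFeatures("AAGGGCCCAA")[["site_ApaI"]], 1)
  expect_equal(restrictionFeatures("GGGCCCGGGCCC")[["site_ApaI"]], 2)
  # non-palindromic site counted on both strands (BsaI: GGTCTC / GAGACC)
  s <- paste0(strrep("A", 12), "GGTCTC", strrep("T", 6), "GAGACC")
  expect_equal(restrictionFeatures(s)[["site_BsaI"]], 2)

  for (seed in 1:3) {
    s <- oracle_random_seq(500L, seed + 60L)
    expect_equal(unname(restrictionFeatures(s)),
                 unname(oracle_restriction_counts(s)))
  }
})
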