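test_that("composition frequencies match definitions and sum to one per k-block", {
  v <- compositionFeatures("ACGT")
  expect_equal(unname(v[c("comp_A", "comp_C", "comp_G", "comp_T")]),
               rep(0.25, 4))
  expect_equal(compositionFeatures("AAATTT")[["comp_AAA"]], 1 / 4)
  expect_error(compositionFeatures("AC"), "length >= 3")

  for (seed in 1:5) {
    s <- oracle_random_seq(150L, seed)
    v <- compositionFeatures(s)
    expect_equal(sum(v[1:4]), 1, tolerance = 1e-9)
    expect_equal(sum(v[5:20]), 1, tolerance = 1e-9)
    expect_equal(sum(v[21:84]), 1, tolerance = 1e-9)
    # against naive per-position counting
    tri <- oracle_kmer_table(s, 3L)
    expect_equal(v[["comp_AAA"]],
                 as.numeric(tri["AAA"] %||% 0) / (150 - 2))
  }
})

test_that("k-mer counts equal a naive substring scan", {
  v <- kmerFeatures("GGGGG")
  expect_equal(v[["kmer_n_GG"]], 4)
  expect_equal(v[["kmer_n_GGG"]], 3)
  expect_equal(sum(kmerFeatures("ACGT")[sprintf("kmer_n_%s",
    c("AA","AC","AG","AT","CA","CC","CG","CT","GA","GC","GG","GT",
      "TA","TC","TG","TT"))]), 3)

  s <- oracle_random_seq(100L, 7L)
  v <- kmerFeatures(s)
  t2 <- oracle_kmer_table(s, 2L)
  t3 <- oracle_kmer_table(s, 3L)
  for (w in names(t2))
    expect_equal(v[[paste0("kmer_n_", w)]], as.numeric(t2[w]))
  for (w in names(t3))
    expect_equal(v[[paste0("kmer_n_", w)]], as.numeric(t3[w]))
  # strand-collapsed frequency pools a trimer with its reverse complement
  n_cag <- as.numeric(t3["CAG"] %||% 0) + as.numeric(t3["CTG"] %||% 0)
  expect_equal(v[["kmer_rc_CAG"]], n_cag / (100 - 2))
})

test_that("ANF signal matches the prefix-count oracle and starts at 1", {
  v <- anfFeatures(strrep("A", 50))
  expect_equal(unname(v[1:20]), rep(1, 20))
  expect_equal(v[["anf_mean"]], 1)
  expect_equal(v[["anf_var"]], 0)

  s <- strrep("AC", 20)
  a <- oracle_anf(s)
  v <- anfFeatures(s)
  idx <- round(seq(1, 40, length.out = 20))
  expect_equal(unname(v[1:20]), a[idx])
  expect_equal(v[["anf_mean"]], mean(a))

  for (seed in 1:5) {
    s <- oracle_random_seq(80L, seed + 10L)
    expect_equal(anfFeatures(s)[["anf_p01"]], 1)
  }
  expect_error(anfFeatures(strrep("A", 21)), "length >= 22")
})

test_that("EIIP spectra match a direct DFT evaluation", {
  v <- eiipFeatures(strrep("A", 100))
  expect_equal(v[["eiip_mean"]], 0.1260)
  expect_equal(v[["eiip_var"]], 0)
  expect_equal(sum(v[3:40]), 0)

  # period-2 signal concentrates power at frequency 0.5 (last bin)
  v2 <- eiipFeatures(strrep("AG", 50))
  expect_equal(which.max(v2[3:40]), 38L, ignore_attr = TRUE)

  s <- oracle_random_seq(200L, 3L)
  eiip <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  x <- eiip[strsplit(s, "")[[1]]]
  pow <- oracle_periodogram(x)
  f <- seq_along(pow) / 200
  bins <- numeric(38)
  for (k in seq_along(pow)) {
    b <- min(max(ceiling(f[k] * 76 - 1e-9), 1L), 38L)
    bins[b] <- bins[b] + pow[k]
  }
  v3 <- eiipFeatures(s)
  expect_equal(unname(v3[3:40]), bins, tolerance = 1e-8)
  expect_error(eiipFeatures(strrep("A", 39)), "length >= 40")
})

test_that("specific motif features match a constructed sequence", {
  v <- specificFeatures(strrep("A", 30))
  expect_equal(v[["spec_run5_A"]], 1)
  expect_equal(v[["spec_term5_run4"]], 1)
  expect_equal(v[["spec_term3_run4"]], 1)
  expect_equal(v[["spec_gc_first30"]], 0)
  expect_equal(v[["spec_gc_last30"]], 0)

  v2 <- specificFeatures(strrep("ACGT", 8))
  expect_equal(unname(v2[1:8]), rep(0, 8))

  s <- paste0("AAAAAAAA", "GGGGG", "ATATATAT", "GCGCGC", "CCCC",
              strrep("T", 9))
  v3 <- specificFeatures(s)
  expect_equal(v3[["spec_run8_A"]], 1)
  expect_equal(v3[["spec_run5_A"]], 1)
  expect_equal(v3[["spec_GGGG"]], 2)    # GGGGG has two overlapping GGGG
  expect_equal(v3[["spec_CCCC"]], 2)    # GCGCGC+CCCC ends in CCCCC
  expect_equal(v3[["spec_AT3"]], 1)     # one maximal (AT)>=3 tandem
  expect_equal(v3[["spec_GC3"]], 1)
  expect_equal(v3[["spec_gquad_len"]], 5)
  expect_equal(v3[["spec_GCGCGC"]], 1)
  expect_equal(v3[["spec_ATATAT"]], 2)  # overlapping occurrences
  expect_equal(v3[["spec_run5_T"]], 1)
  expect_equal(v3[["spec_run8_T"]], 1)
})
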