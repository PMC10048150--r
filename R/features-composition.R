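#' @include features-windows.R
NULL

# overlapping k-mer counts in manifest (lexicographic) order
.kmer_counts <- function(ch, k) {
  L <- length(ch)
  n <- L - k + 1L
  univ <- .kmers(k)
  if (n < 1L) return(setNames(integer(length(univ)), univ))
  words <- ch[seq_len(n)]
  if (k > 1L) for (j in 2:k) words <- paste0(words, ch[j:(n + j - 1L)])
  cnt <- table(factor(words, levels = univ))
  setNames(as.integer(cnt), univ)
}

#' Nucleotide composition features
#'
#' Mono-, di- and trinucleotide frequencies (4 + 16 + 64 = 84 values) in
#' fixed lexicographic order; each k-mer count is divided by the number of
#' k-mer positions, L - k + 1, so each k-block sums to one.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 84 (`comp_A` ... `comp_TTT`).
#' @export
compositionFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 3L) stop("compositionFeatures requires length >= 3")
  ch <- .chars(s)
  out <- c(.kmer_counts(ch, 1L) / L,
           .kmer_counts(ch, 2L) / (L - 1L),
           .kmer_counts(ch, 3L) / (L - 2L))
  setNames(out, paste0("comp_", names(out)))
}

#' K-mer count features
#'
#' Raw overlapping dinucleotide counts (16), raw trinucleotide counts (64),
#' and strand-collapsed trinucleotide frequencies (32): each trinucleotide
#' is pooled with its reverse complement and the pooled count divided by
#' L - 2, keyed by the lexicographically smaller member of the pair.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 112.
#' @export
kmerFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 3L) stop("kmerFeatures requires length >= 3")
  ch <- .chars(s)
  n2 <- .kmer_counts(ch, 2L)
  n3 <- .kmer_counts(ch, 3L)
  canon <- .rc_canonical_trimers()
  pooled <- n3[canon] + n3[.revcomp_chr(canon)]
  c(setNames(as.numeric(n2), paste0("kmer_n_", names(n2))),
    setNames(as.numeric(n3), paste0("kmer_n_", names(n3))),
    setNames(as.numeric(pooled) / (L - 2L), paste0("kmer_rc_", canon)))
}

#' Accumulated nucleotide frequency features
#'
#' The ANF signal a(i) is the frequency of the base at position i within
#' the prefix ending at i; a(1) is always 1. Features: a sampled at 20
#' evenly spaced positions (first and last included) plus the mean and
#' (sample) variance of the full signal.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 22 (`anf_p01` ... `anf_p20`,
#'   `anf_mean`, `anf_var`).
#' @export
anfFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 22L) stop("anfFeatures requires length >= 22")
  ch <- .chars(s)
  cum <- vapply(BASES, function(b) cumsum(ch == b), numeric(L))
  a <- cum[cbind(seq_len(L), match(ch, BASES))] / seq_len(L)
  idx <- round(seq(1L, L, length.out = 20L))
  c(setNames(a[idx], sprintf("anf_p%02d", 1:20)),
    anf_mean = mean(a), anf_var = var(a))
}

# electron-ion interaction potential of each base
.EIIP <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

#' Electron-ion interaction potential spectral features
#'
#' Maps the sequence to its EIIP signal (A 0.1260, C 0.1340, G 0.0806,
#' T 0.1335) and summarizes it by the signal mean, the sample variance, and
#' the periodogram power of the mean-removed signal aggregated into 38
#' equal-width frequency bins over (0, 0.5] cycles/bp (power at frequency
#' k/L is |X_k|^2 / L).
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 40.
#' @export
eiipFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 40L) stop("eiipFeatures requires length >= 40")
  x <- .EIIP[.chars(s)]
  bins <- numeric(38L)
  kmax <- L %/% 2L
  X <- fft(x - mean(x))
  pow <- Mod(X[1L + seq_len(kmax)])^2 / L
  f <- seq_len(kmax) / L
  idx <- pmin(pmax(ceiling(f * 76 - 1e-9), 1L), 38L)
  agg <- tapply(pow, idx, sum)
  bins[as.integer(names(agg))] <- agg
  c(eiip_mean = mean(x), eiip_var = var(x),
    setNames(bins, sprintf("eiip_bin%02d", 1:38)))
}

# count of overlapping exact occurrences of a plain pattern
.count_occ <- function(ch, pattern) {
  k <- nchar(pattern)
  n <- length(ch) - k + 1L
  if (n < 1L) return(0L)
  p <- .chars(pattern)
  hit <- ch[seq_len(n)] == p[1L]
  if (k > 1L) for (j in 2:k) hit <- hit & ch[j:(n + j - 1L)] == p[j]
  sum(hit)
}

#' Specific motif and terminal features
#'
#' Twenty motif, run and terminal-composition statistics known to matter for
#' oligonucleotide synthesis and assembly: per-base run counts (>= 5 and
#' >= 8), G/C quartet motif counts, maximal (AT)>=3 / (GC)>=3 tandems,
#' terminal 30 bp GC fractions, terminal 10 bp homopolymer-run indicators,
#' near-monobase 20 bp window count, longest G-quartet run, and GCGCGC /
#' ATATAT motif counts.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 20.
#' @export
specificFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 30L) stop("specificFeatures requires length >= 30")
  ch <- .chars(s)
  run5 <- vapply(BASES, function(b) sum(.run_lengths(ch, b) >= 5L), numeric(1))
  run8 <- vapply(BASES, function(b) sum(.run_lengths(ch, b) >= 8L), numeric(1))
  n_tandem <- function(unit) {
    m <- gregexpr(sprintf("(?:%s){3,}", unit), s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  gc01 <- as.numeric(ch == "G" | ch == "C")
  mono90 <- {
    wmax <- do.call(pmax, lapply(BASES, function(b)
      .window_means(as.numeric(ch == b), 20L)))
    sum(wmax >= 0.9)
  }
  g_runs <- .run_lengths(ch, "G")
  gquad <- if (any(g_runs >= 4L)) max(g_runs[g_runs >= 4L]) else 0L
  term_run4 <- function(chunk) as.numeric(max(rle(chunk)$lengths) >= 4L)
  c(setNames(run5, paste0("spec_run5_", BASES)),
    setNames(run8, paste0("spec_run8_", BASES)),
    spec_GGGG = .count_occ(ch, "GGGG"),
    spec_CCCC = .count_occ(ch, "CCCC"),
    spec_AT3 = n_tandem("AT"),
    spec_GC3 = n_tandem("GC"),
    spec_gc_first30 = mean(gc01[1:30]),
    spec_gc_last30 = mean(gc01[(L - 29L):L]),
    spec_term5_run4 = term_run4(ch[1:10]),
    spec_term3_run4 = term_run4(ch[(L - 9L):L]),
    spec_win20_mono90 = mono90,
    spec_gquad_len = gquad,
    spec_GCGCGC = .count_occ(ch, "GCGCGC"),
    spec_ATATAT = .count_occ(ch, "ATATAT"))
}
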