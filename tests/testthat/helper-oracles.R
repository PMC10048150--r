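# Independent brute-force oracles. These deliberately avoid the package's
# algorithms (binary search, last-occurrence tables, banded diagonal scans,
# word tallies) in favor of direct definition-level scans.

oracle_random_seq <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# overlapping occurrences of `word` by per-position substr comparison
oracle_count_word <- function(s, word) {
  k <- nchar(word)
  L <- nchar(s)
  if (L < k) return(0L)
  sum(vapply(seq_len(L - k + 1L),
             function(i) substr(s, i, i + k - 1L) == word, logical(1)))
}

# GC fraction of every width-w window via substring counting
oracle_window_gc <- function(s, w) {
  L <- nchar(s)
  if (L <= w) {
    win <- s
    return(vapply(win, function(x) {
      ch <- strsplit(x, "")[[1]]
      mean(ch %in% c("G", "C"))
    }, numeric(1), USE.NAMES = FALSE))
  }
  vapply(seq_len(L - w + 1L), function(i) {
    ch <- strsplit(substr(s, i, i + w - 1L), "")[[1]]
    mean(ch %in% c("G", "C"))
  }, numeric(1))
}

# longest duplicated substring by ascending linear scan with sort-based
# duplicate detection
oracle_longest_direct <- function(s) {
  L <- nchar(s)
  best <- 0L
  for (k in seq_len(L - 1L)) {
    subs <- substring(s, seq_len(L - k + 1L), k:L)
    srt <- sort(subs)
    if (!any(srt[-1] == srt[-length(srt)])) break
    best <- k
  }
  best
}

oracle_revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# longest inverted-repeat stem by ascending scan over arm starts
oracle_longest_inverted <- function(s) {
  L <- nchar(s)
  best <- 0L
  for (k in seq_len(L %/% 2L)) {
    subs <- substring(s, seq_len(L - k + 1L), k:L)
    armrc <- oracle_revcomp(subs)
    found <- FALSE
    for (i in seq_along(subs)) {
      hits <- which(subs == armrc[i])
      if (any(hits >= i + k)) { found <- TRUE; break }
    }
    if (!found) break
    best <- k
  }
  best
}

oracle_inverted10_count <- function(s) {
  L <- nchar(s)
  k <- 10L
  if (L < 2L * k) return(0L)
  subs <- substring(s, seq_len(L - k + 1L), k:L)
  armrc <- oracle_revcomp(subs)
  sum(vapply(seq_along(subs), function(i)
    any(which(subs == armrc[i]) >= i + k), logical(1)))
}

# hairpin enumeration straight from the definition: for each innermost
# pair position e and loop g, extend the stem char by char
oracle_hairpins <- function(s, min_stem = 6L, min_loop = 3L,
                            max_loop = 48L) {
  ch <- strsplit(s, "")[[1]]
  comp <- chartr("ACGT", "TGCA", ch)
  L <- length(ch)
  hits <- list()
  for (e in seq_len(L)) {
    for (g in min_loop:max_loop) {
      j0 <- e + g + 1L
      if (j0 > L) break
      if (ch[e] != comp[j0]) next
      # canonical: no matched pair further in with a legal loop
      if (g - 2L >= min_loop && e + 1L <= L && ch[e + 1L] == comp[j0 - 1L])
        next
      k <- 1L
      while (e - k >= 1L && j0 + k <= L && ch[e - k] == comp[j0 + k])
        k <- k + 1L
      if (k >= min_stem)
        hits[[length(hits) + 1L]] <-
          c(start = e - k + 1L, end = j0 + k - 1L, stem = k, loop = g)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      stem = integer(0), loop = integer(0)))
  df <- as.data.frame(do.call(rbind, hits))
  df[order(df$start, df$end), , drop = FALSE]
}

# restriction counts via perl lookahead regex (overlap-aware), both
# strands for non-palindromic sites
oracle_restriction_counts <- function(s) {
  enz <- restrictionEnzymes()
  vapply(seq_len(nrow(enz)), function(i) {
    cnt <- function(p) {
      m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }
    n <- cnt(enz$site[i])
    if (!enz$palindromic[i]) n <- n + cnt(oracle_revcomp(enz$site[i]))
    n
  }, integer(1))
}

# k-mer counting by explicit per-position substr extraction
oracle_kmer_table <- function(s, k) {
  L <- nchar(s)
  words <- vapply(seq_len(L - k + 1L),
                  function(i) substr(s, i, i + k - 1L), character(1))
  table(words)
}

# accumulated nucleotide frequency by per-position prefix counting
oracle_anf <- function(s) {
  ch <- strsplit(s, "")[[1]]
  vapply(seq_along(ch), function(i) sum(ch[1:i] == ch[i]) / i, numeric(1))
}

# direct discrete-Fourier evaluation of periodogram power at freq k/L
oracle_periodogram <- function(x) {
  L <- length(x)
  y <- x - mean(x)
  vapply(seq_len(L %/% 2L), function(k) {
    w <- exp(-2i * pi * k * (0:(L - 1L)) / L)
    Mod(sum(y * w))^2 / L
  }, numeric(1))
}

# metric recomputation through independent routes: F1 via precision and
# recall, MCC as the Pearson correlation of the 0/1 vectors, kappa via
# e1071's classAgreement
oracle_metrics <- function(tp, fp, tn, fn) {
  truth <- rep(c(1, 0, 0, 1), c(tp, fp, tn, fn))
  pred <- rep(c(1, 1, 0, 0), c(tp, fp, tn, fn))
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else 0
  mcc <- suppressWarnings(cor(truth, pred))
  if (is.na(mcc)) mcc <- 0
  tab <- table(factor(truth, levels = c(0, 1)),
               factor(pred, levels = c(0, 1)))
  ck <- e1071::classAgreement(tab)$kappa
  if (is.na(ck)) ck <- 0
  list(F1 = f1, MCC = mcc, CK = ck)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
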