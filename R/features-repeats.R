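#' @include features-composition.R
NULL

# substrings of length k starting at every position (1..L-k+1)
.all_subs <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, seq_len(L - k + 1L), k:L)
}

# does any length-k substring occur at two distinct positions?
.has_dup_of_len <- function(s, k) {
  subs <- .all_subs(s, k)
  length(subs) > 1L && anyDuplicated(subs) > 0L
}

# longest k with a duplicated substring (0 if none); binary search is valid
# because a duplicated (k+1)-mer contains a duplicated k-mer
.longest_direct_repeat <- function(s) {
  L <- nchar(s)
  if (!.has_dup_of_len(s, 1L)) return(0L)
  lo <- 1L; hi <- L - 1L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (.has_dup_of_len(s, mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# last occurrence index of each distinct value (named by value)
.last_pos <- function(x) {
  ri <- rev(seq_along(x))
  keep <- !duplicated(rev(x))
  setNames(ri[keep], rev(x)[keep])
}

# is there an inverted repeat with stem k (arms disjoint: right arm start
# >= left arm start + k)?  rc(s)[p..p+k-1] == rc of arm starting at
# i = L - p - k + 2, so shared k-mers between s and rc(s) encode arm pairs.
.has_inverted_stem <- function(s, rcs, k) {
  L <- nchar(s)
  if (2L * k > L) return(FALSE)
  subs <- .all_subs(s, k)
  subr <- .all_subs(rcs, k)
  j_max <- .last_pos(subs)                    # right arm candidates
  p_max <- .last_pos(subr)                    # encode left arm candidates
  common <- intersect(names(j_max), names(p_max))
  i_min <- L - p_max[common] - k + 2L
  any(j_max[common] >= i_min + k)
}

.longest_inverted_stem <- function(s, rcs) {
  L <- nchar(s)
  if (!.has_inverted_stem(s, rcs, 1L)) return(0L)
  lo <- 1L; hi <- L %/% 2L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (.has_inverted_stem(s, rcs, mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# number of positions i whose 10-mer arm has a downstream (j >= i + 10)
# reverse-complement occurrence
.inverted10_count <- function(s, rcs) {
  L <- nchar(s)
  k <- 10L
  if (2L * k > L) return(0L)
  subs <- .all_subs(s, k)
  subr <- .all_subs(rcs, k)
  # last occurrence position in s of each candidate arm's reverse complement
  rc_at_i <- subr[L - seq_along(subs) - k + 2L]
  last_pos <- setNames(
    rev(seq_along(subs))[!duplicated(rev(subs))],
    rev(subs)[!duplicated(rev(subs))])
  j_max <- last_pos[rc_at_i]
  sum(!is.na(j_max) & j_max >= seq_along(subs) + k)
}

# longest run with period u (total length, >= 2 full copies required)
.longest_period_run <- function(ch, u, need_alternating = FALSE) {
  L <- length(ch)
  if (L < 2L * u) return(0L)
  eq <- ch[seq_len(L - u)] == ch[(u + 1L):L]
  r <- rle(eq)
  best <- 0L
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] < u) next
    start <- pos[i]
    if (need_alternating && ch[start] == ch[start + 1L]) {
      # a period-2 run of a homopolymer is not a dinucleotide tandem; an
      # alternating stretch inside it cannot be longer, so skip
      next
    }
    best <- max(best, r$lengths[i] + u)
  }
  best
}

# a unit-u tandem implies a direct repeat of length >= u at offset u, so
# units beyond the longest direct repeat need not be scanned
.longest_tandem <- function(ch, max_unit = length(ch) %/% 2L) {
  L <- length(ch)
  best <- 0L
  if (max_unit < 2L) return(best)
  for (u in 2:max_unit) {
    if (2L * u > L) next
    best <- max(best, .longest_period_run(ch, u))
  }
  best
}

# longest even-length palindromic site (== its own reverse complement),
# by expansion around each adjacent complementary pair
.longest_palindrome <- function(ch, comp) {
  L <- length(ch)
  centers <- which(ch[seq_len(L - 1L)] == comp[2:L])
  best <- 0L
  for (i in centers) {
    m <- 1L
    while (i - m >= 1L && i + 1L + m <= L && ch[i - m] == comp[i + 1L + m])
      m <- m + 1L
    best <- max(best, 2L * m)
  }
  best
}

#' Repeat structure features
#'
#' Fifteen statistics of direct, tandem, inverted and homopolymeric
#' repetition. Direct repeats are exact substrings occurring at two
#' distinct (possibly overlapping) positions. Tandem runs report the total
#' length of the longest perfectly periodic stretch (unit >= 2 bp, at least
#' two full copies; a trailing partial copy counts toward the length).
#' Inverted repeats pair an arm with a downstream exact reverse-complement
#' arm (disjoint arms, any spacing). Palindromic sites are even-length
#' substrings equal to their own reverse complement.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 15 (manifest group `repeat`).
#' @examples
#' repeatFeatures("ACGTACGTGGAT")[["rep_longest_direct"]]  # 4
#' @export
repeatFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 10L) stop("repeatFeatures requires length >= 10")
  ch <- .chars(s)
  comp <- .comp_chars(ch)
  rcs <- paste(rev(comp), collapse = "")

  subs10 <- .all_subs(s, 10L)
  dup10_vals <- unique(subs10[duplicated(subs10)])
  covered <- logical(L)
  for (i in which(subs10 %in% dup10_vals)) covered[i:(i + 9L)] <- TRUE
  subs20 <- .all_subs(s, 20L)
  dup20 <- length(unique(subs20[duplicated(subs20)]))

  poly <- vapply(BASES, function(b) {
    runs <- .run_lengths(ch, b)
    if (length(runs)) max(runs) else 0L
  }, integer(1))
  all_runs <- rle(ch)$lengths

  longest_direct <- .longest_direct_repeat(s)
  c(rep_longest_direct = longest_direct,
    rep_dup10_distinct = length(dup10_vals),
    rep_dup20_distinct = dup20,
    rep_cov10_frac = mean(covered),
    rep_longest_tandem = .longest_tandem(
      ch, max_unit = min(longest_direct, L %/% 2L)),
    rep_longest_inverted = .longest_inverted_stem(s, rcs),
    rep_inverted10_count = .inverted10_count(s, rcs),
    rep_longest_palindrome = .longest_palindrome(ch, comp),
    rep_polyA = poly[["A"]], rep_polyC = poly[["C"]],
    rep_polyG = poly[["G"]], rep_polyT = poly[["T"]],
    rep_poly_max = max(poly),
    rep_dinuc_tandem = .longest_period_run(ch, 2L, need_alternating = TRUE),
    rep_polyrun5_count = sum(all_runs >= 5L))
}

# Canonical hairpin enumeration.  A hairpin is a locally maximal stem-loop:
# left arm [i_lo..e], loop (e, e+g], right arm of the same length, with the
# right arm the exact reverse complement of the left arm, stem >= min_stem,
# loop length g in [min_loop, max_loop].  Pairs of one hairpin share the
# index sum c = i + j; walking each anti-diagonal and taking maximal match
# runs yields every hairpin exactly once (the innermost pair is maximal
# subject to loop >= min_loop).
.enumerate_hairpins <- function(ch, comp, min_stem = 6L, min_loop = 3L,
                                max_loop = 48L) {
  L <- length(ch)
  out <- list()
  # only the band of innermost pairs allowed by the loop bounds needs a
  # scan per center; stems then extend outward along the anti-diagonal
  for (cc in (2L + min_loop + 1L):(2L * L - min_loop - 1L)) {
    band_hi <- (cc - min_loop - 1L) %/% 2L  # innermost pair allowed by loop
    band_lo <- max(1L, cc - L, (cc - max_loop - 1L + 1L) %/% 2L)
    if (band_hi < band_lo) next
    ii <- band_lo:band_hi
    m <- ch[ii] == comp[cc - ii]
    if (!any(m)) next
    # canonical innermost pairs: matched, with no matched pair further in
    inner <- m & c(m[-1L] == FALSE, TRUE)
    for (e in ii[inner]) {
      k <- 1L
      lim <- max(1L, cc - L)
      while (e - k >= lim && ch[e - k] == comp[cc - e + k]) k <- k + 1L
      if (k < min_stem) next
      g <- cc - 2L * e - 1L
      i_lo <- e - k + 1L
      out[[length(out) + 1L]] <-
        c(start = i_lo, end = cc - i_lo, stem = k, loop = g)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      stem = integer(0), loop = integer(0)))
  as.data.frame(do.call(rbind, out))
}

#' Hairpin (secondary structure) features
#'
#' Detects hairpins as exact inverted repeats with stem >= 6 bp and loop
#' 3-48 bp (see [repeatFeatures()] for the arm convention) and summarizes
#' them in seven statistics: hairpin count, longest stem, maximum stem GC
#' fraction, strong-hairpin (stem >= 10) count, minimum loop length (0 when
#' no hairpin), and indicators for a hairpin starting in the first 50 bp or
#' ending in the last 50 bp. Detection is combinatorial (exact
#' complementarity), not a thermodynamic fold.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector of length 7 (manifest group `structure`).
#' @export
structureFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 20L) stop("structureFeatures requires length >= 20")
  ch <- .chars(s)
  comp <- .comp_chars(ch)
  hp <- .enumerate_hairpins(ch, comp)
  if (!nrow(hp)) {
    return(c(hp_count = 0, hp_longest_stem = 0, hp_stem_gc_max = 0,
             hp_strong_count = 0, hp_min_loop = 0, hp_first50 = 0,
             hp_last50 = 0))
  }
  stem_gc <- vapply(seq_len(nrow(hp)), function(r) {
    arm <- ch[hp$start[r]:(hp$start[r] + hp$stem[r] - 1L)]
    mean(arm == "G" | arm == "C")
  }, numeric(1))
  c(hp_count = nrow(hp),
    hp_longest_stem = max(hp$stem),
    hp_stem_gc_max = max(stem_gc),
    hp_strong_count = sum(hp$stem >= 10L),
    hp_min_loop = min(hp$loop),
    hp_first50 = as.numeric(any(hp$start <= 50L)),
    hp_last50 = as.numeric(any(hp$end >= L - 49L)))
}
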