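#' @include manifest.R
NULL

# --- small shared helpers ------------------------------------------------

# coerce a single validated sequence to an uppercase character scalar
.seq_chr <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
    if (length(seq) != 1L) stop("expected a single sequence")
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  unname(toupper(seq))
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.comp_chars <- function(ch) chartr("ACGT", "TGCA", ch)

# sliding-window means of a 0/1 indicator, width w, step 1;
# a sequence shorter than w yields one whole-sequence window
.window_means <- function(ind, w) {
  L <- length(ind)
  if (L <= w) return(mean(ind))
  cs <- cumsum(ind)
  (cs[w:L] - c(0, cs[seq_len(L - w)])) / w
}

.run_lengths <- function(ch, base) {
  r <- rle(ch == base)
  runs <- r$lengths[r$values]
  if (length(runs)) runs else integer(0)
}

# --- GC content features -------------------------------------------------

#' Sliding-window GC content features
#'
#' Eight statistics of global and local GC content. Local anomalies are
#' scored on 20 bp (short) and 100 bp (long) windows sliding by 1 bp; `dGC`
#' is the spread (max - min) of the 100 bp window GC fraction, a measure of
#' GC fluctuation along the sequence. Window count cutoffs are strict
#' inequalities: long windows below 30% / above 70% GC, short windows below
#' 40% / above 60%. A sequence shorter than a window contributes one
#' whole-sequence window.
#'
#' @param seq A validated A/C/G/T sequence (character scalar or `DNAString`).
#' @return Named numeric vector of length 8: `GC_global`, `dGC`,
#'   `GC_short_l`, `GC_short_h`, `GC_long_l`, `GC_long_h`, `GC_min`,
#'   `GC_max`.
#' @examples
#' gcFeatures(strrep("G", 150))[c("GC_global", "GC_long_h")]
#' @export
gcFeatures <- function(seq) {
  s <- .seq_chr(seq)
  if (!nzchar(s)) stop("empty sequence")
  ch <- .chars(s)
  gc <- as.numeric(ch == "G" | ch == "C")
  w100 <- .window_means(gc, 100L)
  w20 <- .window_means(gc, 20L)
  c(GC_global = mean(gc),
    dGC = max(w100) - min(w100),
    GC_short_l = sum(w20 < 0.40),
    GC_short_h = sum(w20 > 0.60),
    GC_long_l = sum(w100 < 0.30),
    GC_long_h = sum(w100 > 0.70),
    GC_min = min(w100),
    GC_max = max(w100))
}

# --- melting temperature features ----------------------------------------

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); all 16 stacks via reverse-complement symmetry.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

TM_NA_MOLAR <- 0.05      # 50 mM Na+
TM_STRAND_MOLAR <- 5e-7  # 0.5 uM total strand concentration
.R_GAS <- 1.987          # cal/(mol K)

# Tm of one duplex from precomputed per-stack dH/dS vectors over [from, to]
.tm_span <- function(ch, dh_cum, ds_cum, from, to) {
  dH <- dh_cum[to - 1L] - if (from > 1L) dh_cum[from - 1L] else 0
  dS <- ds_cum[to - 1L] - if (from > 1L) ds_cum[from - 1L] else 0
  ends <- ch[c(from, to)]
  ngc <- sum(ends == "G" | ends == "C")
  dH <- dH + 0.1 * ngc + 2.3 * (2 - ngc)
  dS <- dS + (-2.8) * ngc + 4.1 * (2 - ngc)
  span <- ch[from:to]
  selfcomp <- identical(span, rev(.comp_chars(span)))
  if (selfcomp) dS <- dS - 1.4
  x <- if (selfcomp) 1 else 4
  n <- to - from + 1L
  dS <- dS + 0.368 * (n - 1L) * log(TM_NA_MOLAR)
  unname(1000 * dH / (dS + .R_GAS * log(TM_STRAND_MOLAR / x)) - 273.15)
}

#' Nearest-neighbor melting temperature features
#'
#' Duplex melting temperatures from the unified nearest-neighbor
#' thermodynamic parameter set, at 50 mM Na+ (entropic salt correction
#' 0.368 (n-1) ln\[Na+\]) and 0.5 uM total strand concentration, with the
#' symmetry correction for self-complementary duplexes. `Tm_low` / `Tm_high`
#' are the extremes over all 20 bp windows (step 1); `Tm_global` is the Tm
#' of the whole sequence. A low `Tm_low` flags weakly annealing regions that
#' compromise oligonucleotide assembly.
#'
#' @inheritParams gcFeatures
#' @return Named numeric vector: `Tm_low`, `Tm_high`, `Tm_global` (degrees
#'   Celsius).
#' @export
tmFeatures <- function(seq) {
  s <- .seq_chr(seq)
  L <- nchar(s)
  if (L < 20L) stop("tmFeatures requires length >= 20")
  ch <- .chars(s)
  stacks <- paste0(ch[-L], ch[-1L])
  dh_cum <- cumsum(.NN_DH[stacks])
  ds_cum <- cumsum(.NN_DS[stacks])
  starts <- seq_len(L - 20L + 1L)
  wtm <- vapply(starts, function(i)
    .tm_span(ch, dh_cum, ds_cum, i, i + 19L), numeric(1))
  c(Tm_low = min(wtm), Tm_high = max(wtm),
    Tm_global = .tm_span(ch, dh_cum, ds_cum, 1L, L))
}
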