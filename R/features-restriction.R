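#' @include features-repeats.R
NULL

#' Restriction site features
#'
#' Occurrence counts (overlaps allowed) of the recognition sites of the 114
#' enzymes in [restrictionEnzymes()]. Palindromic sites are counted once
#' per forward-strand position. For non-palindromic sites the forward-strand
#' match positions of the site and of its reverse complement are pooled
#' (their position sets are disjoint), making the count strand-symmetric.
#'
#' @inheritParams gcFeatures
#' @return Named integer vector of length 114 (`site_<enzyme>`).
#' @examples
#' restrictionFeatures("AAGGGCCCAA")[["site_ApaI"]]  # 1
#' @export
restrictionFeatures <- function(seq) {
  s <- .seq_chr(seq)
  if (!nzchar(s)) stop("empty sequence")
  ch <- .chars(s)
  L <- length(ch)
  enz <- restrictionEnzymes()
  rc_site <- .revcomp_chr(enz$site)
  queries <- unique(c(enz$site, rc_site[!enz$palindromic]))
  # tally all query words of each length in one pass over the windows
  tallies <- new.env(parent = emptyenv())
  for (k in sort(unique(nchar(queries)))) {
    n <- L - k + 1L
    qk <- queries[nchar(queries) == k]
    if (n < 1L) {
      for (q in qk) tallies[[q]] <- 0L
      next
    }
    words <- ch[seq_len(n)]
    for (j in 2:k) words <- paste0(words, ch[j:(n + j - 1L)])
    cnt <- tabulate(match(words, qk), nbins = length(qk))
    for (qi in seq_along(qk)) tallies[[qk[qi]]] <- cnt[qi]
  }
  counts <- vapply(seq_len(nrow(enz)), function(i) {
    n <- tallies[[enz$site[i]]]
    if (!enz$palindromic[i]) n <- n + tallies[[rc_site[i]]]
    n
  }, integer(1))
  setNames(counts, paste0("site_", enz$enzyme))
}
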