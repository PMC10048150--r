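#' @include evaluate.R
NULL

#' Specification of one synthetic sequence
#'
#' Describes a sequence to simulate: an i.i.d. background at a target GC
#' content with planted elements inserted at non-overlapping positions.
#' Supported element kinds (all lists with a `kind` field):
#' \describe{
#'   \item{tandem_repeat}{`unit` (string), `copies`}
#'   \item{direct_repeat}{`len`, `spacing` (random segment repeated after a
#'     spacer)}
#'   \item{inverted_repeat}{`stem`, `loop` (plants a hairpin)}
#'   \item{homopolymer}{`base`, `run`}
#'   \item{motif}{`motif` (literal string)}
#'   \item{low_gc_patch / high_gc_patch}{`len`, `gc` (i.i.d. patch at its
#'     own GC)}
#' }
#' Each element may carry `at` (1-based start); elements without `at` are
#' placed uniformly at random without overlap (bounded retries, then
#' error).
#'
#' @param length Sequence length in bp.
#' @param targetGC Background GC fraction, in (0, 1).
#' @param elements List of planted-element descriptions (possibly empty).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return A list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(length, targetGC = 0.5, elements = list(),
                          seed = 0L) {
  stopifnot(length >= 1L, targetGC > 0, targetGC < 1)
  structure(list(length = as.integer(length), targetGC = targetGC,
                 elements = elements, seed = as.integer(seed)),
            class = "syntheticSpec")
}

.random_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# render an element to its literal bases (under the caller's RNG)
.render_element <- function(el, gc) {
  switch(el$kind,
    tandem_repeat = rep(.chars(toupper(el$unit)), el$copies),
    direct_repeat = {
      seg <- .random_bases(el$len, gc)
      c(seg, .random_bases(el$spacing, gc), seg)
    },
    inverted_repeat = {
      arm <- .random_bases(el$stem, gc)
      c(arm, .random_bases(el$loop, gc), rev(.comp_chars(arm)))
    },
    homopolymer = rep(toupper(el$base), el$run),
    motif = .chars(toupper(el$motif)),
    low_gc_patch = .random_bases(el$len, el$gc),
    high_gc_patch = .random_bases(el$len, el$gc),
    stop("unknown element kind: ", el$kind))
}

#' Generate one synthetic sequence
#'
#' Draws background bases i.i.d. at the spec's target GC and inserts the
#' planted elements at their requested or randomly chosen non-overlapping
#' positions. Deterministic given the spec (including its seed).
#'
#' @param spec A [syntheticSpec()].
#' @param id Sequence id for the returned record.
#' @return A length-1 named `DNAStringSet`.
#' @export
generateSequence <- function(spec, id = "synth1") {
  stopifnot(inherits(spec, "syntheticSpec"))
  s <- .with_seed(spec$seed, .generate_chars(spec))
  Biostrings::DNAStringSet(setNames(paste(s, collapse = ""), id))
}

.generate_chars <- function(spec) {
  L <- spec$length
  s <- .random_bases(L, spec$targetGC)
  if (!length(spec$elements)) return(s)
  rendered <- lapply(spec$elements, .render_element, gc = spec$targetGC)
  widths <- lengths(rendered)
  if (any(widths > L)) stop("planted element longer than the sequence")
  occupied <- logical(L)
  place <- function(start, w) {
    if (start < 1L || start + w - 1L > L)
      stop("planted element exceeds the sequence bounds")
    span <- start:(start + w - 1L)
    if (any(occupied[span])) stop("planted elements overlap")
    occupied[span] <<- TRUE
    span
  }
  # fixed positions first, then random placement with bounded retries
  fixed <- !vapply(spec$elements, function(e) is.null(e$at), logical(1))
  for (i in which(fixed))
    s[place(spec$elements[[i]]$at, widths[i])] <- rendered[[i]]
  for (i in which(!fixed)) {
    w <- widths[i]
    ok <- FALSE
    for (try in 1:200) {
      start <- sample.int(L - w + 1L, 1L)
      span <- start:(start + w - 1L)
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        s[span] <- rendered[[i]]
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place element ", i, " without overlap")
  }
  s
}

#' Planted difficulty rule
#'
#' A threshold rule on true sequence properties that defines the HARD
#' class of a synthetic dataset: a sequence is HARD iff its GC fluctuation
#' `dGC` exceeds `dgcOver`, or its longest exact direct repeat is at least
#' `repeatAtLeast` bp, or it carries at least `strongHairpins` hairpins
#' with stem >= 10 bp. `noise` is the label-flip probability applied after
#' the rule.
#'
#' @param dgcOver Threshold on dGC (max - min 100 bp window GC).
#' @param repeatAtLeast Threshold on the longest direct repeat (bp).
#' @param strongHairpins Minimum count of strong (stem >= 10) hairpins.
#' @param noise Label noise rate in \[0, 1\].
#' @return A list of class `difficultyRule`.
#' @export
difficultyRule <- function(dgcOver = 0.35, repeatAtLeast = 20L,
                           strongHairpins = 1L, noise = 0) {
  stopifnot(noise >= 0, noise <= 1)
  structure(list(dgcOver = dgcOver, repeatAtLeast = as.integer(repeatAtLeast),
                 strongHairpins = as.integer(strongHairpins), noise = noise),
            class = "difficultyRule")
}

# evaluate the rule's three determinants on an actual sequence
.rule_stats <- function(s) {
  c(dGC = unname(gcFeatures(s)[["dGC"]]),
    longest_direct = unname(repeatFeatures(s)[["rep_longest_direct"]]),
    strong_hairpins = unname(structureFeatures(s)[["hp_strong_count"]]))
}

.rule_is_hard <- function(stats, rule) {
  stats[["dGC"]] > rule$dgcOver ||
    stats[["longest_direct"]] >= rule$repeatAtLeast ||
    stats[["strong_hairpins"]] >= rule$strongHairpins
}

#' Generate a labeled synthetic dataset
#'
#' Simulates `n` sequences whose HARD labels are planted by
#' [difficultyRule()]: HARD sequences carry one randomly chosen difficulty
#' determinant (a deep low-GC patch, a long direct repeat, or a strong
#' hairpin), EASY sequences are plain background. Every generated sequence
#' is checked against the rule's determinants as measured by the feature
#' extractors and regenerated (bounded retries) if the measurement
#' disagrees with the intended class, so at `noise = 0` the labels are
#' perfectly predictable from extracted features. Label noise then flips
#' each label independently with probability `rule$noise`.
#'
#' @param n Number of sequences (>= 20).
#' @param rule A [difficultyRule()].
#' @param classBalance Target HARD fraction (default 0.5).
#' @param seed Dataset seed.
#' @param length Sequence length in bp (default 500).
#' @param targetGC Background GC (default 0.5).
#' @param fastaPath,labelsPath Optional output paths; when given, the
#'   FASTA and the two-column label table are written.
#' @return A [SeqDataset]. The pre-noise planted labels are attached as
#'   attribute `plantedLabels`.
#' @export
generateDataset <- function(n, rule = difficultyRule(), classBalance = 0.5,
                            seed = 0L, length = 500L, targetGC = 0.5,
                            fastaPath = NULL, labelsPath = NULL) {
  if (n < 20L) stop("generateDataset requires n >= 20")
  stopifnot(inherits(rule, "difficultyRule"),
            classBalance > 0, classBalance < 1)
  n_hard <- round(n * classBalance)
  if (n_hard < 1L || n_hard >= n)
    stop("class balance ", classBalance, " unachievable with n = ", n)
  out <- .with_seed(seed, {
    want_hard <- sample(rep(c(TRUE, FALSE), c(n_hard, n - n_hard)))
    seqs <- character(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:25) {
        elements <- if (want_hard[i]) list(.hard_element(rule)) else list()
        spec <- syntheticSpec(length, targetGC, elements,
                              seed = sample.int(.Machine$integer.max, 1L))
        s <- paste(.with_seed(spec$seed, .generate_chars(spec)),
                   collapse = "")
        if (.rule_is_hard(.rule_stats(s), rule) == want_hard[i]) {
          seqs[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not realize the planted class for sequence ", i,
                    " after bounded retries")
    }
    planted <- ifelse(want_hard, "HARD", "EASY")
    flip <- runif(n) < rule$noise
    list(seqs = seqs, planted = planted,
         labels = ifelse(flip, ifelse(planted == "HARD", "EASY", "HARD"),
                         planted))
  })
  ids <- sprintf("synth%04d", seq_len(n))
  sset <- Biostrings::DNAStringSet(setNames(out$seqs, ids))
  labels <- setNames(factor(out$labels, levels = c("EASY", "HARD")), ids)
  ds <- seqDataset(sset, labels)
  attr(ds, "plantedLabels") <-
    setNames(factor(out$planted, levels = c("EASY", "HARD")), ids)
  if (!is.null(fastaPath)) writeSequences(sset, fastaPath)
  if (!is.null(labelsPath)) writeLabels(labels, labelsPath)
  ds
}

# one difficulty determinant, drawn under the caller's RNG, strong enough
# to trip the rule with margin
.hard_element <- function(rule) {
  kind <- sample(c("low_gc_patch", "direct_repeat", "inverted_repeat"), 1L)
  switch(kind,
    low_gc_patch = list(kind = "low_gc_patch", len = 120L, gc = 0.05),
    direct_repeat = list(kind = "direct_repeat",
                         len = rule$repeatAtLeast + 5L, spacing = 30L),
    inverted_repeat = list(kind = "inverted_repeat", stem = 12L, loop = 8L))
}
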