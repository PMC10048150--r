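#' @include AllClasses.R
NULL

BASES <- c("A", "C", "G", "T")

# all k-mers over ACGT in lexicographic order
.kmers <- function(k) {
  g <- do.call(expand.grid,
               rev(replicate(k, BASES, simplify = FALSE)))
  sort(apply(g, 1, function(r) paste(rev(r), collapse = "")))
}

.revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(z) paste(rev(z), collapse = ""),
                character(1)))
}

# canonical trinucleotides under reverse complement (lexicographic min of pair)
.rc_canonical_trimers <- function() {
  k3 <- .kmers(3)
  canon <- pmin(k3, .revcomp_chr(k3))
  sort(unique(canon))
}

#' The versioned 426-feature manifest
#'
#' Every feature the extractor computes, in its fixed order, with the group
#' it belongs to and a one-line description. The manifest is the contract
#' between extraction, normalization, selection and modeling: feature
#' matrices, normalizers, masks and model bundles all carry its version and
#' refuse to mix versions.
#'
#' Group sizes: composition 84, anf 22, eiip 40, kmer 112, repeat 15, gc 8,
#' tm 3, structure 7, specific 20, restriction 114, length 1 (426 total).
#'
#' @return data.frame with columns `name`, `group`, `description`, plus
#'   attribute `version`.
#' @examples
#' m <- featureManifest()
#' nrow(m)           # 426
#' table(m$group)
#' @export
featureManifest <- function() {
  .manifest_cache()
}

.manifest_env <- new.env(parent = emptyenv())

.manifest_cache <- function() {
  if (is.null(.manifest_env$m)) .manifest_env$m <- .build_manifest()
  .manifest_env$m
}

.build_manifest <- function() {
  k1 <- BASES; k2 <- .kmers(2); k3 <- .kmers(3)
  rc3 <- .rc_canonical_trimers()
  enz <- restrictionEnzymes()

  rows <- rbind(
    data.frame(name = paste0("comp_", k1), group = "composition",
               description = paste0("mononucleotide frequency of ", k1)),
    data.frame(name = paste0("comp_", k2), group = "composition",
               description = paste0("dinucleotide frequency of ", k2)),
    data.frame(name = paste0("comp_", k3), group = "composition",
               description = paste0("trinucleotide frequency of ", k3)),
    data.frame(name = sprintf("anf_p%02d", 1:20), group = "anf",
               description = sprintf(
                 "accumulated nucleotide frequency at relative position %d/20",
                 1:20)),
    data.frame(name = c("anf_mean", "anf_var"), group = "anf",
               description = c("mean of the ANF signal",
                               "variance of the ANF signal")),
    data.frame(name = c("eiip_mean", "eiip_var"), group = "eiip",
               description = c("mean of the EIIP signal",
                               "variance of the EIIP signal")),
    data.frame(name = sprintf("eiip_bin%02d", 1:38), group = "eiip",
               description = sprintf(
                 "periodogram power of the EIIP signal in frequency bin %d/38 over (0,0.5]",
                 1:38)),
    data.frame(name = paste0("kmer_n_", k2), group = "kmer",
               description = paste0("occurrence count of ", k2)),
    data.frame(name = paste0("kmer_n_", k3), group = "kmer",
               description = paste0("occurrence count of ", k3)),
    data.frame(name = paste0("kmer_rc_", rc3), group = "kmer",
               description = paste0(
                 "strand-collapsed trinucleotide frequency of ", rc3, "/",
                 .revcomp_chr(rc3))),
    data.frame(
      name = c("rep_longest_direct", "rep_dup10_distinct",
               "rep_dup20_distinct", "rep_cov10_frac", "rep_longest_tandem",
               "rep_longest_inverted", "rep_inverted10_count",
               "rep_longest_palindrome", "rep_polyA", "rep_polyC",
               "rep_polyG", "rep_polyT", "rep_poly_max", "rep_dinuc_tandem",
               "rep_polyrun5_count"),
      group = "repeat",
      description = c(
        "length of the longest exact direct repeat (two occurrences at distinct positions)",
        "number of distinct 10-mers occurring at least twice",
        "number of distinct 20-mers occurring at least twice",
        "fraction of positions covered by 10-mers occurring at least twice",
        "total length of the longest tandem repeat run (unit >= 2 bp, >= 2 full copies)",
        "longest inverted repeat stem (reverse-complement arm pair, disjoint arms)",
        "number of left-arm positions carrying an inverted repeat stem of >= 10 bp",
        "length of the longest even palindromic site (equal to its own reverse complement)",
        "longest A homopolymer run", "longest C homopolymer run",
        "longest G homopolymer run", "longest T homopolymer run",
        "longest homopolymer run over all four bases",
        "total length of the longest perfect dinucleotide tandem run",
        "number of homopolymer runs of length >= 5 (any base)")),
    data.frame(
      name = c("GC_global", "dGC", "GC_short_l", "GC_short_h", "GC_long_l",
               "GC_long_h", "GC_min", "GC_max"),
      group = "gc",
      description = c(
        "global GC fraction",
        "max - min GC fraction over 100 bp sliding windows (step 1)",
        "number of 20 bp windows with GC < 0.40",
        "number of 20 bp windows with GC > 0.60",
        "number of 100 bp windows with GC < 0.30",
        "number of 100 bp windows with GC > 0.70",
        "minimum 100 bp window GC fraction",
        "maximum 100 bp window GC fraction")),
    data.frame(
      name = c("Tm_low", "Tm_high", "Tm_global"),
      group = "tm",
      description = c(
        "minimum nearest-neighbor Tm over 20 bp windows (50 mM Na+, 0.5 uM strands)",
        "maximum nearest-neighbor Tm over 20 bp windows",
        "nearest-neighbor Tm of the whole sequence")),
    data.frame(
      name = c("hp_count", "hp_longest_stem", "hp_stem_gc_max",
               "hp_strong_count", "hp_min_loop", "hp_first50", "hp_last50"),
      group = "structure",
      description = c(
        "number of hairpins (stem >= 6 bp exact reverse-complement, loop 3-48 bp)",
        "longest hairpin stem", "maximum stem GC fraction over hairpins",
        "number of strong hairpins (stem >= 10 bp)",
        "minimum loop length over hairpins (0 if none)",
        "1 if a hairpin starts within the first 50 bp",
        "1 if a hairpin ends within the last 50 bp")),
    data.frame(
      name = c(paste0("spec_run5_", k1), paste0("spec_run8_", k1),
               "spec_GGGG", "spec_CCCC", "spec_AT3", "spec_GC3",
               "spec_gc_first30", "spec_gc_last30", "spec_term5_run4",
               "spec_term3_run4", "spec_win20_mono90", "spec_gquad_len",
               "spec_GCGCGC", "spec_ATATAT"),
      group = "specific",
      description = c(
        paste0("number of ", k1, " runs of length >= 5"),
        paste0("number of ", k1, " runs of length >= 8"),
        "occurrences of GGGG", "occurrences of CCCC",
        "maximal (AT) tandems with >= 3 copies",
        "maximal (GC) tandems with >= 3 copies",
        "GC fraction of the first 30 bp", "GC fraction of the last 30 bp",
        "1 if the first 10 bp contain a homopolymer run >= 4",
        "1 if the last 10 bp contain a homopolymer run >= 4",
        "number of 20 bp windows that are >= 90% one base",
        "length of the longest run of >= 4 consecutive G",
        "occurrences of GCGCGC", "occurrences of ATATAT")),
    data.frame(name = paste0("site_", enz$enzyme), group = "restriction",
               description = paste0(
                 "occurrences of the ", enz$enzyme, " site ", enz$site,
                 ifelse(enz$palindromic, " (palindromic)",
                        " (both strands)"))),
    data.frame(name = "length", group = "length",
               description = "sequence length in bp")
  )
  rownames(rows) <- NULL
  stopifnot(nrow(rows) == 426L, !anyDuplicated(rows$name))
  attr(rows, "version") <- MANIFEST_VERSION
  rows
}

#' Write the feature manifest to a tab-separated file
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path) {
  m <- featureManifest()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synthscreen feature manifest version %s",
                     attr(m, "version")), con)
  write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
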