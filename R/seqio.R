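#' @include AllClasses.R
NULL

#' Read DNA sequences from a FASTA file
#'
#' Parses a multi-record FASTA file (any line wrapping), uppercases the
#' sequences and checks id uniqueness. Validation of the alphabet is a
#' separate step ([validateSequences()]) so that a permissive read can be
#' followed by either a strict or an ambiguity-stripping policy.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]; may be empty.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", ">s2", "GGGCCC"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) return(set)
  # FASTA descriptions: id = first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA entry with empty id in ", path)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate sequence ids in ", path, ": ",
         paste(dups, collapse = ", "))
  }
  names(set) <- ids
  # readDNAStringSet uppercases; be explicit about the contract anyway
  Biostrings::DNAStringSet(toupper(as.character(set)))
}

#' Write DNA sequences to a FASTA file
#'
#' @param sequences A named `DNAStringSet` (or a `SeqDataset`).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(sequences, path, width = 70L) {
  if (is(sequences, "SeqDataset")) sequences <- sequences@sequences
  Biostrings::writeXStringSet(sequences, path, width = width)
  invisible(path)
}

#' Validate sequences against the A/C/G/T alphabet contract
#'
#' All extractors assume uppercase A/C/G/T. Under the default `"strict"`
#' policy any other character is an error naming the first offending record,
#' 1-based position and character. Under `"strip_ambiguous"` every non-ACGT
#' character (N and other IUPAC ambiguity codes) is removed with a warning
#' stating how many characters were dropped. Validation is idempotent.
#'
#' @param sequences A named `DNAStringSet` (as from [readSequences()]).
#' @param policy `"strict"` (default) or `"strip_ambiguous"`.
#' @return The validated `DNAStringSet`.
#' @examples
#' s <- Biostrings::DNAStringSet(c(s1 = "ACGT"))
#' validateSequences(s)
#' @export
validateSequences <- function(sequences,
                              policy = c("strict", "strip_ambiguous")) {
  policy <- match.arg(policy)
  chr <- as.character(sequences)
  if (any(!nzchar(chr)))
    stop("empty sequence: ", names(chr)[!nzchar(chr)][1])
  bad <- regexpr("[^ACGT]", chr)
  if (all(bad < 0L)) return(sequences)
  if (policy == "strict") {
    i <- which(bad > 0L)[1]
    stop(sprintf(
      "non-ACGT character '%s' at position %d of sequence '%s' (strict policy)",
      substr(chr[i], bad[i], bad[i]), bad[i], names(chr)[i]))
  }
  cleaned <- gsub("[^ACGT]", "", chr)
  removed <- nchar(chr) - nchar(cleaned)
  warning(sprintf(
    "removed %d ambiguous character(s) from %d sequence(s): %s",
    sum(removed), sum(removed > 0),
    paste(names(chr)[removed > 0], collapse = ", ")))
  if (any(!nzchar(cleaned)))
    stop("sequence empty after stripping ambiguous characters: ",
         names(chr)[!nzchar(cleaned)][1])
  Biostrings::DNAStringSet(setNames(cleaned, names(chr)))
}

#' Read a sequence label table
#'
#' Two-column tab-separated file: sequence id, label. Labels are
#' case-insensitive `EASY` / `HARD`; `HARD` is the positive (difficult to
#' synthesize) class. A header line `id<TAB>label` is allowed and skipped.
#'
#' @param path Path to the label table.
#' @return A factor with levels `EASY`, `HARD`, named by sequence id.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = FALSE, colClasses = "character",
                    col.names = c("id", "label"), strip.white = TRUE)
  if (nrow(tab) && tolower(tab$id[1]) == "id") tab <- tab[-1, , drop = FALSE]
  if (!nrow(tab)) stop("empty label table: ", path)
  lab <- toupper(tab$label)
  bad <- !(lab %in% c("EASY", "HARD"))
  if (any(bad))
    stop("labels must be EASY or HARD; offending ids: ",
         paste(tab$id[bad], collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  setNames(factor(lab, levels = c("EASY", "HARD")), tab$id)
}

#' Write a label table
#'
#' @param labels Named EASY/HARD factor (or character) vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  write.table(data.frame(id = names(labels), label = as.character(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Assemble a labeled dataset
#'
#' Pairs validated sequences with their labels, checking that every sequence
#' has exactly one label and that no label is orphaned.
#'
#' @param sequences Named `DNAStringSet` of validated sequences.
#' @param labels Named EASY/HARD factor (as from [readLabels()]).
#' @return A [SeqDataset].
#' @export
seqDataset <- function(sequences, labels) {
  ids <- names(sequences)
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("no label for sequence id(s): ", paste(missing, collapse = ", "))
  orphans <- setdiff(names(labels), ids)
  if (length(orphans))
    stop("label(s) without a sequence: ", paste(orphans, collapse = ", "))
  labels <- factor(as.character(labels[ids]), levels = c("EASY", "HARD"))
  names(labels) <- ids
  new("SeqDataset", sequences = sequences, labels = labels)
}
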