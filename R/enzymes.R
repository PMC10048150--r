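#' Restriction enzymes scanned by the feature extractor
#'
#' The fixed panel of 114 commercially common restriction endonucleases whose
#' recognition sites are counted as sequence features. All recognition
#' sequences are unambiguous (plain A/C/G/T, no IUPAC degeneracy) so that a
#' site count is a simple exact-match count. Palindromic sites (equal to
#' their own reverse complement) are counted once per position; for
#' non-palindromic sites occurrences of the site and of its reverse
#' complement on the forward strand are pooled, so the count is
#' strand-symmetric.
#'
#' @return A data.frame with columns `enzyme` (name), `site` (recognition
#'   sequence, uppercase ACGT) and `palindromic` (logical).
#' @examples
#' enz <- restrictionEnzymes()
#' nrow(enz)                       # 114
#' enz[enz$enzyme == "ApaI", ]    # GGGCCC
#' @export
restrictionEnzymes <- function() {
  .enzyme_table
}

# Panel pinned at manifest version 1; order here is the manifest order.
.enzyme_table <- local({
  x <- c(
    # -- palindromic 6-cutters --
    AatII   = "GACGTC",  AclI   = "AACGTT",  AfeI    = "AGCGCT",
    AflII   = "CTTAAG",  AgeI   = "ACCGGT",  ApaI    = "GGGCCC",
    ApaLI   = "GTGCAC",  AseI   = "ATTAAT",  AvrII   = "CCTAGG",
    BamHI   = "GGATCC",  BclI   = "TGATCA",  BglII   = "AGATCT",
    BsiWI   = "CGTACG",  BspEI  = "TCCGGA",  BspHI   = "TCATGA",
    BsrGI   = "TGTACA",  BssHII = "GCGCGC",  BstBI   = "TTCGAA",
    BstZ17I = "GTATAC",  ClaI   = "ATCGAT",  DraI    = "TTTAAA",
    EagI    = "CGGCCG",  EcoRI  = "GAATTC",  EcoRV   = "GATATC",
    FspI    = "TGCGCA",  HindIII = "AAGCTT", HpaI    = "GTTAAC",
    KasI    = "GGCGCC",  KpnI   = "GGTACC",  MfeI    = "CAATTG",
    MluI    = "ACGCGT",  MscI   = "TGGCCA",  NaeI    = "GCCGGC",
    NcoI    = "CCATGG",  NdeI   = "CATATG",  NheI    = "GCTAGC",
    NruI    = "TCGCGA",  NsiI   = "ATGCAT",  PciI    = "ACATGT",
    PmlI    = "CACGTG",  PsiI   = "TTATAA",  PstI    = "CTGCAG",
    PvuI    = "CGATCG",  PvuII  = "CAGCTG",  SacI    = "GAGCTC",
    SacII   = "CCGCGG",  SalI   = "GTCGAC",  ScaI    = "AGTACT",
    SmaI    = "CCCGGG",  SnaBI  = "TACGTA",  SpeI    = "ACTAGT",
    SphI    = "GCATGC",  SspI   = "AATATT",  StuI    = "AGGCCT",
    XbaI    = "TCTAGA",  XhoI   = "CTCGAG",
    # -- palindromic 8-cutters --
    AbsI    = "CCTCGAGG", AscI  = "GGCGCGCC", AsiSI  = "GCGATCGC",
    FseI    = "GGCCGGCC", NotI  = "GCGGCCGC", PacI   = "TTAATTAA",
    PmeI    = "GTTTAAAC", SbfI  = "CCTGCAGG", SgrDI  = "CGTCGACG",
    SrfI    = "GCCCGGGC", SwaI  = "ATTTAAAT", MreI   = "CGCCGGCG",
    # -- palindromic 4-cutters --
    AluI    = "AGCT",  BfaI   = "CTAG",  BstUI  = "CGCG",
    Csp6I   = "GTAC",  DpnII  = "GATC",  HaeIII = "GGCC",
    HhaI    = "GCGC",  HpaII  = "CCGG",  HpyCH4IV = "ACGT",
    MseI    = "TTAA",  NlaIII = "CATG",  TaqI   = "TCGA",
    Tsp509I = "AATT",
    # -- non-palindromic (Type IIS and offset cutters; both strands) --
    AarI    = "CACCTGC", AcuI  = "CTGAAG", AlwI   = "GGATC",
    BbsI    = "GAAGAC",  BccI  = "CCATC",  BciVI  = "GTATCC",
    BmgBI   = "CACGTC",  BmrI  = "ACTGGG", BpmI   = "CTGGAG",
    BpuEI   = "CTTGAG",  BsaI  = "GGTCTC", BseRI  = "GAGGAG",
    BsgI    = "GTGCAG",  BsmBI = "CGTCTC", BsmI   = "GAATGC",
    BspMI   = "ACCTGC",  BsrBI = "CCGCTC", BsrDI  = "GCAATG",
    BssSI   = "CACGAG",  BtgZI = "GCGATG", BtsI   = "GCAGTG",
    EarI    = "CTCTTC",  EciI  = "GGCGGA", FauI   = "CCCGC",
    FokI    = "GGATG",   HgaI  = "GACGC",  HphI   = "GGTGA",
    HpyAV   = "CCTTC",   MboII = "GAAGA",  MlyI   = "GAGTC",
    MnlI    = "CCTC",    SapI  = "GCTCTTC", SfaNI = "GCATC"
  )
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(s, function(z) paste(rev(strsplit(z, "")[[1]]), collapse = ""),
                  character(1)))
  }
  data.frame(
    enzyme = names(x),
    site = unname(x),
    palindromic = unname(x == rc(x)),
    stringsAsFactors = FALSE
  )
})
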