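# Gorilla alphoid consensus sequences (printed set): a general consensus,
# A- and B-type consensuses, two SF1 units, eight SF2 units, five SF3 units
# and the monomeric-array consensus gM1. Sequences use the extended
# alphabet: IUPAC degeneracy codes plus the gap codes F (-/A), I (-/C),
# J (-/G).
.gorilla_consensus_seqs <- c(
  GGO_consensus       = "AATCTGCAAGTGGATATTTGGASYSYTTTGAGGVCTTCGKTGGAAAMGGRAATWTCTTCATATAAAAACTAGACAGAAGCATTCTCAGAAACTTCTTTGTGATGTGTGCATTCAACTCACAGAGTTGAACCTTYCTTTTGATAGAGCAGTTTTGAAACACYYCTTTTTGTAG",
  GGO_consensus_Atype = "AATTTGCAAGTGGABATTTCGAGCGCTTTGJGGCCTATGGTAGAAAFAGGAAATATCTTCATATAAAAACTAGACAGAAGCATTCTCAGAAACTWCTTTGTGATGTGTGIRTTCAACTCACAGAJKTGAACCTTTCTTTTGATAGAGCAGTTTTGAAACACTCTTTTTGTAG",
  GGO_consensus_Btype = "AATCTGCAAGTGGATATTTGGACCTCTTTGAGGATTTCGTTGGAAACGGKATTTCTTCATATAARAWCTAGACAGAAGAATTCTCAGWAACTTCTTTGKGATGTWTGCBTTCAACTCACAGAGTTGAACMTTCCTTTTGATAGAGCAGRTTTGAAACACTCTTTTTGTGG",
  gJ1   = "AATTTGCAAGTGGACATTTCAAGCGCTTTGGGGCCAACGGTAGAAAAGGAAATATCTTCGTATAAAAACTAGAGAGAATCATTCTCAGAAACCACTTTGTGATGTGTGCGTTCCACTCACAGAGTTTAACCTTTCTTTTCATAGAGCAGTTTGGAAACACTCTGTTTGTAA",
  gJ2   = "AGTCTGCAAGTGGATATTTGGACCTCTTTGAGGATTTCGTTGGAAACGGGATTTCTTCATCTAATGCTAGACAGAAGAATTCTCAGTAACTTCTTTGGGTTGCGTGTGTTCAACTCACAGAGTTGAACCTTCCTTTAGACAGAGCAGATTTGAAACCCTCTTTTTGTGG",
  gD1.0 = "AATCTGCAAGTGGATATTTGGATAGGTTTGAAGATTTCGTTGGAAACGGGAATATCTTCATATAAAATCTAGACAGAAGCATTCTCAGAAACTTCTTTGTGATATCTGCATTCAAGACACAGAGTTGAATATTCCCCTTCATAGAGCAAGTTTGAAACACTCTTTTTGTGG",
  gD1.1 = "AATCTGCAAGTGGATATTTGGATAGCTTTGAAGATTTCGTTGGAAACGGGAATTTCTTCATATCAAATCGAGACAGTAGCATTCTCAGAAACTTCCTTGTGATATCTGCATTCAAGTCAGAGAGTTGAACATTCCCTTTCATAGAGCAGGTTTGAAACACTCTTTCGGTGG",
  gD1.2 = "AATCTGCAACTGGATATTTGGATAGATTTGAAGAATTCGTTGGAAACGGGAATATCTTCCAATAAAATCTAGACAGAAGCATTCTCAGAAACTTCTTTGTGATGCTTGCATTCAACTCATAGAGTTGAACATTCCCTATCATAGAGCAGGTTGGAAACACTCATTTTGTAG",
  gD1.3 = "AATCTGCAAGTGGATATTTGGATAGATTTGAGGATTTCCGTTGGAAACGGGATTACATATAAAAAGCAGACGGCAGCATTCTCCGAAATTTCTTTGCGATGTTTGCATTCAAGTCACAGAGTTGAACATTCCCTTTCATAGAGCAGGTTTGAAACACTCTTTTTGTGG",
  gD1.4 = "AATCTGCAAGTGGATATTTGGGTAGATCTGAGGATTTCGTTGGAAACCTTTGAGGATTTCGTTGGAAACGGGATTACATATAAGAAGCAGACAGAAGCATTCTCCGAAATTTCTTTGTGATGTTTGCATTCAAGTCGCAGAGTTGAACATTCCCTTTCATAGAGCAGGTTTGAAACACTCTTTCTGTAC",
  gD2.0 = "AATGTGGAAGTGGACATTTGGAGCGCTTTGAGGCCTATGGTGAAAAAGGAAATATCTTCCCATAAAACCTAGACAGAAGCATTGTCAGAAACTTCTTTGTGATGTGTGTACTCAACTAACAGAGTTGAACCTTCCTTTTGACAGAGCAGTTTTGAAACACTCTTTTTGTAG",
  gD2.1 = "TATCTAGAGGAGGACATTTCGAGCGCTTTCTGGCCTATGCTGAGAAGGGAAATATCTTCAAATAAAAACTAGACAGAAGCATTCTCAGAAAGTTGTTTGTGATGTGTGTCCTCAACTAACAGAGTTGAACCTTTGTTTTGATACAGCAGTGTGGAAACACTCTTTTTGTAG",
  gD2.2 = "TATCTGCAAGTGGGCATTTCGAGCGCTTTCAGGCCTATGCTGAGAAACGGAATATCTTCAAATAAAAACCAGACCGAAGCATTCTCAGAAACTTATTTGTGATGTGTGTCCTCACCTAACAGAGTTGAACGTTTGTTTTGATACAGCAGTTTGGAAACACTCTTTTTGTAG",
  gW1   = "AATCTGTAAGTGGATATTTGGACCCCTCTGAGGATTTCGTTGGAAACGGGATAAACTTCCCATAACTAAACGGAAGCATTCTCAGAAACTTCTTTGTGATGTTTGCATTCAGCTCACAGAGTTGAACCTTCCTTTGATAGTTCAGGTTTGAAACACTCTTTTTGTAG",
  gW2   = "AATCTGCAAGTGCATATTTGGACCACCGAGTGGCCTTCGTTCGAAACGGGTATATCTTCACGTAAAAGCTAGGCAGAAGCATTCTCGGGAACTTCTCTGTGATGATTGCATTCAACTCACAGAGTTGGACACTCCTTTTGATAGAGCAGTTTTGAAACTCTCTTTTGGTAG",
  gW3   = "AATCTGCAAGTGGATATGTGGACCTCTTTGAAGATTTCTTTGGAAACGGGAATATCTTCACATAAAAACTAAACAGAAGCATTCTCAGAAACTACTTTGTGATGATTGCATTCAACTCACAGAGTTGAACATTCCTATTGATAGAGCAGTTTGGAAACACTCTTTTGGTAG",
  gW4   = "AATCTGCAAGTGGACATTTGGAGCGCTTTGAGGCCTGTGGTGGAAAAGGAAATATCTTCACATAAAAACTAGATAGAAGCATTCTCAGAAACTCTTTGTGATGATTGCATTCAACTCACAGAGTTGAACATTCCTTTTGATAGAGCAGTTTGGAAACACTCTTTTTGTG",
  gW5   = "AATCTGCAAGTGGAGATTTGGACTGCTTTGAGGCCTAYGGTAGTAAAGGAAATAACTTCATATAAAAACCAAACAGAAGCATTCTCAGAAAATTCTTTGTGATGATTGAGTTGAACTCACAGAGCTGAACATTGCTTTTGATGGAGCAGTTTCCAAACACACTTTTTGTAG",
  gM1   = "AATCTGCAAGTGGATATTTGGAGCGCTTTGAGGCCTATGGTGGAAAAGGAAATATCTTCACATAAAAACTAGACAGAAGCATTCTGAGAAACTTCTTTGTGATGTGTGCATTCATCTCACAGAGTTGAACCTTTCTTTTGATTGAGCAGTTTTGAAACACTCTTTTTGTAG"
)

.gorilla_consensus_sizes <- c(
  GGO_consensus = 172L, GGO_consensus_Atype = 172L, GGO_consensus_Btype = 170L,
  gJ1 = 171L, gJ2 = 169L,
  gD1.0 = 171L, gD1.1 = 171L, gD1.2 = 171L, gD1.3 = 168L, gD1.4 = 189L,
  gD2.0 = 171L, gD2.1 = 171L, gD2.2 = 171L,
  gW1 = 167L, gW2 = 171L, gW3 = 171L, gW4 = 169L, gW5 = 171L,
  gM1 = 171L
)

.gorilla_sf <- c(
  GGO_consensus = "general", GGO_consensus_Atype = "general",
  GGO_consensus_Btype = "general",
  gJ1 = "SF1", gJ2 = "SF1",
  gD1.0 = "SF2", gD1.1 = "SF2", gD1.2 = "SF2", gD1.3 = "SF2", gD1.4 = "SF2",
  gD2.0 = "SF2", gD2.1 = "SF2", gD2.2 = "SF2",
  gW1 = "SF3", gW2 = "SF3", gW3 = "SF3", gW4 = "SF3", gW5 = "SF3",
  gM1 = "monomeric"
)

# A/B type per unit, following the printed family compositions:
# SF1 gJ1-gJ2 = A-B; SF2 gD1.0-gD1.3-gD1.4-gD2.1-gD1.2-gD2.0-gD1.1-gD2.2 =
# B-B-B-A-B-A-B-A; SF3 gW1..gW5 = B-B-B-A-A.
.gorilla_unit_type <- c(
  GGO_consensus = "unspecified", GGO_consensus_Atype = "A",
  GGO_consensus_Btype = "B",
  gJ1 = "A", gJ2 = "B",
  gD1.0 = "B", gD1.1 = "B", gD1.2 = "B", gD1.3 = "B", gD1.4 = "B",
  gD2.0 = "A", gD2.1 = "A", gD2.2 = "A",
  gW1 = "B", gW2 = "B", gW3 = "B", gW4 = "A", gW5 = "A",
  gM1 = "unspecified"
)

# HOR unit orders per family, in the printed succession.
.gorilla_sf_units <- list(
  SF1 = c("gJ1", "gJ2"),
  SF2 = c("gD1.0", "gD1.3", "gD1.4", "gD2.1", "gD1.2", "gD2.0", "gD1.1", "gD2.2"),
  SF3 = c("gW1", "gW2", "gW3", "gW4", "gW5"),
  monomeric = "gM1"
)

#' Built-in gorilla alphoid consensus set
#'
#' Returns the published gorilla alpha-satellite consensus sequences: the
#' general, A-type and B-type consensuses plus the sixteen family-specific
#' units (two SF1, eight SF2, five SF3, and gM1 for monomeric arrays).
#' Sequences are over the extended alphabet (IUPAC degeneracy codes plus the
#' gap codes `F` = -/A, `I` = -/C, `J` = -/G).
#'
#' The returned data frame carries an attribute `sf_units`: a list mapping
#' each family to the ordered monomer succession of its HOR unit
#' (SF1 dimeric, SF2 octameric, SF3 pentameric).
#'
#' @return A data frame of class `consensus_set` with columns `name`,
#'   `sequence`, `declared_length`, `sf` and `unit_type`.
#' @examples
#' cset <- gorilla_consensuses()
#' nrow(cset)               # 19 entries
#' attr(cset, "sf_units")$SF2
#' @export
gorilla_consensuses <- function() {
  nm <- names(.gorilla_consensus_seqs)
  out <- data.frame(
    name = nm,
    sequence = unname(.gorilla_consensus_seqs),
    declared_length = unname(.gorilla_consensus_sizes[nm]),
    sf = unname(.gorilla_sf[nm]),
    unit_type = unname(.gorilla_unit_type[nm]),
    stringsAsFactors = FALSE
  )
  attr(out, "sf_units") <- .gorilla_sf_units
  class(out) <- c("consensus_set", "data.frame")
  out
}

#' Look up one consensus entry by name
#'
#' @param name entry name, e.g. `"GGO_consensus"` or `"gD1.4"`.
#' @param cset a consensus set, by default [gorilla_consensuses()].
#' @return A one-row data frame (consensus entry).
#' @export
consensus_entry <- function(name, cset = gorilla_consensuses()) {
  i <- match(name, cset$name)
  if (is.na(i)) stop("unknown consensus entry: ", name)
  cset[i, , drop = FALSE]
}

# sequence string for one entry (accepts a name, a one-row entry, or a
# plain sequence string)
.entry_seq <- function(x, cset = NULL) {
  if (is.data.frame(x)) return(x$sequence[[1]])
  if (is.character(x) && length(x) == 1) {
    if (grepl("^[ACGTMRWSYKVHDBNFIJO-]+$", x) && nchar(x) >= 50) return(x)
    if (is.null(cset)) cset <- gorilla_consensuses()
    return(consensus_entry(x, cset)$sequence)
  }
  stop("cannot interpret consensus reference")
}

#' Protein-recognition-domain motif specifications
#'
#' The two 17-bp alphoid protein-recognition domains: the pJ-alpha motif
#' `CTAPyGGTGPuAAAAGGAA` of A-type monomers and the CENP-B box
#' `PyTTCGTTGGAAPuCGGGA` of B-type monomers, written with one IUPAC symbol
#' per position (`Py` = Y, `Pu` = R).
#'
#' Core positions are the positions that must be intact for protein binding
#' to be called. For the CENP-B box the default is the nine essential
#' nucleotides (positions 2-5, 10, 13-16 of the 17-mer); for the pJ-alpha
#' motif no canonical core is established and the default is all
#' non-degenerate positions, which callers may override.
#'
#' @param kind `"pJalpha"` or `"cenpb"`.
#' @param core_positions integer vector of 1-based positions within the
#'   17-mer; `NULL` for the kind-specific default.
#' @param max_mismatch_call maximum mismatches against the degenerate
#'   pattern for a hit to be reported (default 5).
#' @return An object of class `motif_spec` with elements `kind`, `pattern`,
#'   `core_positions`, `max_mismatch_call` and `core_default` (TRUE when the
#'   default core was used).
#' @export
motif_spec <- function(kind = c("pJalpha", "cenpb"), core_positions = NULL,
                       max_mismatch_call = 5) {
  kind <- match.arg(kind)
  pattern <- switch(kind,
    pJalpha = "CTAYGGTGRAAAAGGAA",
    cenpb   = "YTTCGTTGGAARCGGGA")
  core_default <- is.null(core_positions)
  if (is.null(core_positions)) {
    core_positions <- switch(kind,
      cenpb = c(2L, 3L, 4L, 5L, 10L, 13L, 14L, 15L, 16L),
      pJalpha = {
        p <- strsplit(pattern, "")[[1]]
        which(p %in% c("A", "C", "G", "T"))
      })
  }
  stopifnot(nchar(pattern) == 17, all(core_positions %in% 1:17))
  structure(list(kind = kind, pattern = pattern,
                 core_positions = as.integer(core_positions),
                 max_mismatch_call = as.integer(max_mismatch_call),
                 core_default = core_default),
            class = "motif_spec")
}
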