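#' Extended nucleotide alphabet
#'
#' The package works over `{A,C,G,T,N}` plus the IUPAC degeneracy codes and
#' three "gap codes" used in alphoid consensus sequences: `F` (- or A),
#' `I` (- or C) and `J` (- or G). The symbol for - or T is configurable and
#' defaults to `O` (see [build_consensus()]).
#'
#' @format A named list mapping each symbol to the set of concrete bases it
#'   can stand for (gap codes map to their base only; the possible absence is
#'   handled where it matters).
#' @export
iupac_expand <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"),
  F = "A", I = "C", J = "G", O = "T"
)

# symbols whose presence in a column means "base or absent"
.gap_codes <- c(F = "A", I = "C", J = "G", O = "T")

#' Reverse complement over the extended alphabet
#'
#' Complements IUPAC codes in the usual way (R<->Y, K<->M, S<->S, W<->W,
#' V<->B, H<->D) and gap codes by complementing their base (F<->O, I<->J).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  from <- "ACGTMRWSYKVHDBNFIJO-"
  to   <- "TGCAKYWSRMBDHVNOJIF-"
  vapply(x, function(s) {
    s <- chartr(from, to, s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Alignment scoring parameters
#'
#' Defaults follow the standard BLASTN-style scheme used for alphoid
#' monomer comparisons: +1 for a match, -2 for a mismatch, gap open 5 and
#' gap extension 2.
#'
#' @param match_reward,mismatch_penalty,gap_open,gap_extend integers;
#'   penalties are magnitudes (non-negative).
#' @return an object of class `align_params`.
#' @export
align_params <- function(match_reward = 1, mismatch_penalty = 2,
                         gap_open = 5, gap_extend = 2) {
  stopifnot(match_reward > 0, mismatch_penalty >= 0,
            gap_open >= 0, gap_extend >= 0)
  structure(list(match_reward = match_reward,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# Substitution matrix over the extended alphabet. Two symbols score as a
# match when their expansion sets intersect, so a degenerate consensus
# position matches any of its bases at full reward. N is scored neutrally
# (0) against everything so N-runs neither attract nor repel alignments.
.subst_matrix <- function(params = align_params()) {
  key <- paste(params$match_reward, params$mismatch_penalty)
  cached <- .alphoidr_cache[[key]]
  if (!is.null(cached)) return(cached)
  syms <- names(iupac_expand)
  m <- matrix(-params$mismatch_penalty, length(syms), length(syms),
              dimnames = list(syms, syms))
  for (a in syms) for (b in syms) {
    if (length(intersect(iupac_expand[[a]], iupac_expand[[b]])) > 0)
      m[a, b] <- params$match_reward
  }
  m["N", ] <- 0
  m[, "N"] <- 0
  .alphoidr_cache[[key]] <- m
  m
}

.alphoidr_cache <- new.env(parent = emptyenv())

# Does concrete base `base` satisfy (possibly degenerate) symbol `sym`?
.base_matches <- function(base, sym) {
  base %in% iupac_expand[[sym]]
}
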