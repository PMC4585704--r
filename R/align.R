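# Pairwise alignment helpers. All alignments go through
# Biostrings::pairwiseAlignment on BString objects with a substitution
# matrix over the extended alphabet (.subst_matrix), so degenerate
# consensus symbols score as a match against any of their expansion bases.

.pw_align <- function(pattern, subject, type = "global",
                      params = align_params()) {
  Biostrings::pairwiseAlignment(
    Biostrings::BString(pattern), Biostrings::BString(subject),
    type = type,
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
}

# gapped aligned strings of a global alignment
.aligned_pair <- function(aln) {
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)))
}

#' p-distance between two aligned rows
#'
#' Proportion of differing sites with pairwise deletion: only columns where
#' both rows carry a concrete base (`A`, `C`, `G` or `T`) are compared;
#' gaps, `N` and ambiguity codes in either row are removed for the pair.
#'
#' @param a,b aligned sequences of equal length (strings or character
#'   vectors of single symbols).
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1) a <- strsplit(a, "", fixed = TRUE)[[1]]
  if (length(b) == 1) b <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("aligned rows must have equal length")
  conc <- c("A", "C", "G", "T")
  ok <- a %in% conc & b %in% conc
  if (!any(ok)) stop("no overlap: zero comparable positions")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' p-distance between two unaligned sequences
#'
#' Globally aligns the two sequences (affine gap penalties, degenerate
#' symbols matching their expansion bases) and returns the [p_distance()]
#' of the aligned rows. Gap columns created by length differences (such as
#' the 18-bp block of extra-long insertion monomers) are excluded by
#' pairwise deletion, so monomers of different lengths compare cleanly.
#'
#' @param x,y sequences over the extended alphabet.
#' @param params [align_params()].
#' @return p-distance in `[0, 1]`.
#' @export
pairwise_pdist <- function(x, y, params = align_params()) {
  ap <- .aligned_pair(.pw_align(x, y, "global", params))
  p_distance(ap$pattern, ap$subject)
}

#' Pairwise p-distance matrix of a set of sequences
#'
#' @param seqs character vector of (unaligned) sequences; names are used as
#'   labels.
#' @param params [align_params()].
#' @return A symmetric matrix of p-distances with zero diagonal.
#' @export
monomer_distance_matrix <- function(seqs, params = align_params()) {
  n <- length(seqs)
  labels <- names(seqs)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- pairwise_pdist(seqs[[i]], seqs[[j]], params)
  }
  d
}

#' p-distance matrix from pre-aligned rows
#'
#' @param aln character matrix (rows = sequences, columns = alignment
#'   positions) or character vector of equal-length gapped strings.
#' @return A symmetric p-distance matrix.
#' @export
pdistance_matrix <- function(aln) {
  m <- .as_aln_matrix(aln)
  n <- nrow(m)
  labels <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- p_distance(m[i, ], m[j, ])
  }
  d
}

.as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.character(aln)) {
    w <- unique(nchar(aln))
    if (length(w) != 1) stop("aligned rows must have equal length")
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(m) <- if (is.null(names(aln))) as.character(seq_along(aln)) else names(aln)
    return(m)
  }
  if (inherits(aln, "monomer_alignment")) return(aln$matrix)
  stop("cannot interpret alignment")
}
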