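# Reference-projected monomer alignment and majority-rule consensus over
# the extended ambiguity alphabet.

#' Align monomers into reference coordinates
#'
#' Each monomer is aligned pairwise-globally to the reference and projected
#' into its coordinate system. Monomer insertions relative to the reference
#' open new alignment columns only when more than half of the rows carry an
#' insertion at the same reference position; rarer insertions are kept as
#' per-row metadata so every monomer remains reconstructible (see
#' [reconstruct_monomer()]).
#'
#' @param monomers character vector of monomer sequences (or a monomer
#'   table, in which case non-partial sequences are used).
#' @param ref reference consensus (entry, name or sequence).
#' @param params [align_params()].
#' @return An object of class `monomer_alignment`: `matrix` (rows =
#'   monomers, cells in `{A,C,G,T,N,-}`), `ref_pos` (reference position
#'   consumed up to each column; insertion columns repeat the preceding
#'   value), `insertions` (data frame `row`, `after`, `seq` of
#'   non-projected insertions).
#' @export
align_monomers <- function(monomers, ref = "GGO_consensus",
                           params = align_params()) {
  if (is.data.frame(monomers))
    monomers <- monomers$sequence[!monomers$partial]
  if (length(monomers) == 0) stop("no monomers to align")
  refseq <- .entry_seq(ref)
  L <- nchar(refseq)
  nr <- length(monomers)
  labels <- if (is.null(names(monomers))) as.character(seq_len(nr))
            else names(monomers)

  rows <- matrix("-", nr, L)
  ins <- vector("list", nr)  # per row: named list ref_pos -> inserted seq
  for (i in seq_len(nr)) {
    ap <- .aligned_pair(.pw_align(refseq, monomers[[i]], "global", params))
    rs <- strsplit(ap$pattern, "", fixed = TRUE)[[1]]
    ms <- strsplit(ap$subject, "", fixed = TRUE)[[1]]
    pos <- 0L
    ilist <- list()
    for (k in seq_along(rs)) {
      if (rs[k] != "-") {
        pos <- pos + 1L
        rows[i, pos] <- ms[k]
      } else if (ms[k] != "-") {
        key <- as.character(pos)
        ilist[[key]] <- paste0(if (is.null(ilist[[key]])) "" else ilist[[key]],
                               ms[k])
      }
    }
    ins[[i]] <- ilist
  }

  # shared insertions (> 50% of rows at the same reference position) are
  # promoted to alignment columns, left-aligned and padded with gaps
  all_keys <- sort(unique(as.integer(unlist(lapply(ins, names)))))
  shared <- all_keys[vapply(all_keys, function(q) {
    sum(vapply(ins, function(x) !is.null(x[[as.character(q)]]), logical(1)))
  }, numeric(1)) > nr / 2]

  out_cols <- list()
  ref_pos <- integer(0)
  for (q in 0:L) {
    if (q > 0) {
      out_cols[[length(out_cols) + 1L]] <- rows[, q]
      ref_pos <- c(ref_pos, q)
    }
    if (q %in% shared) {
      key <- as.character(q)
      pieces <- vapply(ins, function(x)
        if (is.null(x[[key]])) "" else x[[key]], character(1))
      w <- max(nchar(pieces))
      block <- matrix("-", nr, w)
      for (i in seq_len(nr)) {
        p <- strsplit(pieces[i], "", fixed = TRUE)[[1]]
        if (length(p)) block[i, seq_along(p)] <- p
      }
      for (cc in seq_len(w)) {
        out_cols[[length(out_cols) + 1L]] <- block[, cc]
        ref_pos <- c(ref_pos, q)
      }
      for (i in seq_len(nr)) ins[[i]][[key]] <- NULL
    }
  }
  m <- do.call(cbind, out_cols)
  rownames(m) <- labels

  leftovers <- do.call(rbind, lapply(seq_len(nr), function(i) {
    ks <- names(ins[[i]])
    if (length(ks) == 0) return(NULL)
    data.frame(row = i, after = as.integer(ks),
               seq = unlist(ins[[i]], use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(leftovers))
    leftovers <- data.frame(row = integer(0), after = integer(0),
                            seq = character(0), stringsAsFactors = FALSE)

  structure(list(matrix = m, ref_pos = ref_pos, insertions = leftovers),
            class = "monomer_alignment")
}

#' Reconstruct a monomer from a monomer alignment row
#'
#' Removes gaps and re-inserts the per-row insertion metadata, recovering
#' the original monomer sequence exactly.
#'
#' @param aln a `monomer_alignment`.
#' @param i row index.
#' @return The monomer sequence.
#' @export
reconstruct_monomer <- function(aln, i) {
  row <- aln$matrix[i, ]
  ext <- aln$insertions[aln$insertions$row == i, , drop = FALSE]
  out <- character(0)
  qs <- unique(c(0L, aln$ref_pos))
  for (q in qs) {
    if (q %in% ext$after && q == 0L)
      out <- c(out, ext$seq[ext$after == 0L])
    cols <- which(aln$ref_pos == q)
    if (length(cols)) out <- c(out, row[cols][row[cols] != "-"])
    if (q > 0L && q %in% ext$after)
      out <- c(out, ext$seq[ext$after == q])
  }
  paste(out, collapse = "")
}

# map a set of column symbols to the extended-alphabet code
.code_for_set <- function(set, t_gap_symbol = "O") {
  bases <- setdiff(set, "-")
  has_gap <- "-" %in% set
  if (has_gap) {
    if (length(bases) == 1) {
      return(switch(bases, A = "F", C = "I", G = "J", T = t_gap_symbol, "N"))
    }
    return("N")
  }
  if (length(bases) == 1) return("N")  # lone base that failed the >50% rule
  key <- paste(sort(bases), collapse = "")
  code <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")[key]
  if (is.na(code)) "N" else unname(code)
}

#' Majority-rule consensus of a monomer alignment
#'
#' Per column: a symbol observed in strictly more than 50% of rows is
#' emitted (a majority gap deletes the column); otherwise the ambiguity
#' code covering the set of symbols at frequency of at least
#' `min_component_freq` is emitted, with gap-containing sets written as the
#' gap codes `F` (-/A), `I` (-/C), `J` (-/G) and `t_gap_symbol` (-/T).
#' Columns too ambiguous for any code become `N`.
#'
#' @param aln a `monomer_alignment`, a character matrix, or a character
#'   vector of equal-length gapped rows.
#' @param min_component_freq minimum frequency for a symbol to enter an
#'   ambiguity-code set (default 0.2; filters sporadic substitutions).
#' @param t_gap_symbol symbol used for the -/T ambiguity (default `"O"`;
#'   the published code table does not define one).
#' @param name name for the resulting entry.
#' @return A one-row `consensus_set` data frame (name, sequence,
#'   declared_length, sf = `"general"`, unit_type = `"unspecified"`).
#' @export
build_consensus <- function(aln, min_component_freq = 0.2,
                            t_gap_symbol = "O", name = "consensus") {
  m <- .as_aln_matrix(aln)
  if (nrow(m) == 0) stop("empty alignment")
  nr <- nrow(m)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col[!(col %in% c("A", "C", "G", "T", "-"))] <- NA  # N etc. ignored
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "-")))
    freq <- as.numeric(tab) / nr
    names(freq) <- names(tab)
    top <- names(freq)[which.max(freq)]
    if (freq[top] > 0.5) {
      if (top != "-") out <- c(out, top)
      next
    }
    set <- names(freq)[freq >= min_component_freq]
    out <- c(out, if (length(set) == 0) "N"
             else .code_for_set(set, t_gap_symbol))
  }
  seq <- paste(out, collapse = "")
  res <- data.frame(name = name, sequence = seq,
                    declared_length = nchar(seq), sf = "general",
                    unit_type = "unspecified", stringsAsFactors = FALSE)
  class(res) <- c("consensus_set", "data.frame")
  res
}
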