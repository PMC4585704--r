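# Extra-long (~189 bp) monomer detection and characterization of the
# CENP-B-box-interrupting tandem-duplication insertion.

#' Detect extra-long monomers
#'
#' @param monomers a monomer table.
#' @param min_len minimum length to call a monomer extra-long
#'   (default 180).
#' @return The rows of non-partial monomers with `length >= min_len`.
#' @export
detect_long_monomers <- function(monomers, min_len = 180) {
  monomers[!monomers$partial & monomers$length >= min_len, , drop = FALSE]
}

#' Characterize the insertion of an extra-long monomer
#'
#' Globally aligns the monomer to a B-type reference, locates the inserted
#' block, and tests whether it is a tandem repetition of the immediately
#' upstream segment (at most 4 edits per copy). The insertion in the
#' published 189-bp monomer interrupts the CENP-B box, duplicates the
#' unfinished box plus upstream bases, and regenerates a complete box
#' downstream; with a small downstream deletion the net gain is 18 bp. The
#' 22-bp-duplication-plus-4-bp-deletion description and an 18-bp perfect
#' duplication are degenerate readings of the same sequence; the report's
#' `notes` field records the alignment-level gap structure so both can be
#' recovered.
#'
#' @param monomer extra-long monomer sequence (or monomer-table row).
#' @param bref B-type reference consensus (default `GGO_consensus_Btype`;
#'   `gD1.0` is the natural choice for SF2-specific analysis).
#' @param spec the CENP-B [motif_spec()].
#' @param params [align_params()].
#' @return A list of class `insertion_report`: `monomer_length`,
#'   `net_insertion` (inserted minus deleted bases vs the reference),
#'   `dup_unit_len`, `copies` (1 + extra tandem copies; 0 when no
#'   insertion was found), `box_break_pos` (first position of the 17-mer
#'   pattern at which the interrupted upstream box stops matching),
#'   `regenerated_box_core_intact`, `insertion_start` (0-based, monomer
#'   coordinates), `insertion_length`, `notes`.
#' @export
characterize_insertion <- function(monomer, bref = "GGO_consensus_Btype",
                                   spec = motif_spec("cenpb"),
                                   params = align_params()) {
  seq <- .monomer_seq(monomer)
  brefseq <- .entry_seq(bref)
  ap <- .aligned_pair(.pw_align(brefseq, seq, "global", params))
  rs <- strsplit(ap$pattern, "", fixed = TRUE)[[1]]
  ms <- strsplit(ap$subject, "", fixed = TRUE)[[1]]

  # insertion runs (gaps in the reference row), in monomer coordinates
  mpos <- cumsum(ms != "-")
  ins_rle <- rle(rs == "-")
  idx_end <- cumsum(ins_rle$lengths)
  idx_start <- idx_end - ins_rle$lengths + 1L
  ins_runs <- data.frame(
    start = mpos[idx_start[ins_rle$values]],
    len = ins_rle$lengths[ins_rle$values])
  del_total <- sum((ms == "-"))
  ins_total <- sum((rs == "-"))
  net <- ins_total - del_total

  base <- list(monomer_length = nchar(seq), net_insertion = net)
  if (nrow(ins_runs) == 0 || net < 10) {
    warning("no insertion found (length gain ", net, " < 10)")
    return(structure(c(base, list(
      dup_unit_len = NA_integer_, copies = 0L,
      box_break_pos = NA_integer_, regenerated_box_core_intact = NA,
      insertion_start = NA_integer_, insertion_length = NA_integer_,
      notes = "no insertion")), class = "insertion_report"))
  }

  main <- ins_runs[which.max(ins_runs$len), ]
  s <- main$start        # 1-based first inserted base in monomer coords
  L <- main$len
  Ltot <- ins_total      # total inserted bases across runs

  # duplication unit: search the neighbourhood of the inserted block for a
  # tandem seam - the (position, period) pair minimizing the edit distance
  # between the segment immediately upstream of the seam and the segment
  # of the same length starting at it. The exact gap placement chosen by
  # the aligner inside a tandem repeat is not canonical, so the seam may
  # sit up to one unit length away from the reported block.
  n_m <- nchar(seq)
  dup_unit_len <- NA_integer_
  copies <- 1L
  seam <- s
  best_ed <- Inf
  for (sp in max(2L, s - 25L):min(n_m, s + 25L)) {
    for (p in 14:min(40L, sp - 1L, n_m - sp + 1L)) {
      ed <- utils::adist(substr(seq, sp - p, sp - 1L),
                         substr(seq, sp, sp + p - 1L))[1, 1]
      if (ed < best_ed || (ed == best_ed && sp == s)) {
        best_ed <- ed; seam <- sp; dup_best <- p
      }
    }
  }
  if (is.finite(best_ed) && best_ed <= 4) {
    dup_unit_len <- as.integer(dup_best)
    copies <- max(1L, as.integer(round(Ltot / dup_best)))
  } else seam <- s

  # interrupted upstream box: the 17-bp window in/left of the first
  # duplication copy with the longest matching prefix of the CENP-B
  # pattern
  pat <- strsplit(spec$pattern, "", fixed = TRUE)[[1]]
  scan_lo <- if (!is.na(dup_unit_len)) seam - dup_unit_len else s - 30L
  starts <- max(1L, scan_lo):max(1L, seam - 1L)
  prefix_len <- function(w0) {
    win <- strsplit(substr(seq, w0, w0 + 16L), "", fixed = TRUE)[[1]]
    if (length(win) < 17) return(-1L)
    ok <- mapply(.base_matches, win, pat)
    m <- which(!ok)
    if (length(m) == 0) 17L else m[1] - 1L
  }
  pl <- vapply(starts, prefix_len, integer(1))
  box_break_pos <- if (max(pl) >= 17) NA_integer_ else {
    w <- max(which(pl == max(pl)))   # tie: window closest to the insertion
    as.integer(pl[w] + 1L)
  }

  # regenerated box downstream of the seam (i.e. in or after the last
  # duplication copy)
  down <- substr(seq, seam, nchar(seq))
  mm <- .window_mismatches(down, spec$pattern)
  regenerated <- FALSE
  if (length(mm) > 0) {
    cand_w <- which(mm == min(mm))
    for (w0 in cand_w) {
      win <- strsplit(substr(down, w0, w0 + 16L), "", fixed = TRUE)[[1]]
      ok <- mapply(.base_matches, win, pat)
      if (all(ok[spec$core_positions])) { regenerated <- TRUE; break }
    }
  }

  notes <- sprintf(
    "alignment gaps: %s inserted / %d deleted; main block %d bp at %d",
    paste(ins_runs$len, collapse = "+"), del_total, L, s - 1L)
  structure(c(base, list(
    dup_unit_len = dup_unit_len, copies = copies,
    box_break_pos = box_break_pos,
    regenerated_box_core_intact = regenerated,
    insertion_start = s - 1L, insertion_length = as.integer(L),
    notes = notes)), class = "insertion_report")
}
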