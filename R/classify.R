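# Protein-recognition-domain scanning and A/B monomer typing.

# mismatch count of every 17-bp window of `seq` against a degenerate
# pattern (position matches when the base is in the pattern symbol's
# expansion set)
.window_mismatches <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(p)
  n <- length(s)
  if (n < L) return(integer(0))
  nwin <- n - L + 1L
  mm <- integer(nwin)
  for (k in seq_len(L)) {
    ok <- s[k:(k + nwin - 1L)] %in% iupac_expand[[p[k]]]
    mm <- mm + !ok
  }
  mm
}

#' Scan a monomer for protein-recognition domains
#'
#' Slides both 17-bp degenerate patterns (pJ-alpha motif and CENP-B box)
#' over the monomer and returns the best hit: fewest mismatches across both
#' motifs, ties broken by lower mismatch count then pJ-alpha first.
#' Windows spanning monomer junctions are not scanned.
#'
#' @param monomer a monomer sequence (string) or one row of a monomer
#'   table.
#' @param specs list of [motif_spec()] objects (default both motifs).
#' @return A list of class `prd_hit` (`motif`, `offset` 0-based,
#'   `mismatches`, `core_intact`, `full_intact`), or `NULL` when no motif
#'   scores within `max_mismatch_call` or the monomer is shorter than 17.
#' @export
scan_prd <- function(monomer,
                     specs = list(motif_spec("pJalpha"), motif_spec("cenpb"))) {
  seq <- .monomer_seq(monomer)
  best <- NULL
  for (spec in specs) {
    mm <- .window_mismatches(seq, spec$pattern)
    if (length(mm) == 0) next
    i <- which.min(mm)
    if (mm[i] > spec$max_mismatch_call) next
    if (is.null(best) || mm[i] < best$mismatches) {
      best <- list(motif = spec$kind, offset = i - 1L,
                   mismatches = as.integer(mm[i]), spec = spec)
    }
  }
  if (is.null(best)) return(NULL)
  ci <- score_core(best, seq, best$spec)
  structure(list(motif = best$motif, offset = best$offset,
                 mismatches = best$mismatches,
                 core_intact = ci[["core_intact"]],
                 full_intact = ci[["full_intact"]]),
            class = "prd_hit")
}

#' Score core and full conservation of a PRD hit
#'
#' `full_intact` is TRUE when all 17 positions of the window satisfy the
#' degenerate pattern; `core_intact` when all core positions do.
#'
#' @param hit a hit with an `offset` field (0-based), as from [scan_prd()].
#' @param monomer the monomer sequence the hit was found in.
#' @param spec the [motif_spec()] scanned.
#' @return Named logical vector `c(core_intact =, full_intact =)`.
#' @export
score_core <- function(hit, monomer, spec) {
  seq <- .monomer_seq(monomer)
  win <- strsplit(substr(seq, hit$offset + 1L, hit$offset + 17L), "")[[1]]
  pat <- strsplit(spec$pattern, "", fixed = TRUE)[[1]]
  ok <- mapply(.base_matches, win, pat)
  c(core_intact = all(ok[spec$core_positions]), full_intact = all(ok))
}

#' Classify a monomer as A- or B-type
#'
#' Computes the p-distance (global alignment, pairwise deletion) from the
#' monomer to the A-type and B-type consensuses and assigns the strictly
#' nearer type. Monomers within the tie margin of both, or farther than
#' `max_assign_dist` from both, are left undetermined (monomers that have
#' accumulated too many substitutions cannot be confidently grouped).
#'
#' @param monomer monomer sequence or monomer-table row.
#' @param cset consensus set providing `GGO_consensus_Atype` and
#'   `GGO_consensus_Btype`.
#' @param delta tie margin on the p-distance difference (default 0:
#'   strict nearest).
#' @param max_assign_dist maximum p-distance for a confident call
#'   (default 0.40, the upper end of the monomeric divergence range).
#' @param params [align_params()].
#' @return A list of class `monomer_call`: `ab_type` (`"A"`, `"B"` or
#'   `"undetermined"`), `dist_A`, `dist_B`, `prd` (a `prd_hit` or `NULL`).
#' @export
classify_ab <- function(monomer, cset = gorilla_consensuses(), delta = 0,
                        max_assign_dist = 0.40, params = align_params()) {
  seq <- .monomer_seq(monomer)
  dA <- pairwise_pdist(consensus_entry("GGO_consensus_Atype", cset)$sequence,
                       seq, params)
  dB <- pairwise_pdist(consensus_entry("GGO_consensus_Btype", cset)$sequence,
                       seq, params)
  ab <- if (min(dA, dB) > max_assign_dist) "undetermined"
        else if (dA + delta < dB) "A"
        else if (dB + delta < dA) "B"
        else "undetermined"
  structure(list(ab_type = ab, dist_A = dA, dist_B = dB,
                 prd = scan_prd(seq)),
            class = "monomer_call")
}

#' Classify all monomers of a monomer table
#'
#' Applies [classify_ab()] and [scan_prd()] to each non-partial monomer.
#'
#' @param monomers a monomer table from [segment_monomers()].
#' @inheritParams classify_ab
#' @return The monomer table with added columns `ab_type`, `dist_A`,
#'   `dist_B`, `motif`, `motif_offset`, `motif_mismatches`, `core_intact`,
#'   `full_intact` (NA for partial monomers).
#' @export
classify_monomers <- function(monomers, cset = gorilla_consensuses(),
                              delta = 0, max_assign_dist = 0.40,
                              params = align_params()) {
  n <- nrow(monomers)
  monomers$ab_type <- NA_character_
  monomers$dist_A <- NA_real_
  monomers$dist_B <- NA_real_
  monomers$motif <- NA_character_
  monomers$motif_offset <- NA_integer_
  monomers$motif_mismatches <- NA_integer_
  monomers$core_intact <- NA
  monomers$full_intact <- NA
  for (i in seq_len(n)) {
    if (monomers$partial[i]) next
    call <- classify_ab(monomers$sequence[i], cset, delta,
                        max_assign_dist, params)
    monomers$ab_type[i] <- call$ab_type
    monomers$dist_A[i] <- call$dist_A
    monomers$dist_B[i] <- call$dist_B
    if (!is.null(call$prd)) {
      monomers$motif[i] <- call$prd$motif
      monomers$motif_offset[i] <- call$prd$offset
      monomers$motif_mismatches[i] <- call$prd$mismatches
      monomers$core_intact[i] <- call$prd$core_intact
      monomers$full_intact[i] <- call$prd$full_intact
    }
  }
  monomers
}

.monomer_seq <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)
  if (is.data.frame(x)) return(x$sequence[[1]])
  if (is.list(x) && !is.null(x$sequence)) return(x$sequence)
  stop("cannot interpret monomer")
}
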