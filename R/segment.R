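# Orientation detection, tandem period estimation and monomer
# segmentation.

#' Segmentation parameters
#'
#' @param align [align_params()].
#' @param min_len,max_len accepted monomer length range in bases. The
#'   defaults bracket the observed alphoid monomer range (consensuses run
#'   167-189 bp around the canonical 171).
#' @param min_flank_keep flanking fragments shorter than this are dropped
#'   rather than emitted as partial monomers.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(align = align_params(), min_len = 140,
                                max_len = 220, min_flank_keep = 100) {
  stopifnot(min_len < 171, 171 < max_len, min_flank_keep >= 0)
  structure(list(align = align, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_flank_keep = as.integer(min_flank_keep)),
            class = "segmentation_params")
}

#' Detect array orientation against a reference consensus
#'
#' Scores the best local alignment of the reference on both strands of the
#' array and returns the better strand. Arrays scoring below the floor on
#' both strands carry no recognizable alphoid signal.
#'
#' @param array a `sat_array` or plain sequence string.
#' @param ref reference consensus (entry, name, or sequence); degenerate
#'   symbols match any of their bases.
#' @param params [align_params()].
#' @param score_floor minimum acceptable local score (default 50).
#' @return `"forward"` or `"reverse"`.
#' @export
detect_orientation <- function(array, ref = "GGO_consensus",
                               params = align_params(), score_floor = 50) {
  seq <- .array_seq(array)
  refseq <- .entry_seq(ref)
  fwd <- Biostrings::score(.pw_align(refseq, seq, "local", params))
  rev <- Biostrings::score(.pw_align(refseq, revcomp(seq), "local", params))
  if (max(fwd, rev) < score_floor)
    stop("no alphoid signal: best local score ", max(fwd, rev),
         " below floor ", score_floor)
  if (fwd >= rev) "forward" else "reverse"
}

#' Normalize an array to forward orientation
#'
#' @inheritParams detect_orientation
#' @return A `sat_array` in forward orientation (reverse-complemented if
#'   needed), with the `orientation` field recording what was done.
#' @export
normalize_orientation <- function(array, ref = "GGO_consensus",
                                  params = align_params()) {
  id <- .array_id(array)
  seq <- .array_seq(array)
  o <- detect_orientation(seq, ref, params)
  if (o == "reverse") sat_array(id, revcomp(seq), "reverse-complemented")
  else sat_array(id, seq, "forward")
}

#' Estimate the dominant tandem period of an array
#'
#' Computes the base-identity autocorrelation of the array (fraction of
#' positions where the sequence matches itself shifted by `k`) for all lags
#' in `[min_len, max_len]` and returns the argmax. On a noise-free tandem
#' repeat of unit length L in range the profile is 1 exactly at L.
#'
#' @param array a `sat_array` or sequence string.
#' @param min_len,max_len lag range searched (defaults 140-220).
#' @param floor minimum autocorrelation to accept a period; below it the
#'   array is called non-tandem (random sequence sits near 0.25).
#' @return Period in bases, with the profile attached as attribute
#'   `"profile"`.
#' @export
estimate_period <- function(array, min_len = 140, max_len = 220,
                            floor = 0.45) {
  seq <- .array_seq(array)
  n <- nchar(seq)
  if (n < 2 * min_len)
    stop("array shorter than twice the minimum monomer length")
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  lags <- min_len:min(max_len, n - 1)
  ac <- vapply(lags, function(k) {
    mean(s[seq_len(n - k)] == s[(k + 1):n])
  }, numeric(1))
  names(ac) <- lags
  if (max(ac) < floor)
    stop("non-tandem: no periodicity in [", min_len, ", ", max_len,
         "] (max autocorrelation ", round(max(ac), 3), ")")
  k <- lags[which.max(ac)]
  structure(k, profile = ac)
}

#' Segment an array into head-to-tail monomers
#'
#' Anchor-and-extend decomposition: the best placement of the reference
#' consensus in the (orientation-normalized) array fixes the phase, then
#' monomer boundaries are propagated outwards in both directions by
#' repeatedly aligning the whole reference inside a window that starts (or
#' ends) at the last committed boundary. Cut points are the alignment ends,
#' so the emitted intervals tile the array exactly; flanking fragments
#' shorter than `min_flank_keep` are dropped and all other flanks or
#' out-of-range intervals are emitted with `partial = TRUE`.
#'
#' @param array a `sat_array` or sequence string, forward orientation
#'   (use [normalize_orientation()] first, or `normalize = TRUE`).
#' @param ref reference consensus (default the general gorilla consensus);
#'   degenerate symbols match any of their bases.
#' @param params [segmentation_params()].
#' @param normalize detect and normalize orientation first (default TRUE).
#' @return A data frame of class `monomer_set` with columns `array_id`,
#'   `index`, `start`, `end` (0-based half-open), `length`, `partial`,
#'   `sequence`. Ordered, non-overlapping and adjacent.
#' @export
segment_monomers <- function(array, ref = "GGO_consensus",
                             params = segmentation_params(),
                             normalize = TRUE) {
  id <- .array_id(array)
  refseq <- .entry_seq(ref)
  if (normalize) array <- normalize_orientation(array, refseq, params$align)
  seq <- .array_seq(array)
  n <- nchar(seq)
  empty <- .monomer_set(id, integer(0), integer(0), logical(0), seq)
  if (n < params$min_len) {
    warning("array '", id, "' shorter than min_len; no monomers emitted")
    return(empty)
  }
  ap <- params$align
  pad <- 30L
  win <- params$max_len + pad
  head_len <- 20L
  head_pat <- substr(refseq, 1L, head_len)
  rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = "")

  # anchor: best placement of the whole reference fixes the phase; the
  # anchor start is snapped onto the nearest strong match of the
  # reference head (the most conserved stretch of the monomer)
  anchor <- .pw_align(refseq, seq, "global-local", ap)
  a_start <- Biostrings::start(Biostrings::subject(anchor))
  lo <- max(1L, a_start - pad)
  mm <- .window_mismatches(substr(seq, lo, min(n, a_start + pad + head_len)),
                           head_pat)
  if (length(mm) && min(mm) <= 3L)
    a_start <- lo + which.min(mm) - 1L

  # one extension step: align the whole ref inside a window that starts
  # at the last committed boundary; prefer a cut at a strong reference-
  # head match in the admissible length range, fall back to the
  # alignment end. `rev` flips the head scan to end-anchored windows.
  step_cut <- function(w, refstr, headstr, rev) {
    hl <- nchar(headstr)
    L <- nchar(w)
    mm <- .window_mismatches(w, headstr)
    cut <- NA_integer_
    if (length(mm)) {
      if (!rev) {  # head starts at the cut + 1
        j <- (params$min_len + 1L):min(params$max_len + 1L, length(mm))
      } else {     # head ends at the cut
        j <- (params$min_len - hl + 1L):min(params$max_len - hl + 1L,
                                            length(mm))
      }
      j <- j[j >= 1]
      if (length(j) && min(mm[j]) <= 3L) {
        jbest <- j[which.min(mm[j])]
        cut <- if (!rev) jbest - 1L else jbest + hl - 1L
      }
    }
    if (is.na(cut)) {
      al <- .pw_align(refstr, w, "global-local", ap)
      cut <- Biostrings::end(Biostrings::subject(al))
    }
    cut
  }

  # rightward from the anchor start
  ends <- integer(0)
  pos <- a_start
  while (n - pos + 1L >= params$min_len) {
    w <- substr(seq, pos, min(n, pos + win - 1L))
    e <- pos + step_cut(w, refseq, head_pat, rev = FALSE) - 1L
    if (e < pos) break
    ends <- c(ends, min(e, n))
    pos <- e + 1L
  }

  # leftward: same procedure on the reversed strings, so every window
  # again starts at a committed boundary and only its far end is free
  rref <- rev_str(refseq)
  rhead <- rev_str(head_pat)
  rseq <- rev_str(seq)
  starts <- a_start
  pos <- n - a_start + 2L          # reversed coordinate just past anchor
  while (n - pos + 1L >= params$min_len) {
    w <- substr(rseq, pos, min(n, pos + win - 1L))
    e <- pos + step_cut(w, rref, rhead, rev = TRUE) - 1L
    if (e < pos) break
    starts <- c(n - min(e, n) + 1L, starts)
    pos <- e + 1L
  }

  cuts <- sort(unique(c(starts, ends + 1L)))  # 1-based starts of intervals
  first <- cuts[1]; last <- cuts[length(cuts)] - 1L
  s1 <- cuts[-length(cuts)]
  e1 <- cuts[-1] - 1L
  partial <- (e1 - s1 + 1L) < params$min_len | (e1 - s1 + 1L) > params$max_len

  # flanks
  if (first > 1L) {
    flank_len <- first - 1L
    if (flank_len >= params$min_flank_keep) {
      s1 <- c(1L, s1); e1 <- c(first - 1L, e1); partial <- c(TRUE, partial)
    }
  }
  if (last < n) {
    flank_len <- n - last
    if (flank_len >= params$min_flank_keep) {
      s1 <- c(s1, last + 1L); e1 <- c(e1, n); partial <- c(partial, TRUE)
    }
  }
  .monomer_set(id, s1, e1, partial, seq)
}

.monomer_set <- function(id, s1, e1, partial, seq) {
  out <- data.frame(
    array_id = rep(id, length(s1)),
    index = seq_along(s1),
    start = s1 - 1L,            # 0-based half-open
    end = e1,
    length = e1 - s1 + 1L,
    partial = partial,
    sequence = if (length(s1)) substring(seq, s1, e1) else character(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("monomer_set", "data.frame")
  out
}
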