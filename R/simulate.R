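# Ground-truth synthetic alphoid arrays built from the consensus set.

#' Resolve extended-alphabet symbols to concrete DNA
#'
#' Each IUPAC degeneracy code is replaced by a uniform draw from its
#' expansion set; gap codes (`F`, `I`, `J`, `O`) draw uniformly from
#' {absent, base}, so resolving can shorten the sequence. Deterministic
#' given `seed`.
#'
#' @param entry a consensus entry (one-row data frame), entry name, or
#'   plain sequence over the extended alphabet.
#' @param seed optional RNG seed.
#' @return A concrete DNA string over `{A,C,G,T}`.
#' @export
resolve_ambiguity <- function(entry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- if (is.data.frame(entry)) entry$sequence[[1]] else {
    if (nchar(entry) < 50 && entry %in% gorilla_consensuses()$name)
      consensus_entry(entry)$sequence else entry
  }
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(s), names(iupac_expand))
  if (length(bad)) stop("unknown symbol(s): ", paste(bad, collapse = ", "))
  out <- vapply(s, function(sym) {
    if (sym %in% c("A", "C", "G", "T")) return(sym)
    if (sym %in% names(.gap_codes)) {
      if (stats::runif(1) < 0.5) "" else .gap_codes[[sym]]
    } else {
      set <- iupac_expand[[sym]]
      set[sample.int(length(set), 1)]
    }
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' Simulation parameters for synthetic alphoid arrays
#'
#' @param sf family to simulate: `"SF1"` (dimeric), `"SF2"` (octameric,
#'   includes the 189-bp insertion monomer), `"SF3"` (pentameric) or
#'   `"monomeric"`.
#' @param n_units number of HOR units (for `"monomeric"`, the number of
#'   monomers).
#' @param sub_rate per-base substitution probability (HOR families;
#'   within-HOR divergence in real arrays is below 2%).
#' @param indel_rate per-base indel probability (default 0).
#' @param insertion_copies 1, 2 or 3 copies of the duplication unit at the
#'   gD1.4 position (SF2 only; extra copies model the further duplicated /
#'   triplicated insertions seen in shotgun contigs).
#' @param revcomp emit the reverse-complemented strand.
#' @param seed RNG seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sf = c("SF1", "SF2", "SF3", "monomeric"),
                       n_units = 4, sub_rate = 0, indel_rate = 0,
                       insertion_copies = 1, revcomp = FALSE, seed = NULL) {
  sf <- match.arg(sf)
  stopifnot(n_units >= 1, sub_rate >= 0, sub_rate <= 0.45,
            indel_rate >= 0, indel_rate <= 0.45,
            insertion_copies %in% 1:3)
  structure(list(sf = sf, n_units = as.integer(n_units),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 insertion_copies = as.integer(insertion_copies),
                 revcomp = isTRUE(revcomp), seed = seed),
            class = "sim_params")
}

.mutate_seq <- function(seq, sub_rate, indel_rate, protect = integer(0)) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    hit <- setdiff(hit, protect)
    for (i in hit) {
      s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
    }
  }
  if (indel_rate > 0) {
    keep <- stats::runif(n) >= indel_rate / 2
    keep[protect] <- TRUE
    s <- s[keep]
    n2 <- length(s)
    insat <- which(stats::runif(n2) < indel_rate / 2)
    if (length(insat)) {
      pieces <- as.list(s)
      for (i in rev(insat)) {
        pieces[[i]] <- c(pieces[[i]], sample(c("A", "C", "G", "T"), 1))
      }
      s <- unlist(pieces)
    }
  }
  paste(s, collapse = "")
}

#' Simulate a synthetic alphoid array with ground truth
#'
#' Builds one HOR unit by concatenating the family's consensus monomers in
#' their published succession (ambiguity codes resolved once per array),
#' tiles it `n_units` times, and applies i.i.d. substitutions. Monomeric
#' arrays draw every monomer from gM1 and mutate each at its own rate,
#' uniform in `[0.10, 0.40]`, emulating the divergence of HOR-less arrays.
#' For SF2, `insertion_copies` extra tandem copies of the gD1.4
#' duplication unit can be inserted. Truth (monomer boundaries on the
#' forward-normalized array, source consensus, A/B label, family, HOR
#' period, strand) is recorded exactly.
#'
#' @param params a [sim_params()].
#' @param cset consensus set (default [gorilla_consensuses()]).
#' @param protect_motifs when TRUE, substitutions never hit the 17-bp PRD
#'   of each source monomer (default FALSE).
#' @return A list: `array` (a `sat_array`), `truth` (list with
#'   `monomers` data frame - `index`, `start`, `end` 0-based half-open,
#'   `source`, `ab_type` -, `sf`, `period`, `strand`,
#'   `insertion_copies`).
#' @export
simulate_array <- function(params, cset = gorilla_consensuses(),
                           protect_motifs = FALSE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  sf_units <- attr(cset, "sf_units")
  monomeric <- params$sf == "monomeric"
  unit_names <- if (monomeric) rep("gM1", params$n_units)
                else rep(sf_units[[params$sf]], params$n_units)

  # resolve each distinct consensus once per array
  distinct <- unique(unit_names)
  resolved <- vapply(distinct, function(nm)
    resolve_ambiguity(consensus_entry(nm, cset)), character(1))

  if (params$sf == "SF2" && params$insertion_copies > 1) {
    resolved[["gD1.4"]] <- .expand_insertion(resolved[["gD1.4"]],
                                             params$insertion_copies)
  }

  mono_seqs <- character(length(unit_names))
  for (i in seq_along(unit_names)) {
    src <- resolved[[unit_names[i]]]
    rate <- if (monomeric) stats::runif(1, 0.10, 0.40) else params$sub_rate
    protect <- integer(0)
    if (protect_motifs) {
      hit <- scan_prd(src)
      if (!is.null(hit)) protect <- (hit$offset + 1L):(hit$offset + 17L)
    }
    mono_seqs[i] <- .mutate_seq(src, rate, params$indel_rate, protect)
  }
  lens <- nchar(mono_seqs)
  ends <- cumsum(lens)
  starts <- ends - lens
  seq_fwd <- paste(mono_seqs, collapse = "")

  ut <- cset$unit_type[match(unit_names, cset$name)]
  truth_monomers <- data.frame(
    index = seq_along(unit_names), start = as.integer(starts),
    end = as.integer(ends), source = unit_names,
    ab_type = ifelse(ut %in% c("A", "B"), ut, "undetermined"),
    stringsAsFactors = FALSE)

  out_seq <- if (params$revcomp) revcomp(seq_fwd) else seq_fwd
  id <- sprintf("sim_%s_x%d", params$sf, params$n_units)
  list(
    array = sat_array(id, out_seq,
                      if (params$revcomp) "unknown" else "forward"),
    truth = list(monomers = truth_monomers, sf = params$sf,
                 period = if (monomeric) NA_integer_
                          else length(sf_units[[params$sf]]),
                 strand = if (params$revcomp) "-" else "+",
                 insertion_copies = params$insertion_copies,
                 resolved = resolved)
  )
}

# insert extra tandem copies of the gD1.4 duplication unit. The insertion
# in gD1.4 is a tandem duplication whose second copy regenerates a complete
# CENP-B box; extra copies repeat the 22-bp unit right after the first.
.expand_insertion <- function(gd14, copies) {
  unit <- "CTTTGAGGATTTCGTTGGAAAC"
  at <- regexpr(unit, gd14, fixed = TRUE)
  if (at < 0) {
    # the resolved sequence mutated away the landmark; fall back to the
    # printed coordinates (unit occupies positions 48..69 of gD1.4)
    at <- 48L
  }
  paste0(substr(gd14, 1, at + nchar(unit) - 1L),
         paste(rep(unit, copies - 1L), collapse = ""),
         substr(gd14, at + nchar(unit), nchar(gd14)))
}
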