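# Suprachromosomal family assignment: nearest-consensus monomer
# assignment, then array-level concordance of monomer majority, HOR period
# and unit order.

#' Assign a monomer to its nearest consensus
#'
#' Returns the family/monomeric consensus (the sixteen unit consensuses;
#' the three general consensuses are excluded) minimizing the p-distance to
#' the monomer. Ties go to the lexicographically smallest name and are
#' flagged.
#'
#' @param monomer monomer sequence or monomer-table row.
#' @param cset a consensus set (default [gorilla_consensuses()]); a
#'   user-supplied set (e.g. human consensuses) may be given instead.
#' @param params [align_params()].
#' @return A list: `name`, `distance`, `tie` (logical).
#' @export
assign_monomer_sf <- function(monomer, cset = gorilla_consensuses(),
                              params = align_params()) {
  seq <- .monomer_seq(monomer)
  units <- cset[cset$sf != "general", , drop = FALSE]
  d <- vapply(units$sequence, function(cs) pairwise_pdist(cs, seq, params),
              numeric(1))
  names(d) <- units$name
  dmin <- min(d)
  hits <- sort(names(d)[d == dmin])
  list(name = hits[1], distance = unname(dmin), tie = length(hits) > 1)
}

#' Assign an array to a suprachromosomal family
#'
#' An array is assigned to a family only on concordant evidence: the HOR
#' period equals the family's unit count, at least `majority` of monomers
#' have their nearest consensus among the family's units, and (optionally)
#' the succession of nearest-unit labels matches the family's unit order up
#' to cyclic rotation. Arrays called monomeric by the HOR detector whose
#' monomers sit nearest gM1 (or fail every family majority) are
#' `"monomeric"`; everything else is `"unassigned"`.
#'
#' @param assignments list of per-monomer [assign_monomer_sf()] results (in
#'   array order), or a data frame with columns `name`, `distance`.
#' @param hor an `hor_call` for the same array.
#' @param cset the consensus set used for the assignments.
#' @param majority fraction of monomers that must belong to the family
#'   (default 0.8, tolerant of truncated units).
#' @param require_order require the cyclic unit order to match
#'   (default FALSE).
#' @return A list of class `sf_assignment`: `sf`, `per_monomer` (data
#'   frame), `order_match`.
#' @export
assign_array_sf <- function(assignments, hor, cset = gorilla_consensuses(),
                            majority = 0.8, require_order = FALSE) {
  per <- if (is.data.frame(assignments)) assignments
         else data.frame(
           name = vapply(assignments, `[[`, character(1), "name"),
           distance = vapply(assignments, `[[`, numeric(1), "distance"),
           stringsAsFactors = FALSE)
  sf_units <- attr(cset, "sf_units")
  hor_families <- setdiff(names(sf_units), "monomeric")

  sf <- "unassigned"
  order_match <- NA
  if (!is.na(hor$period) && hor$period > 1) {
    for (fam in hor_families) {
      units <- sf_units[[fam]]
      if (hor$period != length(units)) next
      frac <- mean(per$name %in% units)
      if (frac < majority) next
      om <- .order_matches(per$name, units)
      if (require_order && !om) next
      sf <- fam
      order_match <- om
      break
    }
  } else {
    # HOR-less (or fully homogenized) arrays: monomeric when the majority
    # of monomers sit nearest gM1 or no family reaches a majority
    frac_m <- mean(per$name %in% sf_units$monomeric)
    fam_major <- any(vapply(hor_families, function(fam)
      mean(per$name %in% sf_units[[fam]]) >= majority, logical(1)))
    if (frac_m >= majority || !fam_major) sf <- "monomeric"
  }
  structure(list(sf = sf, per_monomer = per, order_match = order_match),
            class = "sf_assignment")
}

# does the label succession match the unit order up to cyclic rotation?
.order_matches <- function(labels, units) {
  p <- length(units)
  for (r in seq_len(p)) {
    expected <- units[((r - 1 + seq_along(labels) - 1) %% p) + 1]
    if (all(labels == expected)) return(TRUE)
  }
  FALSE
}
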