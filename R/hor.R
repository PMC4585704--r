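# Higher-order repeat periodicity detection on the ordered monomer
# sequence of an array.

#' HOR calling parameters
#'
#' @param max_dist maximum mean p-distance at the period for a HOR call
#'   (default 0.10: between within-HOR divergence, under ~6%, and the
#'   10-40% divergence of monomeric arrays).
#' @param dominance the at-period distance must be at most `dominance`
#'   times the median off-period distance (default 0.5).
#' @param min_units minimum complete units (default 2).
#' @return An object of class `hor_params`.
#' @export
hor_params <- function(max_dist = 0.10, dominance = 0.5, min_units = 2) {
  stopifnot(max_dist > 0, max_dist < 0.5, min_units >= 2)
  structure(list(max_dist = max_dist, dominance = dominance,
                 min_units = as.integer(min_units)),
            class = "hor_params")
}

#' Monomer-lag periodicity profile of an array
#'
#' Computes the full pairwise p-distance matrix of the (non-partial)
#' monomers and, for each lag `k`, the mean distance between monomer `i`
#' and monomer `i + k` - the diagonal means of the dot-plot matrix.
#'
#' @param monomers monomer table (or character vector of monomer
#'   sequences) in array order.
#' @param params [align_params()].
#' @return An object of class `periodicity_profile`: `n`, `d` (named
#'   vector over lags `1..floor(n/2)`), `dist_matrix`.
#' @export
periodicity_profile <- function(monomers, params = align_params()) {
  seqs <- if (is.data.frame(monomers)) monomers$sequence[!monomers$partial]
          else as.character(monomers)
  n <- length(seqs)
  if (n < 4) stop("insufficient monomers: need at least 4, got ", n)
  D <- monomer_distance_matrix(seqs, params)
  ks <- seq_len(n %/% 2)
  d <- vapply(ks, function(k) {
    mean(D[cbind(seq_len(n - k), (k + 1):n)])
  }, numeric(1))
  names(d) <- ks
  structure(list(n = n, d = d, dist_matrix = D),
            class = "periodicity_profile")
}

#' Call the higher-order repeat structure of an array
#'
#' The period is the smallest lag `k` whose mean at-lag distance is at most
#' `max_dist`, is dominant over the median off-period distance, and leaves
#' at least `min_units` complete units. Lag 1 means a homogenized
#' (effectively monomeric) array; no qualifying lag means a monomeric
#' array. Periods 2-8 are labelled dimeric through octameric, larger ones
#' `other(k)`.
#'
#' @param profile a [periodicity_profile()].
#' @param params [hor_params()].
#' @return An object of class `hor_call`: `period` (integer or `NA`),
#'   `label`, `d_at_period`, `n_units`.
#' @export
call_hor <- function(profile, params = hor_params()) {
  n <- profile$n
  d <- profile$d
  ks <- as.integer(names(d))
  period <- NA_integer_
  for (k in ks) {
    if (n %/% k < params$min_units) next
    if (d[as.character(k)] > params$max_dist) next
    off <- ks[ks %% k != 0]
    if (length(off) > 0) {
      med <- stats::median(d[as.character(off)])
      if (d[as.character(k)] > params$dominance * med) next
    }
    period <- k
    break
  }
  if (is.na(period)) {
    return(structure(list(period = NA_integer_, label = "monomeric",
                          d_at_period = NA_real_, n_units = NA_integer_),
                     class = "hor_call"))
  }
  labels <- c("monomeric", "dimeric", "trimeric", "tetrameric",
              "pentameric", "hexameric", "heptameric", "octameric")
  label <- if (period <= 8) labels[period] else sprintf("other(%d)", period)
  structure(list(period = period, label = label,
                 d_at_period = unname(d[as.character(period)]),
                 n_units = n %/% period),
            class = "hor_call")
}
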