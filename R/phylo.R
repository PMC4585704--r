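# Neighbor-joining on p-distance matrices with deterministic tie-breaking,
# and column-resampling bootstrap support.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q criterion is joined, with ties broken by the lexicographically
#' smallest pair of cluster labels so the result is fully deterministic.
#' Negative branch lengths are clamped to zero; the number of clamped
#' edges is recorded in the attribute `"clamped"` of the returned tree.
#'
#' @param dm symmetric distance matrix with labels as dimnames (at least
#'   3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 labels for neighbor-joining")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  frag <- labels          # newick fragment per active cluster
  key <- labels           # smallest leaf label per cluster, for tie-breaks
  clamped <- 0L

  fmt <- function(x) sprintf("%.12g", x)
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }

  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    # candidate pairs at the minimum; tie-break on sorted label pair
    idx <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pk <- apply(idx, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    best <- idx[order(pk)[1], ]
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newkey <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
    n <- n - 1
  }
  a <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  cc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(a), frag[2], fmt(b), frag[3], fmt(cc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Neighbor-joining with bootstrap support
#'
#' Builds the NJ tree of the p-distance matrix of an alignment, then
#' resamples alignment columns with replacement `reps` times, rebuilds the
#' tree for each replicate and reports for each internal node the
#' percentage of replicates recovering its bipartition. Deterministic
#' given `seed`.
#'
#' @param aln a `monomer_alignment`, character matrix or vector of
#'   equal-length gapped rows (at least 10 columns).
#' @param reps bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @return The `phylo` tree with `node.label` set to supports in
#'   `[0, 100]` (the root label is empty).
#' @export
bootstrap_support <- function(aln, reps = 500, seed = NULL) {
  m <- .as_aln_matrix(aln)
  if (ncol(m) < 10) stop("alignment must have at least 10 columns")
  if (!is.null(seed)) set.seed(seed)
  main <- nj_tree(pdistance_matrix(m))
  boots <- vector("list", reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[b]] <- nj_tree(pdistance_matrix(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / reps, 1)
  main$node.label <- c("", as.character(support[-1]))
  attr(main, "support") <- support
  main
}

#' Pairwise path lengths of a tree
#'
#' Convenience wrapper around [ape::cophenetic.phylo()], used to check
#' that NJ reproduces additive distances.
#'
#' @param tree a `phylo` tree.
#' @return Symmetric matrix of leaf-to-leaf path lengths.
#' @export
tree_path_lengths <- function(tree) {
  stats::cophenetic(tree)
}
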