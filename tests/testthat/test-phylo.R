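test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AA-N", "AAAA"), 0)   # 2 comparable positions
  expect_equal(p_distance("ARGT", "AAGT"), 0)   # ambiguity removed
  expect_error(p_distance("--NN", "AAAA"), "no overlap")
  expect_error(p_distance("AAA", "AAAA"), "equal length")
})

test_that("three-taxon branch lengths follow the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("additive matrices are reproduced to machine precision", {
  for (s in 1:20) {
    set.seed(s)
    ref <- ape::rtree(7)
    ref$edge.length <- runif(nrow(ref$edge), 0.05, 0.5)
    D <- stats::cophenetic(ref)
    tr <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(ref), tr), 0,
                 ignore_attr = TRUE)
    got <- tree_path_lengths(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(got - D)), 1e-9)
    # independent implementation agrees on the topology
    expect_equal(ape::dist.topo(ape::nj(D), tr), 0, ignore_attr = TRUE)
  }
})

test_that("degenerate all-equal distances still give a valid binary tree", {
  n <- 6
  d <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_true(ape::is.binary(tr) || tr$Nnode == n - 2)
  expect_true(all(tr$edge.length >= 0))
  expect_setequal(tr$tip.label, letters[1:n])
})

test_that("A- and B-derived monomers split on the longest internal edge", {
  set.seed(77)
  ares <- resolve_ambiguity("GGO_consensus_Atype")
  bres <- resolve_ambiguity("GGO_consensus_Btype")
  seqs <- c(replicate(20, mutate_subs(ares, 0.02)),
            replicate(20, mutate_subs(bres, 0.02)))
  names(seqs) <- c(paste0("A", 1:20), paste0("B", 1:20))
  tr <- nj_tree(monomer_distance_matrix(seqs))
  internal <- tr$edge[, 2] > length(tr$tip.label)
  top <- which(internal)[which.max(tr$edge.length[internal])]
  node <- tr$edge[top, 2]
  clade <- ape::extract.clade(tr, node)$tip.label
  side <- substr(clade, 1, 1)
  other <- setdiff(tr$tip.label, clade)
  expect_equal(length(unique(side)), 1)
  expect_equal(length(unique(substr(other, 1, 1))), 1)
  expect_false(unique(side) == unique(substr(other, 1, 1)))
})

test_that("SF1 monomers never have an SF2-derived nearest neighbour", {
  sim1 <- simulate_array(sim_params("SF1", n_units = 4, sub_rate = 0.01,
                                    seed = 8))
  sim2 <- simulate_array(sim_params("SF2", n_units = 1, sub_rate = 0.01,
                                    seed = 8))
  m1 <- sim1$truth$monomers
  m2 <- sim2$truth$monomers
  seqs <- c(substring(sim1$array$sequence, m1$start + 1, m1$end),
            substring(sim2$array$sequence, m2$start + 1, m2$end))
  names(seqs) <- c(paste0("SF1_", seq_len(nrow(m1))),
                   paste0("SF2_", seq_len(nrow(m2))))
  D <- monomer_distance_matrix(seqs)
  diag(D) <- Inf
  nn <- rownames(D)[apply(D, 1, which.min)]
  is_sf1 <- startsWith(names(seqs), "SF1")
  expect_false(any(startsWith(nn[is_sf1], "SF2")))
})

test_that("bootstrap supports are deterministic and saturate clean splits", {
  set.seed(5)
  a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  b <- mutate_subs(a, 0.4)
  rows <- c(replicate(5, mutate_subs(a, 0.02)),
            replicate(5, mutate_subs(b, 0.02)))
  names(rows) <- paste0(rep(c("a", "b"), each = 5), 1:5)
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  t1 <- bootstrap_support(m, reps = 50, seed = 9)
  t2 <- bootstrap_support(m, reps = 50, seed = 9)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  s50 <- attr(t1, "support")
  t3 <- bootstrap_support(m, reps = 500, seed = 9)
  s500 <- attr(t3, "support")
  # the a/b split is clean: its support saturates at both depths
  expect_gte(max(s50, na.rm = TRUE), 98)
  expect_gte(max(s500, na.rm = TRUE), 98)
  expect_lt(abs(max(s50, na.rm = TRUE) - max(s500, na.rm = TRUE)), 10)
  expect_error(bootstrap_support(m[, 1:5]), "at least 10")
})
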