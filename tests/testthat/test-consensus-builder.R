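test_that("consensus of identical sequences is that sequence", {
  s <- cseq("gM1")
  aln <- align_monomers(rep(s, 5), ref = "gM1")
  expect_equal(sum(aln$matrix == "-"), 0)
  expect_equal(build_consensus(aln)$sequence, s)
})

test_that("noisy copies of a source consensus are recovered exactly", {
  sources <- c("gJ1", "gM1", "gD1.0", "gW3", "gD2.1")
  for (r in 1:10) {
    set.seed(r)
    src <- cseq(sources[(r %% length(sources)) + 1])
    copies <- replicate(20, mutate_subs(src, 0.05))
    cons <- build_consensus(align_monomers(copies, ref = src))
    expect_equal(cons$sequence, src)
  }
})

test_that("column rules follow the majority/ambiguity scheme", {
  col <- function(x) build_consensus(matrix(x, length(x), 1))$sequence
  expect_equal(col(c("A", "A", "A", "G")), "A")    # 75% > 50%
  expect_equal(col(c("A", "G")), "R")              # exact 50/50 -> code
  expect_equal(col(c("-", "G")), "J")              # gap code
  expect_equal(col(c("-", "T")), "O")              # configurable -/T code
  expect_equal(build_consensus(matrix(c("-", "T"), 2, 1),
                               t_gap_symbol = "U")$sequence, "U")
  expect_equal(col(c("A", "C", "G")), "V")
  expect_equal(col(c("-", "-", "-", "A")), "")     # majority gap: dropped
  # exactly-50% columns are never a single base
  expect_equal(col(c("A", "A", "C", "G", "T", "T")), "W")
  m <- matrix(c("A", "A", "C", "G", "T", "G", "C", "A"), 8, 1)
  expect_false(build_consensus(m)$sequence %in% c("A", "C", "G", "T"))
})

test_that("component frequency filter prunes rare symbols from codes", {
  colv <- c(rep("A", 4), rep("C", 4), rep("G", 2))   # 0.4/0.4/0.2
  expect_equal(build_consensus(matrix(colv, 10, 1))$sequence, "V")
  expect_equal(build_consensus(matrix(colv, 10, 1),
                               min_component_freq = 0.25)$sequence, "M")
})

test_that("rare insertions stay as metadata and rows reconstruct exactly", {
  aln <- align_monomers(c(cseq("gD1.0"), cseq("gD1.4")), ref = "gD1.0")
  ins_per_row <- vapply(1:2, function(i)
    sum(nchar(aln$insertions$seq[aln$insertions$row == i])), numeric(1))
  expect_equal(ins_per_row, c(0, 18))   # the 18-bp net insertion
  expect_equal(ncol(aln$matrix), 171)   # not opened as columns (1 of 2 rows)
  expect_equal(reconstruct_monomer(aln, 1), cseq("gD1.0"))
  expect_equal(reconstruct_monomer(aln, 2), cseq("gD1.4"))
})

test_that("insertions shared by most rows open alignment columns", {
  base <- substr(cseq("gM1"), 1, 60)
  with_ins <- paste0(substr(base, 1, 30), "TTTTT", substr(base, 31, 60))
  aln <- align_monomers(c(with_ins, with_ins, base), ref = base)
  expect_equal(ncol(aln$matrix), 65)
  expect_equal(nrow(aln$insertions), 0)
  for (i in 1:3)
    expect_equal(reconstruct_monomer(aln, i),
                 c(with_ins, with_ins, base)[i])
  # consensus sees the gap-or-base ambiguity at the inserted columns
  cons <- build_consensus(aln)
  expect_equal(cons$sequence,
               paste0(substr(base, 1, 30), "TTTTT", substr(base, 31, 60)))
})
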