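test_that("ambiguity resolution draws only from the symbol's set", {
  expect_equal(resolve_ambiguity("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"),
               "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT")
  rs <- vapply(1:200, function(s)
    resolve_ambiguity(paste0(strrep("A", 60), "R"), seed = s), character(1))
  last <- substr(rs, 61, 61)
  expect_setequal(unique(last), c("A", "G"))
  js <- vapply(1:200, function(s)
    resolve_ambiguity(paste0(strrep("A", 60), "J"), seed = s), character(1))
  expect_setequal(unique(nchar(js)), c(60L, 61L))
  expect_setequal(unique(substr(js[nchar(js) == 61], 61, 61)), "G")
  expect_error(resolve_ambiguity(paste0(strrep("A", 60), "Z")),
               "unknown symbol")
})

test_that("zero-noise arrays have the printed lengths and structure", {
  sim <- simulate_array(sim_params("SF2", n_units = 4, sub_rate = 0,
                                   insertion_copies = 1, seed = 1))
  expect_equal(nchar(sim$array$sequence), 5532L)  # 4 x (171+168+189+5*171)
  sim1 <- simulate_array(sim_params("SF1", n_units = 6, sub_rate = 0,
                                    seed = 1))
  tr <- sim1$truth$monomers
  expect_equal(nrow(tr), 12)
  expect_equal(tr$ab_type, rep(c("A", "B"), 6))
  expect_equal(tr$source, rep(c("gJ1", "gJ2"), 6))
})

test_that("simulation is deterministic given the seed", {
  p <- sim_params("SF3", n_units = 3, sub_rate = 0.05, seed = 123)
  s1 <- simulate_array(p)
  s2 <- simulate_array(p)
  expect_identical(s1$array$sequence, s2$array$sequence)
  expect_identical(s1$truth, s2$truth)
})

test_that("truth boundaries slice the emitted sequence consistently", {
  sim <- simulate_array(sim_params("SF3", n_units = 3, sub_rate = 0.10,
                                   seed = 6))
  tr <- sim$truth$monomers
  pieces <- substring(sim$array$sequence, tr$start + 1, tr$end)
  expect_equal(paste(pieces, collapse = ""), sim$array$sequence)
  expect_equal(tr$end[nrow(tr)], nchar(sim$array$sequence))
})

test_that("the realized substitution fraction tracks the nominal rate", {
  rate <- 0.05
  mism <- 0; total <- 0
  for (s in 1:30) {
    sim <- simulate_array(sim_params("SF1", n_units = 2, sub_rate = rate,
                                     seed = 200 + s))
    tr <- sim$truth$monomers
    for (i in seq_len(nrow(tr))) {
      src <- sim$truth$resolved[[tr$source[i]]]
      got <- substr(sim$array$sequence, tr$start[i] + 1, tr$end[i])
      a <- strsplit(src, "")[[1]]; b <- strsplit(got, "")[[1]]
      mism <- mism + sum(a != b)
      total <- total + length(a)
    }
  }
  # substitutions hit a random other base, so realized != source always
  se <- sqrt(rate * (1 - rate) / total)
  expect_lt(abs(mism / total - rate), 3 * se)
})

test_that("reverse-complement emission records the strand in the truth", {
  p <- sim_params("SF1", n_units = 3, sub_rate = 0, revcomp = TRUE,
                  seed = 4)
  sim <- simulate_array(p)
  expect_equal(sim$truth$strand, "-")
  fwd <- simulate_array(sim_params("SF1", n_units = 3, sub_rate = 0,
                                   seed = 4))
  expect_equal(revcomp(sim$array$sequence), fwd$array$sequence)
  # truth boundaries refer to the forward-normalized array
  tr <- sim$truth$monomers
  expect_equal(substring(fwd$array$sequence, tr$start + 1, tr$end)[1],
               fwd$truth$resolved[["gJ1"]])
})

test_that("monomeric arrays draw per-monomer divergence in 10-40%", {
  sim <- simulate_array(sim_params("monomeric", n_units = 10, seed = 2))
  tr <- sim$truth$monomers
  src <- sim$truth$resolved[["gM1"]]
  rates <- vapply(seq_len(nrow(tr)), function(i) {
    got <- substr(sim$array$sequence, tr$start[i] + 1, tr$end[i])
    mean(strsplit(src, "")[[1]] != strsplit(got, "")[[1]])
  }, numeric(1))
  expect_true(all(rates > 0.03 & rates < 0.45))
  expect_gt(max(rates) - min(rates), 0.02)  # heterogeneous, not one rate
})
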