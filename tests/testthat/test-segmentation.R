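test_that("zero-noise tandem arrays segment exactly", {
  r <- resolve_ambiguity("GGO_consensus", seed = 2)   # 172 bp concrete
  arr <- sat_array("t", paste(rep(r, 5), collapse = ""))
  mon <- segment_monomers(arr)
  expect_equal(nrow(mon), 5)
  expect_true(all(mon$length == 172))
  expect_equal(mon$start, (0:4) * 172L)
  expect_false(any(mon$partial))
})

test_that("zero-noise family units segment at the true boundaries", {
  for (sf in c("SF1", "SF2", "SF3")) {
    nu <- c(SF1 = 6, SF2 = 4, SF3 = 5)[[sf]]
    sim <- simulate_array(sim_params(sf, n_units = nu, sub_rate = 0,
                                     seed = 1))
    mon <- segment_monomers(sim$array)
    expect_equal(mon$start, sim$truth$monomers$start)
    expect_equal(mon$end, sim$truth$monomers$end)
  }
})

test_that("emitted intervals tile the array with no gaps or overlaps", {
  sim <- simulate_array(sim_params("SF2", n_units = 2, sub_rate = 0.02,
                                   seed = 11))
  mon <- segment_monomers(sim$array)
  expect_equal(mon$start[-1], mon$end[-nrow(mon)])
  expect_equal(paste(mon$sequence, collapse = ""),
               substr(sim$array$sequence, mon$start[1] + 1,
                      mon$end[nrow(mon)]))
})

test_that("segmentation is strand-invariant after normalization", {
  for (s in 1:3) {
    sim <- simulate_array(sim_params("SF1", n_units = 4, sub_rate = 0.02,
                                     seed = s))
    fwd <- segment_monomers(sim$array)
    rc <- segment_monomers(sat_array("rc", revcomp(sim$array$sequence)))
    expect_equal(rc$sequence, fwd$sequence)
    expect_equal(rc$start, fwd$start)
  }
})

test_that("boundary recovery stays above 99% within 3 bp at 2% noise", {
  cases <- rbind(
    data.frame(sf = "SF1", n_units = 6, seed = 1:10),
    data.frame(sf = "SF2", n_units = 2, seed = 1:5),
    data.frame(sf = "SF3", n_units = 3, seed = 1:5))
  hits <- 0; total <- 0
  for (i in seq_len(nrow(cases))) {
    sim <- simulate_array(sim_params(cases$sf[i], cases$n_units[i],
                                     sub_rate = 0.02, seed = cases$seed[i]))
    mon <- segment_monomers(sim$array)
    tb <- sim$truth$monomers$start
    hits <- hits + sum(vapply(tb, function(x)
      any(abs(mon$start - x) <= 3), logical(1)))
    total <- total + length(tb)
  }
  expect_gte(hits / total, 0.99)
})

test_that("degenerate inputs are handled", {
  expect_warning(mon <- segment_monomers(sat_array("s", "ACGTACGT"),
                                         normalize = FALSE),
                 "shorter than min_len")
  expect_equal(nrow(mon), 0)
  set.seed(9)
  rnd <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_error(segment_monomers(sat_array("r", rnd)), "no alphoid signal")
})

test_that("orientation detection is symmetric and floored", {
  r <- resolve_ambiguity("GGO_consensus", seed = 3)
  arr <- paste(rep(r, 5), collapse = "")
  expect_equal(detect_orientation(arr), "forward")
  expect_equal(detect_orientation(revcomp(arr)), "reverse")
  set.seed(10)
  rnd <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_error(detect_orientation(rnd), "no alphoid signal")
})

test_that("tandem period estimation finds the unit length", {
  mono <- substr(cseq("gM1"), 1, 171)
  expect_equal(as.integer(estimate_period(paste(rep(mono, 10),
                                                collapse = ""))), 171L)
  r <- resolve_ambiguity("GGO_consensus", seed = 2)  # 172 bp
  expect_equal(as.integer(estimate_period(paste(rep(r, 6),
                                                collapse = ""))), 172L)
  sim <- simulate_array(sim_params("SF2", n_units = 4, sub_rate = 0,
                                   seed = 1))
  p <- as.integer(estimate_period(sim$array))
  expect_gte(p, 168L); expect_lte(p, 189L)
  set.seed(4)
  rnd <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_error(estimate_period(rnd), "non-tandem")
})
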