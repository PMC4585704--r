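test_that("periodicity profile reflects exact repetition", {
  unit8 <- vapply(attr(cset, "sf_units")$SF2, cseq, character(1))
  mons <- rep(unname(unit8), 4)
  prof <- periodicity_profile(mons)
  expect_equal(unname(prof$d["8"]), 0)
  expect_true(all(prof$d >= 0 & prof$d <= 1))

  dimer <- rep(c(cseq("gJ1"), cseq("gJ2")), 6)
  pd <- periodicity_profile(dimer)
  expect_equal(unname(pd$d["2"]), 0)
  expect_gt(unname(pd$d["1"]), 0)

  expect_error(periodicity_profile(dimer[1:3]), "insufficient monomers")
})

test_that("zero at the fundamental period propagates to its multiples", {
  dimer <- rep(c(cseq("gJ1"), cseq("gJ2")), 8)   # n = 16
  prof <- periodicity_profile(dimer)
  mult <- seq(2, 8, by = 2)
  expect_true(all(prof$d[as.character(mult)] == 0))
  expect_equal(call_hor(prof)$period, 2L)        # smallest-k rule
})

test_that("HOR calls match the family structures at 1% noise", {
  sim2 <- simulate_array(sim_params("SF2", n_units = 4, sub_rate = 0.01,
                                    seed = 7))
  hor2 <- detect_hor(segment_monomers(sim2$array))
  expect_equal(hor2$label, "octameric")
  expect_equal(hor2$period, 8L)

  sim1 <- simulate_array(sim_params("SF1", n_units = 6, sub_rate = 0.01,
                                    seed = 7))
  hor1 <- detect_hor(segment_monomers(sim1$array))
  expect_equal(hor1$label, "dimeric")
  expect_equal(hor1$period, 2L)
})

test_that("monomeric arrays yield no qualifying period", {
  sim <- simulate_array(sim_params("monomeric", n_units = 8, seed = 5))
  prof <- periodicity_profile(segment_monomers(sim$array))
  expect_gt(min(prof$d), 0.10)
  expect_equal(call_hor(prof)$label, "monomeric")
})

test_that("too few monomers fall back to monomeric with a warning", {
  expect_warning(h <- detect_hor(rep(cseq("gM1"), 3)), "fewer than 4")
  expect_equal(h$label, "monomeric")
  expect_true(is.na(h$period))
})

test_that("the detector agrees with the brute-force partition oracle", {
  cases <- list(
    list(sf = "SF1", n_units = 4, rate = 0),
    list(sf = "SF1", n_units = 6, rate = 0.02),
    list(sf = "SF3", n_units = 2, rate = 0.01),
    list(sf = "monomeric", n_units = 8, rate = 0),
    list(sf = "monomeric", n_units = 10, rate = 0))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    sim <- simulate_array(sim_params(cs$sf, cs$n_units, cs$rate,
                                     seed = 20 + i))
    mon <- segment_monomers(sim$array)
    prof <- periodicity_profile(mon)
    got <- call_hor(prof)$period
    want <- oracle_hor_period(prof$dist_matrix)
    expect_equal(got, want, info = paste("case", i))
  }
  # homogenized tandem: both routes give the trivial period 1
  uni <- rep(substr(cseq("gM1"), 1, 171), 6)
  prof <- periodicity_profile(uni)
  expect_equal(call_hor(prof)$period, 1L)
  expect_equal(oracle_hor_period(prof$dist_matrix), 1L)
})

test_that("the true period is recovered across families and noise", {
  ok <- 0; total <- 0
  grid <- expand.grid(sf = c("SF1", "SF2", "SF3"), rate = c(0, 0.02),
                      seed = 1:3, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    nu <- c(SF1 = 4, SF2 = 2, SF3 = 2)[[grid$sf[i]]]
    sim <- simulate_array(sim_params(grid$sf[i], nu, grid$rate[i],
                                     seed = grid$seed[i]))
    hor <- detect_hor(segment_monomers(sim$array))
    total <- total + 1
    if (identical(hor$period, as.integer(sim$truth$period))) ok <- ok + 1
  }
  expect_gte(ok / total, 0.95)
})
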