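test_that("gamma rate profiles have the requested moments and are seeded", {
  r <- sampleRateProfile(1e4, shape = 2, scale = 0.5, seed = 11)
  seMean <- sqrt(2 * 0.5^2) / sqrt(1e4)
  expect_lt(abs(mean(r) - 1), 3 * seMean)
  # variance of the sample variance for a gamma: (mu4 - sigma^4)/n
  mu4 <- 3 * 0.5^4 * 2 * (2 + 2)  # gamma central 4th moment: 3 s^4 k (k+2)
  seVar <- sqrt((mu4 - 0.5^2) / 1e4)
  expect_lt(abs(var(r) - 0.5), 3 * seVar)
  expect_identical(r, sampleRateProfile(1e4, 2, 0.5, seed = 11))
  # degenerate gamma at fixed mean 1 collapses to constant rates
  r0 <- sampleRateProfile(3, shape = 1e6, scale = 1e-6, seed = 1)
  expect_equal(r0, rep(1, 3), tolerance = 0.01)
  expect_error(sampleRateProfile(10, shape = -1, scale = 1), "positive")
  expect_error(sampleRateProfile(10, shape = 1, scale = 0), "positive")
})

test_that("induced pauses reduce exactly the chosen interior sites", {
  rates <- rep(1, 50)
  expect_identical(inducePauses(rates, 0, 0.02, ell = 5), rates)
  out <- inducePauses(rates, 1, 0.02, ell = 5, seed = 3)
  expect_equal(sum(out != rates), 1)
  expect_equal(min(out), 0.02)
  hit <- which(out != rates)
  expect_gt(hit, 5)           # first ell codons excluded
  expect_lte(hit, 45)         # last ell codons excluded
  expect_identical(out, inducePauses(rates, 1, 0.02, ell = 5, seed = 3))
  # more pauses than eligible sites
  expect_error(inducePauses(rep(1, 12), 5, 0.5, ell = 5, seed = 1),
               "eligible")
  expect_error(inducePauses(rates, 1, 1.5), "between 0 and 1")
})

test_that("simulator reproduces the open-boundary TASEP closed forms", {
  # low-density phase (alpha < 1/2 <= beta): rho = alpha, J = alpha(1-alpha)
  reps <- lapply(1:4, function(s)
    simulateTasep(TasepParams(200, alpha = 0.2, beta = 1,
                              rates = rep(1, 200), ell = 1, seed = 100 + s,
                              burnInTime = 1500, sampleTime = 4000)))
  J <- vapply(reps, current, numeric(1))
  se <- stats::sd(J) / sqrt(length(J))
  expect_lt(abs(mean(J) - 0.16), 3 * se + 0.002)
  rho <- vapply(reps, function(d) mean(occupancy(d)[51:150]), numeric(1))
  seR <- stats::sd(rho) / sqrt(length(rho))
  expect_lt(abs(mean(rho) - 0.2), 3 * seR + 0.002)
  # maximal-current phase: J = 1/4
  repsMC <- lapply(1:4, function(s)
    simulateTasep(TasepParams(200, alpha = 0.9, beta = 0.9,
                              rates = rep(1, 200), ell = 1, seed = 200 + s,
                              burnInTime = 1500, sampleTime = 4000)))
  Jmc <- vapply(repsMC, current, numeric(1))
  seMC <- stats::sd(Jmc) / sqrt(length(Jmc))
  # finite-size correction to J = 1/4 is O(1/n); allow it in the floor
  expect_lt(abs(mean(Jmc) - 0.25), 3 * seMC + 0.004)
})

test_that("a closed entry gives an empty lattice and zero flux", {
  p <- TasepParams(50, alpha = 0, beta = 1, rates = rep(1, 50), ell = 1,
                   seed = 1, burnInTime = 10, sampleTime = 10)
  expect_warning(d <- simulateTasep(p), "low-confidence")
  expect_equal(sum(occupancy(d)), 0)
  expect_equal(current(d), 0)
  expect_true(d@lowConfidence)
})

test_that("hard exclusion and flux conservation hold in steady state", {
  p <- TasepParams(120, alpha = 0.5, beta = 1,
                   rates = sampleRateProfile(120, 2, 0.5, seed = 5),
                   ell = 10, seed = 6)
  d <- simulateTasep(p, recordHops = TRUE)
  occ <- occupancy(d)
  # no window of ell consecutive codons can hold more than one A-site
  win <- vapply(seq_len(120 - 9), function(i) sum(occ[i:(i + 9)]), numeric(1))
  expect_lte(max(win), 1 + 1e-9)
  # current through every interior bond agrees with the exit current
  h <- attr(d, "hop_current")[1:119]
  expect_lt(max(abs(h - current(d))), 6 * sqrt(current(d) / p@sampleTime) + 1e-3)
})

test_that("deterministic under seed and monotone in a single interior rate", {
  p <- TasepParams(80, alpha = 0.4, beta = 1, rates = rep(1, 80), ell = 3,
                   seed = 77, burnInTime = 500, sampleTime = 500)
  d1 <- simulateTasep(p); d2 <- simulateTasep(p)
  expect_identical(occupancy(d1), occupancy(d2))
  expect_identical(current(d1), current(d2))
  # decreasing one interior rate never increases the current (small grid)
  Js <- vapply(c(1, 0.5, 0.1), function(r) {
    rt <- rep(1, 80); rt[40] <- r
    current(simulateTasep(TasepParams(80, alpha = 0.4, beta = 1, rates = rt,
                                      ell = 3, seed = 99, burnInTime = 2000,
                                      sampleTime = 8000)))
  }, numeric(1))
  expect_true(all(diff(Js) <= 0.005))
})

test_that("flux sensitivity recovers the known rate-limiting step", {
  n <- 150
  init <- classifyRegime(TasepParams(n, alpha = 0.05, beta = 1,
                                     rates = rep(1, n), ell = 1, seed = 2,
                                     burnInTime = 1500, sampleTime = 20000))
  expect_identical(regimeLabel(init), "initiation_limited")
  rt <- rep(1, n); rt[70] <- 0.02
  elong <- classifyRegime(TasepParams(n, alpha = 0.5, beta = 1, rates = rt,
                                      ell = 1, seed = 2, burnInTime = 4000,
                                      sampleTime = 40000))
  expect_identical(regimeLabel(elong), "elongation_limited")
  term <- classifyRegime(TasepParams(n, alpha = 0.5, beta = 0.01,
                                     rates = rep(1, n), ell = 1, seed = 2,
                                     burnInTime = 2000, sampleTime = 20000))
  expect_identical(regimeLabel(term), "termination_limited")
})

test_that("undersampling is a seeded multinomial on the occupancy", {
  occ <- rep(0.05, 100)
  d <- new("DensityProfile", transcriptId = "u", occupancy = occ, current = 0.1)
  expect_equal(totalReads(undersampleFootprints(d, 0)), 0)
  s <- undersampleFootprints(d, 1e6, seed = 4)
  expect_equal(totalReads(s), 1e6)
  # uniform probabilities: every codon within 4 SD of 1e4
  sd1 <- sqrt(1e6 * 0.01 * 0.99)
  expect_true(all(abs(footprintCounts(s) - 1e4) <= 4 * sd1))
  expect_identical(footprintCounts(s),
                   footprintCounts(undersampleFootprints(d, 1e6, seed = 4)))
  d0 <- new("DensityProfile", transcriptId = "z", occupancy = rep(0, 10),
            current = 0)
  expect_error(undersampleFootprints(d0, 10), "all-zero")
})

test_that("simulation cohorts are labelled, length-bounded and reproducible", {
  cfg <- cohortConfig(classes = c("elongation_limited", "null"),
                      nPerClass = 3, lengthRange = c(120, 300),
                      depthPerCodon = 2, masterSeed = 42)
  coh <- runSimulationCohort(cfg)
  expect_s4_class(coh, "SimulationCohort")
  truth <- cohortTruth(coh)
  expect_equal(nrow(truth), 6)
  expect_equal(sum(truth$regime == "elongation_limited"), 3)
  lens <- vapply(cohortPairs(coh), `[[`, integer(1), "nCodons")
  expect_true(all(lens >= 120 & lens <= 300))
  coh2 <- runSimulationCohort(cfg)
  expect_identical(footprintCounts(cohortPairs(coh)[[1]]$mutant),
                   footprintCounts(cohortPairs(coh2)[[1]]$mutant))
  expect_error(cohortConfig(classes = character(0)), "empty class")
  expect_error(cohortConfig(classes = "weird_class"), "unknown cohort class")
})
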