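# Genetic-algorithm dynamics and trajectory analytics.

test_that("deltaPR obeys its defining identities", {
  # one amino acid everywhere -> zero asymmetry
  a <- codeAssignments(sgcCode())
  a[a != STOP_SYMBOL] <- "G"
  expect_identical(deltaPR(geneticCode(a)), 0)
  # mirroring left/right halves (2nd base U<->A, C<->G swap) negates it,
  # up to the sense-position imbalance from the pinned stops: build a code
  # whose mirror is stop-compatible by keeping the UA_/UG_ rows uniform
  set.seed(21)
  b2 <- substr(codonTriple(1:64), 2, 2)
  a <- sample(AA_ORDER, 64, replace = TRUE)
  a[substr(codonTriple(1:64), 1, 1) == "U"] <- "S"  # whole U row uniform
  idx <- seq_len(64) - 1L
  mirrorB2 <- c(U = "A", C = "G", A = "U", G = "C")
  mirrored <- paste0(substr(codonTriple(1:64), 1, 1),
                     mirrorB2[b2], substr(codonTriple(1:64), 3, 3))
  am <- a[codonIndex(mirrored)]
  a0 <- a; a0[sgcStopPositions()] <- STOP_SYMBOL
  am[sgcStopPositions()] <- STOP_SYMBOL
  d1 <- deltaPR(geneticCode(a0))
  d2 <- deltaPR(geneticCode(am))
  expect_equal(d2, -d1, tolerance = 0.15)  # stops break exact antisymmetry
  # the standard code is right-enriched (high PR in the A column)
  expect_gt(deltaPR(sgcCode()), 0)
})

test_that("selection-only dynamics are nonincreasing and converge", {
  cfg <- gaConfig(N = 8L, mu = 0, generations = 8L)
  ga <- gaRun(3, cfg, seed = 22L, recordPopulations = TRUE)
  for (r in 1:3) {
    expect_true(all(diff(ga@bestCost[, r]) <= 1e-12))
  }
  # with mu = 0 the population collapses onto copies of the running best
  pops <- attr(ga, "populations")
  final <- pops[[length(pops)]]
  expect_true(all(final == final[, 1]))
})

test_that("selection and refill match the hand-simulated step", {
  # mu = 0 makes the generation update deterministic given the ranking:
  # survivors are the N/2 cheapest codes and each is copied exactly once
  cfg <- gaConfig(N = 6L, mu = 0, generations = 1L)
  ga <- gaRun(1, cfg, seed = 23L, recordPopulations = TRUE)
  pop1 <- attr(ga, "populations")[[1]]
  ctx <- codonscape:::.fullContext()
  costs1 <- apply(pop1, 2, function(a) codonscape:::.cpp_cost(a, ctx))
  # the refilled population holds each survivor exactly twice
  key <- apply(pop1, 2, paste, collapse = ",")
  expect_true(all(table(key) == 2L))
  # and the three distinct codes are the three cheapest of the population
  # they were selected from; with one generation and mu = 0 the best cost
  # equals the recorded generation-1 best
  expect_equal(min(costs1), ga@bestCost[1, 1], tolerance = 1e-12)
})

test_that("every individual satisfies the ensemble constraints", {
  cfg <- gaConfig(N = 10L, generations = 15L)
  ga <- gaRun(2, cfg, seed = 24L, recordPopulations = TRUE)
  pops <- attr(ga, "populations")
  for (g in c(1L, 8L, 15L)) {
    pop <- pops[[g]]
    for (i in seq_len(ncol(pop))) {
      code <- codonscape:::.intToCode(pop[, i])
      expect_identical(validateCode(code), character(0))
    }
  }
})

test_that("GA runs are seed-reproducible and elitist", {
  cfg <- gaConfig(N = 20L, generations = 30L)
  g1 <- gaRun(2, cfg, seed = 25L)
  g2 <- gaRun(2, cfg, seed = 25L)
  expect_identical(g1@bestCost, g2@bestCost)
  expect_identical(g1@bestDpr, g2@bestDpr)
  expect_identical(g1@sliceCodes, g2@sliceCodes)
  # elitism: best cost never rises when survivors persist unmutated
  expect_true(all(apply(g1@bestCost, 2, function(x) all(diff(x) <= 1e-12))))
  # the alternative reading (mutating survivors) is allowed to climb
  g3 <- gaRun(2, gaConfig(N = 20L, generations = 30L,
                          mutateSurvivors = TRUE), seed = 25L)
  expect_false(all(apply(g3@bestCost, 2, function(x) all(diff(x) <= 1e-12))))
})

test_that("trajectoryStats aggregates transitions and latest values", {
  # a synthetic two-run batch exercised through the public container
  bestCost <- cbind(c(5.0, 4.0, 3.0, 3.0, 2.0),
                    c(5.0, 4.5, 4.0, 3.5, 3.0))
  bestDpr <- cbind(c(1, -1, -1, 1, 1),    # two sign changes
                   c(1, 1, 1, 1, 1))      # none
  batch <- new("GABatch", bestCost = bestCost, bestDpr = bestDpr,
               sliceCodes = matrix(NA_integer_, 61, 2),
               sliceCost = c(NA_real_, NA_real_),
               sliceGen = c(NA_integer_, NA_integer_),
               reached = c(TRUE, FALSE), config = list(), seed = 1L)
  ts <- trajectoryStats(batch, binWidth = 1)
  # run 2 never changes sign: all its visited bins contribute 0 transitions
  expect_equal(sum(ts$transitions$posToNeg * ts$visits, na.rm = TRUE), 1)
  expect_equal(sum(ts$transitions$negToPos * ts$visits, na.rm = TRUE), 1)
  # latest value at a revisited bin is the most recent one
  expect_equal(ts$latest[1, ts$bins == 3.5], 1)   # cost 3.0 visited twice
  # negative fraction: run 1 contributes its two negative generations
  expect_equal(sum(ts$negFraction * ts$visits, na.rm = TRUE), 2)
  # conditional curve only counts the run that reached the slice
  expect_equal(sum(ts$negFractionReached * ts$visitsReached, na.rm = TRUE), 2)
})

test_that("asymmetry transitions freeze early in real GA runs", {
  ga <- gaRun(100, seed = 26L)
  ts <- trajectoryStats(ga)
  low <- ts$bins < 4 & ts$visits > 50
  high <- ts$bins > 6 & ts$bins < 13 & ts$visits > 50
  expect_gt(sum(low), 0L); expect_gt(sum(high), 0L)
  rLow <- sum(ts$transitions$either[low] * ts$visits[low]) / sum(ts$visits[low])
  rHigh <- sum(ts$transitions$either[high] * ts$visits[high]) /
    sum(ts$visits[high])
  expect_lt(rLow, 0.1 * rHigh)
})
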