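# Misreading weights, the cost function and the incremental update.

test_that("misreading weights follow the position/TS-TV classes", {
  mw <- misreadingWeights()
  key <- paste(mw@from, mw@to)
  w <- stats::setNames(mw@weight, key)
  pair <- function(c1, c2) w[[paste(codonIndex(c1), codonIndex(c2))]]
  expect_identical(pair("GUG", "GUA"), 1)    # 3rd base, any change
  expect_identical(pair("GUG", "AUG"), 1)    # 1st base TS (G->A)
  expect_identical(pair("GUG", "CUG"), 0.5)  # 1st base TV
  expect_identical(pair("GUG", "GCG"), 0.5)  # 2nd base TS (U->C)
  expect_identical(pair("GUG", "GAG"), 0.1)  # 2nd base TV
  # double/triple changes carry no weight: absent from the sparse pairs
  expect_false(paste(codonIndex("GUG"), codonIndex("AAG")) %in% key)
  expect_false(paste(codonIndex("UUU"), codonIndex("AAA")) %in% key)
  # every codon has exactly 9 weighted neighbours, raw sum 5.7 each
  perCodon <- tapply(mw@weight, mw@from, sum)
  expect_identical(length(perCodon), 64L)
  expect_true(all(abs(perCodon - 5.7) < 1e-12))
  expect_identical(unname(table(mw@from)[1]), 9L)
  # weights are symmetric in the raw classes
  expect_equal(w[paste(mw@to, mw@from)], w, ignore_attr = TRUE)
})

test_that("codeCost matches a hand enumeration and the known identities", {
  # uniform code: one amino acid everywhere -> zero cost
  uni <- codeAssignments(sgcCode())
  uni[uni != STOP_SYMBOL] <- "L"
  expect_identical(codeCost(geneticCode(uni)), 0)
  # independent oracle: direct double loop over all ordered codon pairs
  pr <- scaleValues(polarRequirement())
  purine <- c(U = FALSE, C = FALSE, A = TRUE, G = TRUE)
  rawW <- function(c1, c2) {
    b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
    dd <- which(b1 != b2)
    if (length(dd) != 1L) return(0)
    ts <- purine[b1[dd]] == purine[b2[dd]]
    if (dd == 3) 1 else if (dd == 1) ifelse(ts, 1, 0.5) else ifelse(ts, 0.5, 0.1)
  }
  oracle <- function(code) {
    a <- codeAssignments(code)
    num <- den <- 0
    for (i in 1:64) for (j in 1:64) {
      if (i == j || a[i] == STOP_SYMBOL || a[j] == STOP_SYMBOL) next
      w <- rawW(codonTriple(i), codonTriple(j))
      if (w == 0) next
      num <- num + w * (pr[[a[i]]] - pr[[a[j]]])^2
      den <- den + w
    }
    unname(num / den)
  }
  expect_equal(codeCost(sgcCode()), oracle(sgcCode()), tolerance = 1e-12)
  set.seed(42)
  rnd <- naiveSample(3, seed = 42)
  for (i in 1:3) {
    code <- sampleCode(rnd, i)
    expect_equal(codeCost(code), oracle(code), tolerance = 1e-12)
    expect_equal(codeCost(code), sampleCosts(rnd)[i], tolerance = 1e-12)
  }
})

test_that("cost is invariant under value-preserving and table symmetries", {
  # Leu and Ile share polar requirement 4.9: swapping them changes nothing
  a <- codeAssignments(sgcCode())
  swapped <- a
  swapped[a == "L"] <- "I"; swapped[a == "I"] <- "L"
  expect_equal(codeCost(geneticCode(swapped)), codeCost(sgcCode()),
               tolerance = 1e-12)
  # 1st-base A<->G exchange preserves TS/TV classes and stop positions
  idx <- seq_len(64)
  b1 <- (idx - 1L) %/% 16L
  perm <- idx + ifelse(b1 == 2L, 16L, ifelse(b1 == 3L, -16L, 0L))
  set.seed(7)
  for (i in 1:5) {
    code <- sampleCode(naiveSample(1, seed = i), 1)
    mirrored <- geneticCode(codeAssignments(code)[perm])
    expect_equal(codeCost(mirrored), codeCost(code), tolerance = 1e-12)
  }
})

test_that("squared-difference cost is nonnegative, zero iff flat in value", {
  set.seed(11)
  s <- naiveSample(20, seed = 11)
  expect_true(all(sampleCosts(s) > 0))
  # equal property values everywhere <=> zero (L/I-only code has one value)
  a <- codeAssignments(sgcCode())
  a[a != STOP_SYMBOL] <- sample(c("L", "I"), 61, replace = TRUE)
  expect_equal(codeCost(geneticCode(a)), 0, tolerance = 1e-15)
})

test_that("deltaCost equals full recomputation and is antisymmetric", {
  set.seed(3)
  sense <- setdiff(1:64, sgcStopPositions())
  batch <- naiveSample(20, seed = 3)
  for (i in seq_len(20)) {
    code <- sampleCode(batch, i)
    for (r in 1:50) {
      pos <- sample(sense, 1)
      cur <- codeAssignments(code)[pos]
      new <- sample(setdiff(AA_ORDER, cur), 1)
      d <- deltaCost(code, pos, new)
      a2 <- codeAssignments(code); a2[pos] <- new
      flipped <- geneticCode(a2)
      expect_equal(d, codeCost(flipped) - codeCost(code), tolerance = 1e-9)
      # reverse flip negates the delta
      expect_equal(deltaCost(flipped, pos, cur), -d, tolerance = 1e-9)
    }
  }
  # flipping to an equal-valued amino acid gives exactly zero
  a <- codeAssignments(sgcCode())
  posL <- which(a == "L")[1]
  expect_equal(deltaCost(sgcCode(), posL, "I"), 0, tolerance = 1e-12)
  # stop positions are rejected
  expect_error(deltaCost(sgcCode(), codonIndex("UAA"), "K"), "pinned")
})

test_that("stop costs shift only the baseline when nonzero", {
  cfgDefault <- costConfig()
  cfg <- costConfig(c0 = 2, c1 = 3)
  c1 <- codeCost(sgcCode(), cfg)
  set.seed(5)
  code2 <- sampleCode(naiveSample(1, seed = 5), 1)
  c2 <- codeCost(code2, cfg)
  # cost differences between codes are preserved up to the common rescaling
  # of the denominator (stop-pair weights are code-independent)
  mw <- misreadingWeights()
  stops <- sgcStopPositions()
  wStop <- sum(mw@weight[(mw@from %in% stops) | (mw@to %in% stops)])
  scale <- mw@normalization / (mw@normalization + wStop)
  expect_equal(c1 - c2,
               (codeCost(sgcCode()) - codeCost(code2)) * scale,
               tolerance = 1e-10)
})

test_that("matrix-derived and frequency-weighted variants behave sanely", {
  m <- readSubstitutionMatrix(system.file("extdata", "BLOSUM62.txt",
                                          package = "codonscape"))
  expect_identical(dim(m), c(20L, 20L))
  expect_identical(m["W", "W"], 11)
  expect_identical(m["A", "R"], m["R", "A"])
  pen <- scorePenalty(m, name = "BLOSUM62")
  d <- penaltyMatrix(pen)
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  # the standard code is far more robust than block-random codes under the
  # score-derived penalty too
  cfg <- costConfig(penalty = pen)
  sgcB <- codeCost(sgcCode(), cfg)
  blk <- blockSample(200, seed = 9, config = cfg, keepCodes = TRUE)
  expect_lt(sgcB, stats::quantile(sampleCosts(blk), 0.05))
  # uniform frequencies reproduce the unweighted cost
  fr <- stats::setNames(rep(1, 20), AA_ORDER)
  expect_equal(codeCost(sgcCode(), costConfig(freq = fr)),
               codeCost(sgcCode()), tolerance = 1e-12)
  # up-weighting errors on a heavy amino acid moves the cost
  fr["D"] <- 50
  expect_false(isTRUE(all.equal(codeCost(sgcCode(), costConfig(freq = fr)),
                                codeCost(sgcCode()))))
})
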