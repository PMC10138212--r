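# Codon indexing, the standard-code fixture, constraints, exact counting.

test_that("codon indexing is the UUU..GGG bijection", {
  expect_identical(codonIndex("UUU"), 1L)
  expect_identical(codonIndex("GGG"), 64L)
  # round-trip over all 64 triples
  expect_identical(codonIndex(codonTriple(1:64)), 1:64)
  expect_identical(anyDuplicated(codonTriple(1:64)), 0L)
  # index arithmetic: 16 b1 + 4 b2 + b3 (U=0, C=1, A=2, G=3)
  expect_identical(codonIndex("CAG"), 16L * 1L + 4L * 2L + 3L + 1L)
  expect_identical(codonIndex("TTT"), 1L)  # DNA alphabet accepted
  expect_error(codonIndex("UXU"), "valid base")
})

test_that("transitions are within-purine or within-pyrimidine interchanges", {
  expect_true(isTransition("A", "G"))
  expect_true(isTransition("C", "U"))
  expect_false(isTransition("A", "C"))
  expect_false(isTransition("G", "U"))
  pairs <- expand.grid(b1 = RNA_BASES, b2 = RNA_BASES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$b1 != pairs$b2, ]
  ts <- mapply(isTransition, pairs$b1, pairs$b2)
  expect_identical(sum(ts), 4L)  # 4 of the 12 ordered distinct pairs
  expect_error(isTransition("A", "A"), "differ")
})

test_that("the standard code fixture has the canonical structure", {
  sgc <- sgcCode()
  a <- codeAssignments(sgc)
  expect_identical(length(a), 64L)
  expect_identical(sum(a == STOP_SYMBOL), 3L)
  expect_identical(sgcStopPositions(),
                   codonIndex(c("UAA", "UAG", "UGA")))
  counts <- table(a[a != STOP_SYMBOL])
  expect_setequal(names(counts), AA_ORDER)        # all 20 present
  expect_identical(unname(counts[["D"]]), 2L)     # Asp exactly twice
  expect_identical(unname(counts[["E"]]), 2L)     # Glu exactly twice
  expect_identical(a[codonIndex("AUG")], "M")
  expect_identical(a[codonIndex("UGG")], "W")
})

test_that("the fixture matches the Biostrings codon table", {
  skip_if_not_installed("Biostrings")
  gc <- Biostrings::GENETIC_CODE
  triples <- gsub("U", "T", codonTriple(1:64))
  expect_identical(unname(gc[triples]), codeAssignments(sgcCode()))
})

test_that("polar requirement has Asp and Glu as its two maxima", {
  v <- scaleValues(polarRequirement())
  expect_identical(length(v), 20L)
  expect_true(all(is.finite(v)))
  expect_identical(names(sort(v, decreasing = TRUE))[1:2], c("D", "E"))
  # shipped CSV fixture is in sync with the in-code scale
  csv <- readPropertyScale(system.file("extdata", "polar_requirement.csv",
                                       package = "codonscape"))
  expect_equal(scaleValues(csv), v)
})

test_that("validateCode reports each violated condition as data", {
  expect_identical(validateCode(sgcCode()), character(0))
  # a stop moved off its standard position
  a <- codeAssignments(sgcCode())
  a[codonIndex("UAA")] <- "K"
  a[codonIndex("AAA")] <- STOP_SYMBOL
  expect_match(validateCode(geneticCode(a)), "condition 2", all = FALSE)
  # single Asp violates the multiplicity floor
  a <- codeAssignments(sgcCode())
  a[codonIndex("GAU")] <- "N"
  v <- validateCode(geneticCode(a))
  expect_length(v, 1L)
  expect_match(v, "Asp.*condition 4")
  # relaxed ensemble accepts the same code
  expect_identical(validateCode(geneticCode(a),
                                ensembleConstraints(minAsp = 1L,
                                                    minGlu = 1L)),
                   character(0))
  # removing the last copy of an amino acid -> exactly one condition-3 hit
  a <- codeAssignments(sgcCode())
  a[codonIndex("AUG")] <- "I"  # Met is a singleton in the SGC
  v <- validateCode(geneticCode(a))
  expect_length(v, 1L)
  expect_match(v, "condition 3")
})

test_that("exact ensemble counting agrees with brute force on toy spaces", {
  # 4 positions, 2 symbols, surjective: 2^4 - 2 = 14
  expect_identical(countEnsemble(nFree = 4, minCount = c(1L, 1L))$count, "14")
  # 1 position, 1 symbol, surjective
  expect_identical(countEnsemble(nFree = 1, minCount = 1L)$count, "1")
  # multiplicity floors against direct enumeration
  bruteCount <- function(n, minCount) {
    states <- as.matrix(expand.grid(rep(list(seq_along(minCount)), n)))
    sum(apply(states, 1, function(a)
      all(tabulate(a, length(minCount)) >= minCount)))
  }
  cases <- list(list(n = 6, mc = c(1L, 1L, 2L)),
                list(n = 5, mc = c(0L, 1L, 2L)),
                list(n = 7, mc = c(2L, 2L, 1L)),
                list(n = 8, mc = c(0L, 0L, 1L, 1L)))
  for (cs in cases) {
    expect_identical(countEnsemble(nFree = cs$n, minCount = cs$mc)$count,
                     as.character(bruteCount(cs$n, cs$mc)),
                     label = paste("n =", cs$n))
  }
  # impossible constraints count zero
  expect_identical(countEnsemble(nFree = 2, minCount = c(2L, 2L))$count, "0")
})

test_that("the full ensemble count is exact and consistent on the log scale", {
  ce <- countEnsemble()
  # cross-check the exact integer against log-scale floating arithmetic
  lsurj <- function(n, k) {
    i <- 0:(k - 1)
    m <- max(t0 <- lchoose(k, i) + n * log(k - i))
    log(sum((-1)^i * exp(t0 - m))) + m
  }
  lf <- -Inf
  for (a in 2:41) for (b in 2:(61 - a - 18)) {
    t0 <- lchoose(61, a) + lchoose(61 - a, b) + lsurj(61 - a - b, 18)
    lf <- max(lf, t0) + log1p(exp(min(lf, t0) - max(lf, t0)))
  }
  expect_equal(ce$log10, lf / log(10), tolerance = 1e-10)
  expect_identical(nchar(ce$count), 79L)  # 6.1e78 has 79 digits
  # relaxed ensemble is strictly larger
  expect_gt(countEnsemble(ensembleConstraints(minAsp = 1L, minGlu = 1L))$log10,
            ce$log10)
})
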