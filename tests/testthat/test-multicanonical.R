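# Wang-Landau training, multicanonical sampling and density-of-states
# estimation, validated against exhaustive enumeration on toy systems.

test_that("cost grids bin half-open with edge clamping", {
  g <- costGrid(2, 4, 0.5)
  expect_identical(g@nBins, 4L)
  expect_identical(binIndex(g, c(2, 2.49, 2.5, 3.99, 4.2, 1.0)),
                   c(1L, 1L, 2L, 4L, 4L, 1L) + 0L)
  expect_equal(binMidpoints(g), c(2.25, 2.75, 3.25, 3.75))
})

test_that("a uniform-DOS system trains to constant weights", {
  # single-symbol floor-free toy with one amino acid: every state costs 0;
  # use instead a 2-symbol equal-value system: all assignments cost 0, so
  # the DOS is a point mass and the weight is constant where defined
  toy <- makeToy(2L, 2L, 2L, seed = 2L, minTop = 0L, requireAll = FALSE)
  toy@ctx$d[] <- 0  # equal penalty: strictly uniform DOS over one bin
  g <- costGrid(0, 1, 0.1)
  w <- wangLandau(toy, g, wlSchedule(checkEvery = 1e3, maxSteps = 1e7),
                  seed = 3L)
  expect_identical(sum(w@visited), 1L)
  expect_true(all(is.finite(w@logw)))
  expect_equal(diff(range(w@logw)), 0)
})

test_that("toy DOS matches exact enumeration within tolerance", {
  toy <- midToy()
  ex <- exactDOS(toy, costGrid(0, 60, 0.25))
  cnt <- attr(ex, "counts")
  grid <- costGrid(0, 60, 0.25)
  w <- wangLandau(toy, grid, wlSchedule(checkEvery = 1e4, maxSteps = 1e8),
                  seed = 4L)
  run <- mucaSample(w, toy, steps = 1e7, seed = 5L, thin = 10L,
                    trackDeltaPR = FALSE)
  dos <- estimateDOS(run$hist, w, mode = "count",
                     totalCount = attr(ex, "total"))
  sel <- dos@visited & cnt > 0
  expect_gt(sum(sel), 20L)
  err <- dos@logdos[sel] / log(10) - log10(cnt[sel])
  expect_lt(max(abs(err)), 0.2)  # per-bin exactness on the enumerable toy
  # tail fractions against enumeration, across several thresholds
  dosF <- estimateDOS(run$hist, w, mode = "fraction")
  edges <- grid@lower + seq_len(grid@nBins) * grid@width
  for (thr in attr(ex, "minCost") + c(3, 6, 10)) {
    exact <- sum(cnt[edges <= thr]) / attr(ex, "total")
    est <- tailFraction(dosF, thr)
    if (exact > 0)
      expect_lt(abs(log10(est) - log10(exact)), 0.2)
  }
})

test_that("fixed-weight chains produce flat histograms and obey balance", {
  toy <- midToy()
  grid <- costGrid(0, 60, 0.5)
  w <- wangLandau(toy, grid, wlSchedule(checkEvery = 1e4, maxSteps = 1e8),
                  seed = 6L)
  run <- mucaSample(w, toy, steps = 1e7, seed = 7L, thin = 100L,
                    trackDeltaPR = FALSE, trackFlow = TRUE)
  # flat-histogram property over visited bins
  expect_gt(flatness(run$hist), 0.5)
  # detailed balance: long-run bin-to-bin flows are symmetric
  fl <- run$flow
  ij <- which(fl + t(fl) >= 200 & upper.tri(fl), arr.ind = TRUE)
  expect_gt(nrow(ij), 10L)
  z <- (fl[ij] - t(fl)[ij]) / sqrt(fl[ij] + t(fl)[ij])
  expect_lt(max(abs(z)), 6)
  expect_lt(mean(abs(z)), 1.5)
})

test_that("constant weights reduce to an unweighted constrained walk", {
  toy <- smallToy()
  grid <- costGrid(0, 40, 0.5)
  w0 <- new("WeightFunction", grid = grid, logw = rep(0, grid@nBins),
            visited = rep(TRUE, grid@nBins),
            diagnostics = list())
  run <- mucaSample(w0, toy, steps = 2e5, seed = 8L, thin = 20L,
                    trackDeltaPR = FALSE)
  # the visit distribution then estimates the DOS itself: compare to
  # enumeration in well-populated bins
  ex <- exactDOS(toy, grid)
  cnt <- attr(ex, "counts")
  sel <- run$hist > 500 & cnt > 0
  expect_gt(sum(sel), 3L)
  est <- log(run$hist[sel] / sum(run$hist[sel]))
  exact <- log(cnt[sel] / sum(cnt[sel]))
  expect_lt(max(abs((est - mean(est)) - (exact - mean(exact)))), 0.15)
})

test_that("chains are bit-reproducible under a fixed seed", {
  toy <- midToy()
  grid <- costGrid(0, 60, 0.5)
  w1 <- wangLandau(toy, grid, wlSchedule(checkEvery = 1e4, maxSteps = 1e8),
                   seed = 9L)
  w2 <- wangLandau(toy, grid, wlSchedule(checkEvery = 1e4, maxSteps = 1e8),
                   seed = 9L)
  expect_identical(w1@logw, w2@logw)
  expect_identical(w1@diagnostics$steps, w2@diagnostics$steps)
  r1 <- mucaSample(w1, toy, steps = 1e5, seed = 10L, thin = 10L,
                   trackDeltaPR = FALSE)
  r2 <- mucaSample(w2, toy, steps = 1e5, seed = 10L, thin = 10L,
                   trackDeltaPR = FALSE)
  expect_identical(r1$retCost, r2$retCost)
  expect_identical(r1$finalCode, r2$finalCode)
})

test_that("DOS normalisation modes and tail properties hold", {
  toy <- midToy()
  grid <- costGrid(0, 60, 0.5)
  w <- wangLandau(toy, grid, wlSchedule(checkEvery = 1e4, maxSteps = 1e8),
                  seed = 12L)
  run <- mucaSample(w, toy, steps = 1e6, seed = 13L, thin = 50L,
                    trackDeltaPR = FALSE)
  dos <- estimateDOS(run$hist, w, mode = "fraction")
  # fraction mode sums to one over unmasked bins
  expect_equal(sum(exp(dos@logdos[dos@visited])), 1, tolerance = 1e-9)
  # masked bins are NA, not zero
  expect_true(all(is.na(dos@logdos[!dos@visited])))
  # total mass at the upper grid edge
  expect_equal(tailFraction(dos, grid@upper), 1, tolerance = 1e-9)
  # threshold below the grid -> zero
  expect_identical(tailFraction(dos, -1), 0)
  # monotone nondecreasing in the threshold
  thr <- seq(grid@lower, grid@upper, length.out = 40)
  tails <- vapply(thr, function(t) tailFraction(dos, t), numeric(1))
  expect_true(all(diff(tails) >= 0))
  # count mode anchors to the exact ensemble size
  dosC <- estimateDOS(run$hist, w, mode = "count", totalCount = toyCount(toy))
  expect_equal(sum(exp(dosC@logdos[dosC@visited])),
               as.numeric(toyCount(toy)$count), tolerance = 1e-6)
  # relative mode refuses tail normalisation
  dosR <- estimateDOS(run$hist, w, mode = "relative")
  expect_error(tailFraction(dosR, 10), "fraction")
})

test_that("weight and DOS serialisation round-trips through TSV", {
  toy <- smallToy()
  grid <- costGrid(0, 40, 0.5)
  w <- wangLandau(toy, grid, wlSchedule(checkEvery = 1e4, maxSteps = 1e7),
                  seed = 14L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeWeights(w, tmp)
  w2 <- readWeights(tmp)
  expect_equal(w2@logw, w@logw, tolerance = 1e-12)
  expect_equal(w2@grid@width, grid@width)
  expect_identical(w2@diagnostics$stages, w@diagnostics$stages)
  run <- mucaSample(w, toy, steps = 1e5, seed = 15L, thin = 10L,
                    trackDeltaPR = FALSE)
  dos <- estimateDOS(run$hist, w, mode = "fraction")
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeDOS(dos, tmp2)
  dos2 <- readDOS(tmp2)
  expect_equal(dos2@logdos, dos@logdos, tolerance = 1e-12)
  expect_identical(dos2@mode, "fraction")
})
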