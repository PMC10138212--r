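# Shared fixtures: small toy systems, a brute-force cost oracle, and lazily
# computed (memoised) production-scale artifacts shared by the acceptance
# tests so the expensive chains run once per session.

# brute-force cost: exhaustive ordered-pair enumeration over a context
bruteCost <- function(ctx, a0) {
  s <- 0
  for (p in seq_len(ctx$nPos)) {
    for (k in seq_len(nrow(ctx$nbr))) {
      j <- ctx$nbr[k, p]
      if (j < 0) break
      s <- s + ctx$nbw[k, p] * ctx$d[a0[p] + 1L, a0[j + 1L] + 1L]
    }
  }
  s / ctx$Wtot
}

# brute-force enumeration of a toy ensemble: returns costs of all valid states
bruteEnumerate <- function(toy) {
  ctx <- toy@ctx
  grids <- rep(list(seq_len(ctx$nAA)), ctx$nPos)
  states <- as.matrix(expand.grid(grids))
  valid <- apply(states, 1, function(a) {
    cnt <- tabulate(a, ctx$nAA)
    all(cnt >= ctx$minCount)
  })
  states <- states[valid, , drop = FALSE]
  costs <- apply(states, 1, function(a) bruteCost(ctx, a - 1L))
  list(states = states, costs = costs)
}

smallToy <- function(seed = 1L) makeToy(2L, 2L, 3L, seed = seed)   # 81 states
midToy <- function(seed = 7L) makeToy(2L, 3L, 4L, seed = seed)     # 65536

# ---- memoised production-scale artifacts -----------------------------------

.acc <- new.env(parent = emptyenv())

accGet <- function(name, fn) {
  if (is.null(.acc[[name]])) .acc[[name]] <- fn()
  .acc[[name]]
}

accWeight <- function() accGet("weight", function()
  wangLandau(ensembleConstraints(), costGrid(),
             wlSchedule(checkEvery = 1e6, maxSteps = 6e8), seed = 101L))

accMuca <- function() accGet("muca", function()
  mucaSample(accWeight(), ensembleConstraints(), steps = 6e8, seed = 102L,
             thin = 150L, keepBelow = 2.7))

accDOS <- function() accGet("dos", function()
  estimateDOS(accMuca()$hist, accWeight(), mode = "fraction"))

accLandscape <- function() accGet("landscape", function() {
  m <- accMuca()
  vec <- vectorizeCodes(m$sample)
  costs <- m$sample@costs
  proj <- fitLandscape(vec, costs, cutoff = 2.7)
  pts <- projectCodes(proj, vec)[, 1:3]
  elbow <- elbowK(pts, kMax = 8L, seed = 105L, nstart = 50L)
  sense <- setdiff(1:64, sgcStopPositions())
  sideR <- substr(codonTriple(sense), 2, 2) %in% c("A", "G")
  dpr <- rowMeans(vec[, sense[sideR]]) - rowMeans(vec[, sense[!sideR]])
  clusters <- clusterCodes(pts, 4L, costs = costs, dpr = dpr,
                           projection = proj, seed = 106L, nstart = 50L)
  list(vec = vec, costs = costs, proj = proj, pts = pts, elbow = elbow,
       clusters = clusters,
       occupancy = clusterOccupancy(clusters, costs, c(2.5, 2.7)))
})

accGA <- function() accGet("ga", function() gaRun(1000L, seed = 103L))
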