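# Enumerable toy codon systems and planted-structure point clouds: exact
# oracles for the cost, sampling and clustering machinery.

#' Construct an enumerable toy codon system
#'
#' A reduced codon system: \code{nBases} bases, codons of length
#' \code{codonLen} (so \code{nBases^codonLen} codons, all sense by default),
#' and \code{nAA} toy amino acids with a seeded property scale in which the
#' two designated last symbols carry the two largest values (the Asp/Glu
#' analogue). Misreading weights reuse the position/class structure of the
#' full model: any change in the last base has weight 1, earlier positions
#' are down-weighted, and with a 4-letter base alphabet the
#' transition/transversion distinction applies exactly as in the full
#' model - so toy validation exercises the same code paths.
#'
#' @param nBases base-alphabet size (2 or 4).
#' @param codonLen codon length.
#' @param nAA toy amino-acid count.
#' @param seed integer seed for the property scale.
#' @param minTop multiplicity floor for each of the two top-value symbols
#'   (the Asp/Glu analogue constraint); 0 disables.
#' @param requireAll require every symbol at least once.
#' @param excludePositions codon indices excluded from assignment (the toy
#'   analogue of pinned stop positions); they simply drop out of the system.
#' @param cap refuse systems with more than this many unconstrained states.
#' @return a \linkS4class{ToySystem}.
#' @export
makeToy <- function(nBases = 2L, codonLen = 2L, nAA = 3L, seed = 1L,
                    minTop = 1L, requireAll = TRUE,
                    excludePositions = integer(0), cap = 2e7) {
  nBases <- as.integer(nBases); codonLen <- as.integer(codonLen)
  nAA <- as.integer(nAA)
  if (!nBases %in% c(2L, 4L)) stop("nBases must be 2 or 4")
  nCodons <- nBases^codonLen
  keep <- setdiff(seq_len(nCodons), excludePositions)
  nPos <- length(keep)
  if (nAA^nPos > cap) stop("toy state space exceeds the enumeration cap")
  set.seed(seed)
  # seeded property scale; the last two symbols get the two largest values
  vals <- sort(stats::runif(nAA, 1, 10))
  scale <- if (nAA >= 3L) {
    low <- vals[seq_len(nAA - 2L)]
    c(low[sample.int(nAA - 2L)], vals[nAA - 1L], vals[nAA])
  } else vals
  # codon digits: col p = base at position p, first base slowest
  idx <- 0:(nCodons - 1L)
  digits <- vapply(seq_len(codonLen),
                   function(p) (idx %/% nBases^(codonLen - p)) %% nBases,
                   numeric(nCodons))
  digits <- matrix(as.integer(digits), ncol = codonLen)
  purine <- if (nBases == 4L) c(FALSE, FALSE, TRUE, TRUE) else NULL
  posWeight <- function(p, b, b2) {
    ts <- if (nBases == 4L) purine[b + 1L] == purine[b2 + 1L] else TRUE
    if (p == codonLen) 1
    else if (p == codonLen - 2L) ifelse(ts, 1, 0.5)   # "1st base" analogue
    else ifelse(ts, 0.5, 0.1)                         # "2nd base" analogue
  }
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    for (p in seq_len(codonLen)) {
      for (b2 in setdiff(0:(nBases - 1L), digits[i, p])) {
        d2 <- digits[i, ]; d2[p] <- b2
        j <- sum(d2 * nBases^(codonLen - seq_len(codonLen))) + 1L
        jj <- match(j, keep)
        if (is.na(jj)) next
        from <- c(from, ii); to <- c(to, jj)
        w <- c(w, posWeight(p, digits[i, p], b2))
      }
    }
  }
  K <- max(tabulate(from, nPos))
  nbr <- matrix(-1L, K, nPos); nbw <- matrix(0, K, nPos)
  for (e in seq_along(from)) {
    k <- which(nbr[, from[e]] == -1L)[1]
    nbr[k, from[e]] <- to[e] - 1L
    nbw[k, from[e]] <- w[e]
  }
  minCount <- if (requireAll) rep(1L, nAA) else rep(0L, nAA)
  if (minTop > 0L && nAA >= 2L) {
    minCount[nAA - 1L] <- max(minCount[nAA - 1L], as.integer(minTop))
    minCount[nAA] <- max(minCount[nAA], as.integer(minTop))
  }
  d <- outer(scale, scale, function(x, y) (x - y)^2)
  ctx <- list(nPos = nPos, nAA = nAA, d = d, nbr = nbr, nbw = nbw,
              Wtot = sum(w), minCount = minCount)
  new("ToySystem", nBases = nBases, codonLen = codonLen,
      nCodons = as.integer(nPos), nAA = nAA, scale = scale, ctx = ctx,
      seed = as.integer(seed))
}

#' Exact density of states of a toy system
#'
#' Exhaustive enumeration of every constraint-satisfying assignment, binned
#' by exact cost - the ground truth the multicanonical estimates are checked
#' against.
#'
#' @param toy a \linkS4class{ToySystem}.
#' @param grid a \linkS4class{CostGrid}.
#' @param cap enumeration cap on the unconstrained state count.
#' @return a \linkS4class{DOSEstimate} in count mode; attributes
#'   \code{total}, \code{minCost} and \code{maxCost} carry the exact
#'   summaries.
#' @export
exactDOS <- function(toy, grid, cap = 2e7) {
  res <- .cpp_enum_dos(toy@ctx, grid@lower, grid@width, grid@nBins, cap)
  counts <- res$counts
  logdos <- rep(NA_real_, length(counts))
  logdos[counts > 0] <- log(counts[counts > 0])
  out <- new("DOSEstimate", grid = grid, logdos = logdos, mode = "count",
             visited = counts > 0)
  attr(out, "counts") <- counts
  attr(out, "total") <- res$total
  attr(out, "minCost") <- res$minCost
  attr(out, "maxCost") <- res$maxCost
  out
}

#' Toy-system helpers
#'
#' \code{toyCost} evaluates the toy misreading cost of an assignment;
#' \code{toyCount} counts the constrained toy ensemble exactly (shared
#' inclusion-exclusion machinery with the full problem).
#'
#' @param toy a \linkS4class{ToySystem}.
#' @param assignment integer vector (1-based symbol per codon).
#' @return numeric cost / exact-count list.
#' @export
toyCost <- function(toy, assignment)
  .cpp_cost(as.integer(assignment) - 1L, toy@ctx)

#' @rdname toyCost
#' @export
toyCount <- function(toy)
  countEnsemble(nFree = toy@ctx$nPos, minCount = toy@ctx$minCount)

#' Planted isotropic Gaussian blobs
#'
#' k isotropic clusters with unit within-cluster standard deviation placed
#' so that the pairwise centre distance is \code{separation} (times the
#' within-cluster spread), with ground-truth labels for recovery scoring.
#'
#' @param k cluster count.
#' @param separation centre separation in within-cluster standard
#'   deviations.
#' @param nPer points per blob.
#' @param dim dimensionality.
#' @param seed integer seed.
#' @return list with \code{points} and \code{labels}.
#' @export
plantedBlobs <- function(k, separation = 10, nPer = 100L, dim = 2L,
                         seed = 1L) {
  set.seed(seed)
  # place centres on a simplex-like frame scaled to the target separation
  centers <- matrix(0, k, dim)
  if (k > 1L) {
    raw <- matrix(stats::rnorm(k * dim), k, dim)
    raw <- scale(raw, scale = FALSE)
    dd <- as.matrix(stats::dist(raw))
    scl <- separation / min(dd[upper.tri(dd)])
    centers <- raw * scl
  }
  labels <- rep(seq_len(k), each = nPer)
  pts <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(k * nPer * dim), k * nPer, dim)
  list(points = pts, labels = labels)
}
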