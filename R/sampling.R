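# Reference samplers: naive uniform sampling from the constrained ensemble,
# the block-structure ensemble of the earlier literature, and the single-flip
# proposal shared by the Monte Carlo chains.

#' Naive uniform sampling from the constrained ensemble
#'
#' Draws codes uniformly over the constrained random-code ensemble by
#' assigning each sense codon a uniform amino acid and rejecting
#' constraint violators, which preserves exact uniformity on the constrained
#' set. The empirical acceptance rate estimates
#' \code{countEnsemble(...)/20^61}.
#'
#' @param n number of codes.
#' @param constraints an \linkS4class{EnsembleConstraints}.
#' @param seed integer seed.
#' @param config a \linkS4class{CostConfig}.
#' @param keepCodes retain the sampled codes (set \code{FALSE} for very large
#'   \code{n} to keep only costs).
#' @return a \linkS4class{CodeSample}; the attribute \code{"tries"} holds the
#'   total number of rejection-sampling attempts.
#' @export
naiveSample <- function(n, constraints = ensembleConstraints(), seed = 1L,
                        config = costConfig(), keepCodes = TRUE) {
  set.seed(seed)
  ctx <- .fullContext(constraints, config)
  res <- .cpp_naive(ctx, as.numeric(n), keepCodes)
  out <- new("CodeSample", codes = res$codes, costs = res$costs,
             seed = as.integer(seed), ensemble = "uniform")
  attr(out, "tries") <- res$tries
  out
}

#' Block-structure ensemble sampling
#'
#' Random codes that keep the standard code's block partition of sense
#' codons: each draw is a uniformly random permutation of the 20 amino acids
#' over the 20 standard blocks (stops untouched) - the random ensemble of the
#' earlier error-minimisation studies, with exactly 20! distinct codes.
#'
#' @param n number of permutations.
#' @param seed integer seed.
#' @param config a \linkS4class{CostConfig}.
#' @param keepCodes retain the permuted codes (costs are always returned).
#' @return a \linkS4class{CodeSample}.
#' @export
blockSample <- function(n, seed = 1L, config = costConfig(),
                        keepCodes = FALSE) {
  set.seed(seed)
  sense <- setdiff(1:64, sgcStopPositions())
  blk <- match(sgcCode()@assignments[sense], AA_ORDER)
  ctx <- .fullContext(config = config)
  # total ordered-pair weight between block i and block j
  B <- matrix(0, 20, 20)
  for (p in seq_len(61)) {
    nb <- ctx$nbr[, p]; w <- ctx$nbw[, p]
    for (k in seq_along(nb)) {
      if (nb[k] < 0) break
      B[blk[p], blk[nb[k] + 1L]] <- B[blk[p], blk[nb[k] + 1L]] + w[k]
    }
  }
  if (is(config@penalty, "PropertyPenalty") && !keepCodes) {
    prop <- config@penalty@scale@values[AA_ORDER]
    costs <- .cpp_block_costs(as.numeric(n), B, unname(prop), ctx$Wtot)
    return(new("CodeSample", codes = matrix(integer(0), 0, 0), costs = costs,
               seed = as.integer(seed), ensemble = "block"))
  }
  # generic penalty, or codes requested: permute in R (slower path)
  costs <- numeric(n)
  codes <- if (keepCodes) matrix(NA_integer_, 61, n) else
    matrix(integer(0), 0, 0)
  for (i in seq_len(n)) {
    perm <- sample.int(20)
    a <- perm[blk]
    costs[i] <- .cpp_cost(a - 1L, ctx)
    if (keepCodes) codes[, i] <- a - 1L
  }
  new("CodeSample", codes = codes, costs = costs,
      seed = as.integer(seed), ensemble = "block")
}

#' Single-flip proposal
#'
#' Reassigns one uniformly chosen sense codon to a uniformly chosen
#' different amino acid. Stop positions never change. The candidate may
#' violate the ensemble constraints; the caller decides the rejection
#' policy.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @return the candidate \linkS4class{GeneticCode}.
#' @export
proposeFlip <- function(code) {
  sense <- setdiff(1:64, sgcStopPositions())
  pos <- sense[sample.int(61, 1)]
  cur <- code@assignments[pos]
  newSym <- sample(setdiff(AA_ORDER, cur), 1)
  a <- code@assignments
  a[pos] <- newSym
  geneticCode(a)
}

#' Fraction of sampled costs below a threshold
#'
#' @param x a \linkS4class{CodeSample} or numeric cost vector.
#' @param threshold cost threshold.
#' @param strict count strictly-below when \code{TRUE} (default); the
#'   block-ensemble comparison against "equally or more robust" uses
#'   \code{strict = FALSE}.
#' @return list with \code{fraction}, \code{hits}, \code{n} and the exact
#'   binomial 95 percent interval \code{lower}/\code{upper}.
#' @export
fractionBelow <- function(x, threshold, strict = TRUE) {
  costs <- if (is(x, "CodeSample")) x@costs else x
  if (!length(costs)) stop("empty sample")
  hits <- if (strict) sum(costs < threshold) else sum(costs <= threshold)
  ci <- stats::binom.test(hits, length(costs))$conf.int
  list(fraction = hits / length(costs), hits = hits, n = length(costs),
       lower = ci[1], upper = ci[2])
}

#' Codes of a sample batch
#'
#' @param x a \linkS4class{CodeSample}.
#' @param i column index.
#' @return \code{sampleCode}: the i-th code as a \linkS4class{GeneticCode};
#'   \code{sampleCosts}: the cost vector.
#' @export
sampleCode <- function(x, i) {
  if (!ncol(x@codes)) stop("codes were not retained in this batch")
  .intToCode(x@codes[, i])
}

#' @rdname sampleCode
#' @export
sampleCosts <- function(x) x@costs
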