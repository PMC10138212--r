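# Truncation-selection genetic algorithm on the code landscape and its
# trajectory analytics: right-left polar-requirement asymmetry, sign
# transition rates versus cost, latest-value curves, conditional fractions.

#' GA configuration
#'
#' Defaults follow the reference simulation: population 100, top 50 percent
#' selected by cost, per-element mutation rate 0.1, 500 generations, no
#' crossover. Survivors persist unmutated and each is copied exactly once
#' (drawing without replacement), mutation applying to the copies; set
#' \code{mutateSurvivors = TRUE} for the alternative reading in which the
#' whole refilled population is mutated.
#'
#' @param N population size.
#' @param selectFrac fraction selected each generation.
#' @param mu per-element mutation probability.
#' @param generations generation count.
#' @param retryCap redraw limit for constraint-violating mutants (a mutant
#'   missing an amino acid or an Asp/Glu floor restarts its mutation).
#' @param mutateSurvivors see above.
#' @return list of settings.
#' @export
gaConfig <- function(N = 100L, selectFrac = 0.5, mu = 0.1,
                     generations = 500L, retryCap = 10000L,
                     mutateSurvivors = FALSE)
  list(N = as.integer(N), selectFrac = selectFrac, mu = mu,
       generations = as.integer(generations), retryCap = as.integer(retryCap),
       mutateSurvivors = mutateSurvivors)

#' Run a batch of independent GA optimisations
#'
#' Each run starts from a fresh uniform random population of
#' constraint-satisfying codes and evolves under truncation selection on the
#' misreading cost. Per generation the best cost and the best code's
#' right-left polar-requirement difference are recorded; the first
#' best-of-generation code whose cost lands inside \code{slice} is retained
#' for landscape placement.
#'
#' @param runs number of independent runs.
#' @param config a \code{\link{gaConfig}} list.
#' @param constraints an \linkS4class{EnsembleConstraints}.
#' @param costConf a \linkS4class{CostConfig}.
#' @param seed integer seed.
#' @param slice cost window (default the 2.6 +/- 0.1 slice around the
#'   standard code).
#' @param recordPopulations retain every generation's full population
#'   (small runs only; used by the step-through tests).
#' @return a \linkS4class{GABatch}.
#' @export
gaRun <- function(runs, config = gaConfig(),
                  constraints = ensembleConstraints(),
                  costConf = costConfig(), seed = 1L,
                  slice = c(2.5, 2.7), recordPopulations = FALSE) {
  set.seed(seed)
  ctx <- .fullContext(constraints, costConf)
  nSel <- as.integer(round(config$N * config$selectFrac))
  res <- .cpp_ga(ctx, config$N, nSel, config$mu, config$generations,
                 as.integer(runs), slice[1], slice[2], config$retryCap,
                 unname(polarRequirement()@values[AA_ORDER]),
                 .senseSideMask(), config$mutateSurvivors,
                 recordPopulations)
  out <- new("GABatch", bestCost = res$bestCost, bestDpr = res$bestDpr,
             sliceCodes = res$sliceCodes, sliceCost = res$sliceCost,
             sliceGen = res$sliceGen, reached = res$reached,
             config = config, seed = as.integer(seed))
  if (recordPopulations) attr(out, "populations") <- res$populations
  out
}

#' Right-left polar-requirement asymmetry of a code
#'
#' Mean property value over sense codons in the right half of the codon
#' table (2nd base A or G) minus the mean over the left half (2nd base U or
#' C), stops excluded. Negative values mark codes with the high
#' polar-requirement amino acids concentrated in the two left columns (the
#' rare "blue" landscape peak).
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param scale a \linkS4class{PropertyScale}.
#' @return numeric difference in property units.
#' @export
deltaPR <- function(code, scale = polarRequirement()) {
  sense <- setdiff(1:64, sgcStopPositions())
  v <- scale@values[code@assignments[sense]]
  side <- .senseSideMask() == 1L
  mean(v[side]) - mean(v[!side])
}

#' Trajectory statistics of a GA batch
#'
#' Aggregates the per-generation (cost, asymmetry) traces of a batch into
#' the path-dependence diagnostics: per-cost-bin sign-transition rates of
#' the asymmetry, the per-run latest-value curve (only the most recent
#' asymmetry at each revisited cost bin is kept, making each curve a
#' univalent function of cost), and the fraction of codes with negative
#' asymmetry per bin - overall and conditioned on runs that reach the
#' target cost slice.
#'
#' @param batch a \linkS4class{GABatch}.
#' @param binWidth cost bin width for the curves.
#' @param sliceLo,sliceHi the conditioning slice (defaults to the batch's).
#' @return list with \code{bins} (bin centres), \code{transitions} (data
#'   frame: rate of positive-to-negative, negative-to-positive and either,
#'   per bin, as transitions per generation-step in the bin), \code{latest}
#'   (runs x bins matrix of latest asymmetry values, NA where a run never
#'   visited a bin), \code{negFraction} and \code{negFractionReached}
#'   (per-bin fraction of negative-asymmetry codes), and \code{visits}.
#' @export
trajectoryStats <- function(batch, binWidth = 0.1, sliceLo = NULL,
                            sliceHi = NULL) {
  bc <- batch@bestCost; bd <- batch@bestDpr
  gens <- nrow(bc); runs <- ncol(bc)
  lo <- floor(min(bc) / binWidth) * binWidth
  hi <- ceiling(max(bc) / binWidth) * binWidth
  nb <- max(1L, as.integer(round((hi - lo) / binWidth)))
  binOf <- function(x) pmin(pmax(floor((x - lo) / binWidth), 0), nb - 1L) + 1L
  bins <- lo + (seq_len(nb) - 0.5) * binWidth

  visits <- numeric(nb)
  p2n <- numeric(nb); n2p <- numeric(nb)
  negAll <- numeric(nb)
  negReached <- numeric(nb); visitsReached <- numeric(nb)
  latest <- matrix(NA_real_, runs, nb)
  reached <- batch@reached

  for (r in seq_len(runs)) {
    b <- binOf(bc[, r])
    s <- sign(bd[, r])
    tb <- tabulate(b, nb)
    visits <- visits + tb
    if (reached[r]) visitsReached <- visitsReached + tb
    neg <- tabulate(b[s < 0], nb)
    negAll <- negAll + neg
    if (reached[r]) negReached <- negReached + neg
    if (gens > 1L) {
      ch <- which(s[-1] != s[-gens] & s[-1] != 0 & s[-gens] != 0)
      if (length(ch)) {
        tbin <- b[ch + 1L]
        up <- s[ch] > 0  # positive -> negative
        p2n <- p2n + tabulate(tbin[up], nb)
        n2p <- n2p + tabulate(tbin[!up], nb)
      }
    }
    # latest value per revisited bin: later generations overwrite earlier
    latest[r, b] <- bd[, r]
  }
  transitions <- data.frame(
    bin = bins,
    posToNeg = ifelse(visits > 0, p2n / visits, NA_real_),
    negToPos = ifelse(visits > 0, n2p / visits, NA_real_),
    either = ifelse(visits > 0, (p2n + n2p) / visits, NA_real_))
  list(bins = bins,
       transitions = transitions,
       latest = latest,
       negFraction = ifelse(visits > 0, negAll / visits, NA_real_),
       negFractionReached = ifelse(visitsReached > 0,
                                   negReached / visitsReached, NA_real_),
       visits = visits, visitsReached = visitsReached)
}

#' Per-bin negative-asymmetry fraction of a multicanonical run
#'
#' The unbiased reference curve for the GA comparison: among retained
#' multicanonical states in each cost bin (which are ensemble-weighted
#' within a bin), the fraction with negative right-left polar-requirement
#' difference.
#'
#' @param retCost,retDpr retained costs and asymmetries from
#'   \code{\link{mucaSample}}.
#' @param binWidth cost bin width.
#' @return data frame with bin centres, fractions and counts.
#' @export
mucaNegFraction <- function(retCost, retDpr, binWidth = 0.1) {
  lo <- floor(min(retCost) / binWidth) * binWidth
  b <- floor((retCost - lo) / binWidth)
  nb <- max(b) + 1L
  tot <- tabulate(b + 1L, nb)
  neg <- tabulate(b[retDpr < 0] + 1L, nb)
  data.frame(bin = lo + (seq_len(nb) - 0.5) * binWidth,
             fraction = ifelse(tot > 0, neg / tot, NA_real_),
             n = tot)
}
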