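# Wang-Landau construction of the multicanonical weight over cost,
# fixed-weight multicanonical sampling, and density-of-states estimation.

#' Binned cost axis
#'
#' Equal-width half-open bins over \code{[lower, upper)}; out-of-range costs
#' clamp to the edge bins, so the edge bins also absorb whatever mass lies
#' beyond the grid. The default 0.01 width resolves the 2.6 +/- 0.1 slice
#' around the standard code's cost.
#'
#' @param lower,upper grid range in cost units.
#' @param width bin width.
#' @return a \linkS4class{CostGrid}.
#' @export
costGrid <- function(lower = 2, upper = 21, width = 0.01) {
  nBins <- as.integer(round((upper - lower) / width))
  new("CostGrid", lower = lower, upper = lower + nBins * width,
      width = width, nBins = nBins)
}

#' @rdname costGrid
#' @param grid a \linkS4class{CostGrid}.
#' @return \code{binMidpoints}: bin centres; \code{binIndex}: the bin of each
#'   cost (clamped to the edges).
#' @export
binMidpoints <- function(grid)
  grid@lower + (seq_len(grid@nBins) - 0.5) * grid@width

#' @rdname costGrid
#' @param cost numeric costs.
#' @export
binIndex <- function(grid, cost)
  as.integer(pmin(pmax(floor((cost - grid@lower) / grid@width), 0),
                  grid@nBins - 1L)) + 1L

#' Wang-Landau schedule
#'
#' Training parameters: initial log modification factor, halved (in log
#' space) each time the visited-bin histogram is flat (every visited bin at
#' least \code{flatness} of the mean count), until the factor drops below
#' \code{minLogf}. These are standard Wang-Landau practice; the source
#' analysis leaves them unstated.
#'
#' @param logf0 initial log modification factor.
#' @param flatness flat-histogram threshold in (0, 1).
#' @param minLogf stop once the log factor falls below this.
#' @param checkEvery steps between flatness checks.
#' @param maxSteps hard cap on total training steps.
#' @return list of schedule parameters.
#' @export
wlSchedule <- function(logf0 = 1.0, flatness = 0.8, minLogf = 1e-6,
                       checkEvery = 1e5, maxSteps = 5e8)
  list(logf0 = logf0, flatness = flatness, minLogf = minLogf,
       checkEvery = checkEvery, maxSteps = maxSteps)

# dispatch: a cost context from either the full ensemble or a toy system
.asContext <- function(system, config = costConfig()) {
  if (is(system, "ToySystem")) system@ctx
  else if (is(system, "EnsembleConstraints")) .fullContext(system, config)
  else if (is.list(system) && !is.null(system$nPos)) system
  else stop("system must be EnsembleConstraints or ToySystem")
}

#' Wang-Landau training of the multicanonical weight
#'
#' Builds per-bin log weights w(cost) proportional to 1/Omega(cost) by the
#' flat-histogram Wang-Landau iteration: the running log density-of-states
#' estimate of the current bin is raised by the modification factor at every
#' step, and the factor is halved whenever the visit histogram is flat.
#' Candidate codes violating the ensemble constraints are rejected in place
#' (the chain stays put and the current bin is re-counted), so the chain
#' samples the constrained ensemble throughout.
#'
#' @param system an \linkS4class{EnsembleConstraints} (full 61-codon
#'   problem) or a \linkS4class{ToySystem}.
#' @param grid a \linkS4class{CostGrid}.
#' @param schedule a \code{\link{wlSchedule}} list.
#' @param seed integer seed.
#' @param config a \linkS4class{CostConfig} (full problem only).
#' @return a \linkS4class{WeightFunction}. Training that exhausts
#'   \code{maxSteps} before the factor reaches \code{minLogf} throws, with
#'   the flatness diagnostics in the error message.
#' @export
wangLandau <- function(system, grid = costGrid(), schedule = wlSchedule(),
                       seed = 1L, config = costConfig()) {
  set.seed(seed)
  ctx <- .asContext(system, config)
  init <- .cpp_random_code(ctx)
  res <- .cpp_wang_landau(ctx, grid@lower, grid@width, grid@nBins,
                          schedule$logf0, schedule$flatness, schedule$minLogf,
                          schedule$checkEvery, schedule$maxSteps, init)
  if (!res$converged)
    stop(sprintf(paste0("Wang-Landau did not converge: log-f %.2e after %.3g",
                        " steps (%d flatness passes)"),
                 res$finalLogf, res$steps, res$stages))
  logg <- res$logg
  visited <- res$visited
  logw <- -logg  # w proportional to 1/Omega
  # carry the nearest visited value into unreachable edge bins so the weight
  # is finite everywhere on the grid
  if (any(!visited)) {
    idx <- which(visited)
    for (b in which(!visited)) {
      logw[b] <- logw[idx[which.min(abs(idx - b))]]
    }
  }
  new("WeightFunction", grid = grid, logw = logw - max(logw),
      visited = visited,
      diagnostics = list(stages = res$stages, steps = res$steps,
                         finalLogf = res$finalLogf, seed = seed,
                         finalCode = res$finalCode))
}

#' Fixed-weight multicanonical sampling
#'
#' Markov chain over the constrained ensemble with single-flip proposals and
#' the acceptance rule min(1, w(cost')/w(cost)). Rejected steps re-record
#' the current state, so the returned histogram obeys detailed balance with
#' respect to the weight. With a trained weight the chain performs a random
#' walk along the cost axis, reaching costs below the standard code's that
#' naive sampling cannot.
#'
#' @param weight a \linkS4class{WeightFunction}.
#' @param system as in \code{\link{wangLandau}}.
#' @param steps chain length.
#' @param seed integer seed.
#' @param thin retain every \code{thin}-th state.
#' @param keepBelow retain full codes only for costs below this (bounds
#'   memory; \code{Inf} keeps every thinned code).
#' @param trackDeltaPR also record the right-left polar-requirement
#'   difference of every retained state (full problem only).
#' @param trackFlow accumulate per-step bin-to-bin transition counts
#'   (small grids only; used by the detailed-balance checks).
#' @param config a \linkS4class{CostConfig}.
#' @param init optional integer start code (defaults to the Wang-Landau
#'   final code when present, else a fresh random valid code).
#' @return list with \code{hist} (per-bin visit counts), \code{sample} (a
#'   \linkS4class{CodeSample} of the retained codes below \code{keepBelow}),
#'   \code{retCost}, \code{retDpr}, optionally \code{flow}, and
#'   \code{finalCode}.
#' @export
mucaSample <- function(weight, system, steps, seed = 1L, thin = 50L,
                       keepBelow = Inf, trackDeltaPR = TRUE,
                       trackFlow = FALSE, config = costConfig(),
                       init = NULL) {
  set.seed(seed)
  ctx <- .asContext(system, config)
  if (is.null(init)) {
    init <- weight@diagnostics$finalCode
    if (is.null(init)) init <- .cpp_random_code(ctx)
  }
  grid <- weight@grid
  isFull <- !is(system, "ToySystem")
  propVal <- if (trackDeltaPR && isFull)
    unname(polarRequirement()@values[AA_ORDER]) else numeric(0)
  side <- if (trackDeltaPR && isFull) .senseSideMask() else integer(ctx$nPos)
  res <- .cpp_muca(ctx, grid@lower, grid@width, grid@nBins, weight@logw,
                   as.numeric(steps), as.integer(thin), keepBelow, init,
                   propVal, side, trackFlow)
  sample <- new("CodeSample", codes = res$retCodes,
                costs = res$retCost[res$retCost < keepBelow],
                seed = as.integer(seed), ensemble = "multicanonical")
  out <- list(hist = res$hist, sample = sample, retCost = res$retCost,
              retDpr = res$retDpr, finalCode = res$finalCode,
              finalCost = res$finalCost)
  if (trackFlow) out$flow <- res$flow
  out
}

#' Density of states from a multicanonical histogram
#'
#' Per-bin log density of states log Omega = log H - log w + const, where H
#' is the visit histogram of a fixed-weight run. Modes: \code{"relative"}
#' (constant arbitrary), \code{"fraction"} (normalised so the exponentials
#' over unmasked bins sum to 1 - the fraction of the ensemble per bin), and
#' \code{"count"} (fraction multiplied by the exact ensemble size
#' \code{totalCount}). Empty histogram bins are masked (NA), never zero.
#'
#' @param hist per-bin visit counts (or the list from
#'   \code{\link{mucaSample}}).
#' @param weight the \linkS4class{WeightFunction} the run used.
#' @param mode normalisation mode.
#' @param totalCount exact ensemble size (required for \code{"count"};
#'   accepts the list from \code{\link{countEnsemble}}, whose \code{log10}
#'   is used).
#' @return a \linkS4class{DOSEstimate}.
#' @export
estimateDOS <- function(hist, weight, mode = c("fraction", "relative",
                                               "count"),
                        totalCount = NULL) {
  mode <- match.arg(mode)
  if (is.list(hist)) hist <- hist$hist
  if (length(hist) != weight@grid@nBins) stop("histogram/grid mismatch")
  visited <- hist > 0
  logdos <- rep(NA_real_, length(hist))
  logdos[visited] <- log(hist[visited]) - weight@logw[visited]
  if (mode != "relative") {
    m <- max(logdos[visited])
    logZ <- m + log(sum(exp(logdos[visited] - m)))
    logdos <- logdos - logZ
    if (mode == "count") {
      if (is.null(totalCount)) stop("mode 'count' needs totalCount")
      l10 <- if (is.list(totalCount)) totalCount$log10 else log10(totalCount)
      logdos <- logdos + l10 * log(10)
    }
  }
  new("DOSEstimate", grid = weight@grid, logdos = logdos, mode = mode,
      visited = visited)
}

#' Cumulative tail of the density of states
#'
#' Sum of the exponentiated per-bin density over bins strictly below a cost
#' threshold (bins are attributed by their upper edge, so only bins entirely
#' below the threshold count). For a fraction-mode estimate this is the
#' fraction of the ensemble with cost below the threshold; the headline
#' result is that this is of order 1e-20 at the standard code's cost.
#'
#' @param dos a \linkS4class{DOSEstimate} in fraction (or count) mode.
#' @param threshold cost threshold.
#' @return numeric tail mass (0 when the threshold lies below the grid).
#' @export
tailFraction <- function(dos, threshold) {
  if (dos@mode == "relative")
    stop("tailFraction needs a fraction- or count-normalised estimate")
  g <- dos@grid
  upperEdges <- g@lower + seq_len(g@nBins) * g@width
  sel <- dos@visited & !is.na(dos@logdos) & upperEdges <= threshold
  if (!any(sel)) return(0)
  m <- max(dos@logdos[sel])
  exp(m) * sum(exp(dos@logdos[sel] - m))
}

#' @rdname tailFraction
#' @return \code{tailLog10}: the base-10 logarithm of the tail mass.
#' @export
tailLog10 <- function(dos, threshold) {
  g <- dos@grid
  upperEdges <- g@lower + seq_len(g@nBins) * g@width
  sel <- dos@visited & !is.na(dos@logdos) & upperEdges <= threshold
  if (!any(sel)) return(-Inf)
  m <- max(dos@logdos[sel])
  (m + log(sum(exp(dos@logdos[sel] - m)))) / log(10)
}

#' Histogram flatness statistic
#'
#' min/mean visit count over nonempty bins, the quantity the Wang-Landau
#' flatness criterion thresholds.
#'
#' @param hist per-bin counts.
#' @return numeric in [0, 1].
#' @export
flatness <- function(hist) {
  h <- hist[hist > 0]
  if (!length(h)) return(NA_real_)
  min(h) / mean(h)
}
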