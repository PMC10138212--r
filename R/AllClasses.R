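#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib codonscape, .registration = TRUE
NULL

#' Amino-acid property scale
#'
#' A named assignment of one real value to each of the 20 standard amino
#' acids, such as Woese's polar-requirement (chromatographic hydrophilicity)
#' scale. The squared difference of scale values is the default misreading
#' penalty.
#'
#' @slot values named numeric vector, one finite value per one-letter
#'   amino-acid code; exactly the 20 standard amino acids.
#' @slot name scale label.
#' @export
setClass("PropertyScale",
         representation(values = "numeric", name = "character"))

setValidity("PropertyScale", function(object) {
  v <- object@values
  if (length(v) != 20L || is.null(names(v)))
    return("values must be a named numeric of length 20")
  if (!setequal(names(v), AA_ORDER))
    return("values must be named by the 20 standard one-letter codes")
  if (!all(is.finite(v))) return("all scale values must be finite")
  TRUE
})

#' A genetic code
#'
#' A 64-entry mapping from codons (in UUU..GGG enumeration order, first base
#' slowest) to one-letter amino-acid codes or the stop symbol \code{"*"}.
#'
#' @slot assignments character vector of length 64.
#' @export
setClass("GeneticCode", representation(assignments = "character"))

setValidity("GeneticCode", function(object) {
  a <- object@assignments
  if (length(a) != 64L) return("a genetic code has exactly 64 entries")
  bad <- setdiff(unique(a), c(AA_ORDER, STOP_SYMBOL))
  if (length(bad))
    return(paste0("unknown symbol(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' Random-code ensemble constraints
#'
#' The admissibility conditions on random genetic codes: stop codons pinned
#' to their standard positions (and number), all 20 amino acids present, and
#' minimum multiplicities for Asp and Glu (2 each by default, matching the
#' standard code; 1 each for the relaxed ensemble).
#'
#' @slot stopPositionsFixed logical; stop codons at the standard positions.
#' @slot requireAll20 logical; every amino acid must appear at least once.
#' @slot minAsp,minGlu integer minimum multiplicities.
#' @export
setClass("EnsembleConstraints",
         representation(stopPositionsFixed = "logical",
                        requireAll20 = "logical",
                        minAsp = "integer", minGlu = "integer"))

setValidity("EnsembleConstraints", function(object) {
  if (!object@stopPositionsFixed)
    return("variable stop placement is not supported; stops are pinned")
  if (object@minAsp < 0L || object@minGlu < 0L)
    return("minimum multiplicities must be nonnegative")
  TRUE
})

#' Single-base misreading model
#'
#' Sparse ordered-pair misreading weights over the 64-codon table. Each codon
#' has exactly nine single-base neighbours with nonzero raw weight; the
#' weight depends only on the changed base position and on whether the change
#' is a transition or a transversion.
#'
#' @slot from,to integer codon indices (1-based) of the weighted pairs.
#' @slot weight raw weights, parallel to \code{from}/\code{to}.
#' @slot normalization total raw weight over ordered sense-sense pairs.
#' @export
setClass("MisreadingModel",
         representation(from = "integer", to = "integer",
                        weight = "numeric", normalization = "numeric"))

#' Substitution penalties
#'
#' Virtual parent of the pluggable amino-acid substitution penalties:
#' \code{PropertyPenalty} (squared property-scale difference) and
#' \code{MatrixPenalty} (a symmetric penalty matrix derived from a
#' substitution score matrix such as BLOSUM62).
#'
#' @aliases PropertyPenalty MatrixPenalty
#' @export
setClass("SubstitutionPenalty", representation("VIRTUAL"))

#' @rdname SubstitutionPenalty-class
#' @slot scale a \code{PropertyScale}.
#' @export
setClass("PropertyPenalty", contains = "SubstitutionPenalty",
         representation(scale = "PropertyScale"))

#' @rdname SubstitutionPenalty-class
#' @slot d symmetric 20x20 penalty matrix with zero diagonal optionality.
#' @slot name label.
#' @export
setClass("MatrixPenalty", contains = "SubstitutionPenalty",
         representation(d = "matrix", name = "character"))

setValidity("MatrixPenalty", function(object) {
  d <- object@d
  if (!identical(dim(d), c(20L, 20L))) return("d must be 20x20")
  if (!setequal(rownames(d), AA_ORDER)) return("rows must be amino acids")
  if (max(abs(d - t(d))) > 1e-9) return("d must be symmetric")
  TRUE
})

#' Cost configuration
#'
#' Bundles the substitution penalty with the stop-misreading costs
#' \code{c0} (amino acid misread as stop) and \code{c1} (stop misread as an
#' amino acid). Both default to 0, under which stop-involving pairs drop out
#' of the cost numerator and denominator entirely.
#'
#' @slot penalty a \code{SubstitutionPenalty}.
#' @slot c0,c1 stop misreading costs.
#' @slot freq optional named amino-acid frequency weights for the
#'   frequency-weighted cost variant (empty numeric when unused).
#' @export
setClass("CostConfig",
         representation(penalty = "SubstitutionPenalty",
                        c0 = "numeric", c1 = "numeric", freq = "numeric"))

#' Binned cost axis
#'
#' Half-open, equal-width bins partitioning \code{[lower, upper)}. Costs
#' outside the range clamp to the edge bins.
#'
#' @slot lower,upper,width numeric.
#' @slot nBins integer bin count.
#' @export
setClass("CostGrid",
         representation(lower = "numeric", upper = "numeric",
                        width = "numeric", nBins = "integer"))

setValidity("CostGrid", function(object) {
  if (object@upper <= object@lower) return("upper must exceed lower")
  if (object@width <= 0) return("width must be positive")
  if (object@nBins < 2L) return("need at least two bins")
  TRUE
})

#' Multicanonical weight function
#'
#' Per-bin log weights (defined up to an additive constant) such that a
#' fixed-weight multicanonical run produces an approximately flat cost
#' histogram over the visited bins.
#'
#' @slot grid the \code{CostGrid}.
#' @slot logw per-bin log weight (finite on every bin after edge filling).
#' @slot visited which bins the training chain actually reached.
#' @slot diagnostics list with the training trace (stages, steps, final
#'   modification factor, convergence flag).
#' @export
setClass("WeightFunction",
         representation(grid = "CostGrid", logw = "numeric",
                        visited = "logical", diagnostics = "list"))

#' Density-of-states estimate
#'
#' Per-bin log density of states over a cost grid. \code{mode} is one of
#' \code{"relative"} (arbitrary additive constant), \code{"fraction"}
#' (exponentials over unmasked bins sum to 1) or \code{"count"} (absolute
#' state counts, anchored to the exact ensemble size). Unvisited bins are
#' \code{NA} (masked), never zero.
#'
#' @slot grid the \code{CostGrid}.
#' @slot logdos per-bin natural-log density of states.
#' @slot mode normalisation mode.
#' @slot visited unmasked-bin indicator.
#' @export
setClass("DOSEstimate",
         representation(grid = "CostGrid", logdos = "numeric",
                        mode = "character", visited = "logical"))

#' Batch of sampled codes
#'
#' Codes are stored as an integer matrix (one column per code, rows are the
#' 61 sense positions, values are amino-acid indices into \code{AA_ORDER});
#' the matrix may have zero columns when only costs were retained.
#'
#' @slot codes integer matrix (nSense x n, possibly 0 columns).
#' @slot costs numeric vector, one per sampled code.
#' @slot seed integer seed the batch was drawn under.
#' @slot ensemble label ("uniform", "block", "multicanonical", ...).
#' @export
setClass("CodeSample",
         representation(codes = "matrix", costs = "numeric",
                        seed = "integer", ensemble = "character"))

#' GA trajectory batch
#'
#' Per-generation best cost and best-code polar-requirement asymmetry for a
#' batch of independent genetic-algorithm runs, plus the first code each run
#' recorded inside the target cost slice.
#'
#' @slot bestCost,bestDpr generations x runs matrices.
#' @slot sliceCodes integer matrix (nSense x runs; NA column if the run never
#'   entered the slice).
#' @slot sliceCost,sliceGen per-run cost and generation of the recorded code.
#' @slot reached logical per run.
#' @slot config the \code{GAConfig}-like list used.
#' @slot seed integer.
#' @export
setClass("GABatch",
         representation(bestCost = "matrix", bestDpr = "matrix",
                        sliceCodes = "matrix", sliceCost = "numeric",
                        sliceGen = "integer", reached = "logical",
                        config = "list", seed = "integer"))

#' Landscape projection
#'
#' A principal-component projection fitted on the low-cost subset of
#' polar-requirement code vectors. Signs are fixed so the standard code has a
#' nonnegative first coordinate.
#'
#' @slot center 64-vector of column means.
#' @slot rotation 64 x k loading matrix.
#' @slot evr explained-variance ratios (nonincreasing, in [0,1]).
#' @slot cutoff the cost cutoff the projection was fitted under.
#' @export
setClass("LandscapeProjection",
         representation(center = "numeric", rotation = "matrix",
                        evr = "numeric", cutoff = "numeric"))

setValidity("LandscapeProjection", function(object) {
  e <- object@evr
  if (any(e < -1e-12 | e > 1 + 1e-12)) return("evr must lie in [0,1]")
  if (is.unsorted(rev(e), strictly = FALSE)) return("evr must be nonincreasing")
  TRUE
})

#' k-means cluster model on the projected landscape
#'
#' @slot k cluster count.
#' @slot centers k x d matrix in projection space.
#' @slot labels integer cluster label per sample.
#' @slot colors cluster naming ("red", "orange", "green", "blue", ...)
#'   assigned by occupancy rank and average-code signature.
#' @slot sse total within-cluster sum of squares.
#' @export
setClass("ClusterModel",
         representation(k = "integer", centers = "matrix",
                        labels = "integer", colors = "character",
                        sse = "numeric"))

#' Enumerable toy codon system
#'
#' A reduced codon system (smaller base alphabet/codon length/amino-acid
#' alphabet) small enough for exhaustive enumeration, used as an exact oracle
#' for the cost, sampling and density-of-states machinery. The misreading
#' weights reuse the position/transition class structure of the full model.
#'
#' @slot nBases,codonLen,nCodons,nAA integers.
#' @slot scale property values per toy symbol; the last two designated
#'   symbols hold the two largest values (the Asp/Glu analogue).
#' @slot ctx internal cost context (list) shared with the kernels.
#' @slot seed integer.
#' @export
setClass("ToySystem",
         representation(nBases = "integer", codonLen = "integer",
                        nCodons = "integer", nAA = "integer",
                        scale = "numeric", ctx = "list", seed = "integer"))
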