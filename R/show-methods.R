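# show() and plot() methods

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (64 codons,",
      sum(object@assignments == STOP_SYMBOL), "stops)\n")
  tab <- codeTable(object@assignments)
  print(tab, quote = FALSE)
})

setMethod("show", "PropertyScale", function(object) {
  cat("PropertyScale:", object@name, "\n")
  print(round(sort(object@values, decreasing = TRUE), 2))
})

setMethod("show", "EnsembleConstraints", function(object) {
  cat("EnsembleConstraints: stops pinned;",
      if (object@requireAll20) "all 20 amino acids required;" else "",
      sprintf("Asp >= %d, Glu >= %d\n", object@minAsp, object@minGlu))
})

setMethod("show", "CostGrid", function(object) {
  cat(sprintf("CostGrid: [%g, %g), width %g (%d bins)\n", object@lower,
              object@upper, object@width, object@nBins))
})

setMethod("show", "WeightFunction", function(object) {
  d <- object@diagnostics
  cat(sprintf(paste0("Multicanonical WeightFunction on [%g, %g): %d/%d bins",
                     " visited; %s flatness passes, %.3g training steps\n"),
              object@grid@lower, object@grid@upper, sum(object@visited),
              object@grid@nBins, d$stages, d$steps))
})

setMethod("show", "DOSEstimate", function(object) {
  cat(sprintf("DOSEstimate (%s mode) on [%g, %g): %d/%d bins estimated\n",
              object@mode, object@grid@lower, object@grid@upper,
              sum(object@visited), object@grid@nBins))
})

setMethod("show", "CodeSample", function(object) {
  cat(sprintf("CodeSample: %d costs (%s ensemble), %d codes retained\n",
              length(object@costs), object@ensemble, ncol(object@codes)))
  if (length(object@costs))
    cat(sprintf("  cost range [%.3f, %.3f]\n", min(object@costs),
                max(object@costs)))
})

setMethod("show", "GABatch", function(object) {
  cat(sprintf("GABatch: %d runs x %d generations; %d reached the slice\n",
              ncol(object@bestCost), nrow(object@bestCost),
              sum(object@reached)))
})

setMethod("show", "LandscapeProjection", function(object) {
  cat(sprintf("LandscapeProjection (fit below cost %.2f): EVR %s\n",
              object@cutoff,
              paste(sprintf("%.1f%%", 100 * object@evr), collapse = ", ")))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d (%s), SSE %.3g\n", object@k,
              paste(object@colors, collapse = "/"), object@sse))
})

setMethod("show", "ToySystem", function(object) {
  cat(sprintf("ToySystem: %d codons (%d^%d), %d symbols, %g states\n",
              object@nCodons, object@nBases, object@codonLen, object@nAA,
              object@nAA^as.numeric(object@nCodons)))
})

#' Plot a density-of-states estimate
#'
#' Base-graphics view of the per-bin log10 density of states, with an
#' optional threshold marker.
#'
#' @param x a \linkS4class{DOSEstimate}.
#' @param y unused.
#' @param threshold optional vertical cost marker.
#' @param ... passed to \code{plot}.
#' @export
setMethod("plot", signature("DOSEstimate", "missing"),
          function(x, y, threshold = NULL, ...) {
  mids <- binMidpoints(x@grid)
  graphics::plot(mids[x@visited], x@logdos[x@visited] / log(10),
                 type = "l", xlab = "cost",
                 ylab = sprintf("log10 density of states (%s)", x@mode), ...)
  if (!is.null(threshold))
    graphics::abline(v = threshold, lty = 2, col = "gray40")
})
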