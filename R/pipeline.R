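# Config-driven pipeline driver: runs the stages of the landscape analysis
# from a single (possibly file-based) configuration with explicit seeds, and
# writes the standard artifacts into an output directory.

#' Default pipeline configuration
#'
#' A scaled-down but complete end-to-end configuration: ensemble
#' constraints, cost grid, Wang-Landau schedule, multicanonical production
#' length, GA batch size, landscape cutoffs and per-stage seeds. Every
#' stochastic stage draws its seed deterministically from the master seed.
#'
#' @param seed master seed.
#' @param outDir output directory (created on demand; NULL disables
#'   writing).
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outDir = NULL) {
  list(seed = as.integer(seed), outDir = outDir,
       constraints = list(minAsp = 2L, minGlu = 2L),
       grid = list(lower = 2, upper = 21, width = 0.01),
       schedule = list(logf0 = 1.0, flatness = 0.8, minLogf = 1e-6,
                       checkEvery = 1e5, maxSteps = 5e8),
       muca = list(steps = 6e8, thin = 150L, keepBelow = 2.7),
       ga = list(runs = 1000L, N = 100L, mu = 0.1, generations = 500L),
       landscape = list(cutoff = 2.7, slice = c(2.5, 2.7), kMax = 8L,
                        nstart = 50L, dims = 3L),
       naive = list(n = 1e5))
}

#' Run the landscape pipeline
#'
#' Executes the full analysis from one configuration: exact ensemble count,
#' Wang-Landau weight training, fixed-weight multicanonical production,
#' density-of-states and tail estimates, naive-sampling cross-check, the GA
#' batch, and the PCA / k-means landscape with cluster occupancies. All
#' stage seeds derive from \code{config$seed}; re-running with the same
#' configuration reproduces every artifact.
#'
#' @param config list as returned by \code{\link{defaultPipelineConfig}}, or
#'   a path to a YAML file with the same structure (requires the yaml
#'   package).
#' @param verbose print per-stage progress.
#' @return list with all stage results.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), verbose = TRUE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- utils::modifyList(defaultPipelineConfig(),
                                yaml::read_yaml(config))
  }
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  stageSeed <- function(k) (seed * 97L + k) %% .Machine$integer.max
  cons <- ensembleConstraints(config$constraints$minAsp,
                              config$constraints$minGlu)
  grid <- costGrid(config$grid$lower, config$grid$upper, config$grid$width)
  out <- list(config = config)

  out$sgcCost <- codeCost(sgcCode())
  out$ensembleSize <- countEnsemble(cons)
  say("SGC cost %.4f; ensemble log10 size %.2f", out$sgcCost,
      out$ensembleSize$log10)

  say("training multicanonical weights (Wang-Landau) ...")
  sched <- do.call(wlSchedule, config$schedule)
  out$weight <- wangLandau(cons, grid, sched, seed = stageSeed(1L))
  say("  %d flatness passes in %.3g steps",
      out$weight@diagnostics$stages, out$weight@diagnostics$steps)

  say("multicanonical production (%.3g steps) ...", config$muca$steps)
  out$muca <- mucaSample(out$weight, cons, steps = config$muca$steps,
                         seed = stageSeed(2L), thin = config$muca$thin,
                         keepBelow = config$muca$keepBelow)
  out$dos <- estimateDOS(out$muca$hist, out$weight, mode = "fraction")
  out$tailBelowSGC <- tailLog10(out$dos, out$sgcCost)
  say("  log10 tail below the SGC cost: %.2f", out$tailBelowSGC)

  say("naive-sampling cross-check (n = %.3g) ...", config$naive$n)
  out$naive <- naiveSample(config$naive$n, cons, seed = stageSeed(3L),
                           keepCodes = FALSE)

  say("GA batch (%d runs) ...", config$ga$runs)
  gaConf <- gaConfig(N = config$ga$N, mu = config$ga$mu,
                     generations = config$ga$generations)
  out$ga <- gaRun(config$ga$runs, gaConf, cons, seed = stageSeed(4L),
                  slice = config$landscape$slice)

  say("landscape reconstruction ...")
  ls <- config$landscape
  dims <- seq_len(if (is.null(ls$dims)) 3L else ls$dims)
  vec <- vectorizeCodes(out$muca$sample)
  costs <- out$muca$sample@costs
  out$projection <- fitLandscape(vec, costs, cutoff = ls$cutoff)
  pts <- projectCodes(out$projection, vec)[, dims, drop = FALSE]
  out$elbow <- elbowK(pts, kMax = ls$kMax, seed = stageSeed(5L),
                      nstart = ls$nstart)
  sense <- setdiff(1:64, sgcStopPositions())
  side <- .senseSideMask() == 1L
  dpr <- rowMeans(vec[, sense[side], drop = FALSE]) -
    rowMeans(vec[, sense[!side], drop = FALSE])
  out$clusters <- clusterCodes(pts, out$elbow$k, costs = costs, dpr = dpr,
                               projection = out$projection,
                               slice = ls$slice, seed = stageSeed(6L),
                               nstart = ls$nstart)
  out$occupancy <- clusterOccupancy(out$clusters, costs, ls$slice)
  gaCodes <- out$ga@sliceCodes[, out$ga@reached, drop = FALSE]
  if (ncol(gaCodes)) {
    gaPts <- projectCodes(out$projection,
                          vectorizeCodes(gaCodes))[, dims, drop = FALSE]
    lbl <- assignClusters(out$clusters, gaPts)
    occ <- tabulate(lbl, out$clusters@k)
    out$gaOccupancy <- stats::setNames(occ / sum(occ),
                                       names(out$occupancy))
  }
  say("  occupancy: %s",
      paste(sprintf("%s %.1f%%", names(out$occupancy),
                    100 * out$occupancy), collapse = ", "))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeWeights(out$weight, file.path(config$outDir, "weights.tsv"))
    writeDOS(out$dos, file.path(config$outDir, "dos.tsv"))
    jsonlite::write_json(
      list(seed = seed, sgc_cost = out$sgcCost,
           log10_ensemble = out$ensembleSize$log10,
           log10_tail_below_sgc = out$tailBelowSGC,
           elbow_k = out$elbow$k,
           occupancy = as.list(out$occupancy),
           ga_occupancy = as.list(out$gaOccupancy)),
      file.path(config$outDir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
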