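# Landscape reconstruction: polar-requirement vectorisation, PCA on the
# low-cost slice, k-means with elbow selection, cluster occupancy, average
# codes, and the stacked-slab landscape export.

#' Polar-requirement vectorisation of codes
#'
#' Maps each code to the 64-vector whose entry c holds the property value of
#' the amino acid encoded at codon c; the three (ensemble-invariant) stop
#' positions hold a fixed constant and carry zero variance.
#'
#' @param codes a \linkS4class{CodeSample}, an integer sense-position matrix,
#'   a single \linkS4class{GeneticCode}, or a list of them.
#' @param scale a \linkS4class{PropertyScale}.
#' @param stopValue constant stored at the stop positions.
#' @return numeric matrix, one row per code, 64 columns.
#' @export
vectorizeCodes <- function(codes, scale = polarRequirement(), stopValue = 0) {
  if (is(codes, "GeneticCode")) codes <- list(codes)
  m <- if (is(codes, "CodeSample")) codes@codes
  else if (is.matrix(codes)) codes
  else vapply(codes, .codeToInt, integer(61))
  if (!is.matrix(m) || nrow(m) != 61L)
    stop("expected codes over the 61 sense positions")
  v <- unname(scale@values[AA_ORDER])
  sense <- setdiff(1:64, sgcStopPositions())
  out <- matrix(stopValue, ncol(m), 64)
  out[, sense] <- t(matrix(v[m + 1L], 61L, ncol(m)))
  out
}

#' Fit the landscape projection
#'
#' Principal components of the property vectors of the low-cost subset
#' (cost < cutoff), mean-centred and unscaled (all coordinates share
#' property units). The fitted projection can then place samples of any
#' cost. Component signs are fixed deterministically: the standard code's
#' first coordinate is forced nonnegative, and each further component's
#' largest-magnitude loading is forced positive.
#'
#' @param vectors matrix from \code{\link{vectorizeCodes}}.
#' @param costs parallel cost vector.
#' @param cutoff fit cutoff (default 2.7, the standard-code slice upper
#'   edge).
#' @param rank number of components to keep.
#' @return a \linkS4class{LandscapeProjection}.
#' @export
fitLandscape <- function(vectors, costs, cutoff = 2.7, rank = 3L) {
  sel <- costs < cutoff
  if (sum(sel) < 2L) stop("need at least two samples below the cutoff")
  x <- vectors[sel, , drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = rank)
  tot <- sum(pc$sdev^2)
  if (tot <= 0) stop("degenerate input: zero total variance below cutoff")
  rot <- pc$rotation
  # sign convention
  sgcCoord <- (vectorizeCodes(sgcCode()) - rep(pc$center, each = 1)) %*% rot
  if (sgcCoord[1] < 0) rot[, 1] <- -rot[, 1]
  for (j in seq_len(ncol(rot))[-1]) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  new("LandscapeProjection", center = pc$center, rotation = rot,
      evr = (pc$sdev^2 / tot)[seq_len(ncol(rot))], cutoff = cutoff)
}

#' @rdname fitLandscape
#' @param projection a \linkS4class{LandscapeProjection}.
#' @return \code{projectCodes}: sample coordinates on the leading
#'   components.
#' @export
projectCodes <- function(projection, vectors)
  sweep(vectors, 2, projection@center) %*% projection@rotation

#' @rdname fitLandscape
#' @return \code{explainedVariance}: the explained-variance ratios.
#' @export
explainedVariance <- function(projection) projection@evr

#' Elbow selection of the cluster count
#'
#' Runs k-means for k = 1..kMax with multiple seeded restarts and picks the
#' knee of the within-cluster sum-of-squares (SSE) curve: the largest k
#' whose SSE decrement still dominates the following decrement by at least
#' \code{minStrength} (the point where a rapid decline turns slow), among
#' drops that are a nontrivial fraction of the total variance. When no drop
#' dominates, the curve is deemed structureless and k = 1 is returned.
#'
#' @param points numeric matrix of sample coordinates.
#' @param kMax largest k considered.
#' @param seed integer seed.
#' @param nstart k-means restarts per k.
#' @param minStrength dominance threshold for accepting an elbow.
#' @return list with \code{k} and the \code{sse} curve.
#' @export
elbowK <- function(points, kMax = 8L, seed = 1L, nstart = 50L,
                   minStrength = 4) {
  points <- as.matrix(points)
  if (nrow(points) < kMax) stop("fewer points than kMax")
  set.seed(seed)
  sse1 <- sum(scale(points, scale = FALSE)^2)
  if (sse1 <= max(1e-12, 1e-9 * nrow(points)))
    return(list(k = 1L, sse = sse1))  # degenerate: all points coincide
  # Quick-TRANSfer warnings from Hartigan-Wong on large near-continuous
  # clouds are benign here (the restarts keep the best solution)
  sse <- c(sse1, vapply(2:kMax, function(k)
    suppressWarnings(stats::kmeans(points, k, nstart = nstart,
                                   iter.max = 100L))$tot.withinss,
    numeric(1)))
  drops <- -diff(sse)                     # drop achieved by adding cluster k
  eps <- 1e-12 * sse1
  ratio <- drops[-length(drops)] / pmax(drops[-1], eps)
  # candidate knees: drops that dominate their successor and remove a
  # meaningful share of the SSE they act on
  nd <- length(drops) - 1L
  cand <- which(ratio >= minStrength &
                  drops[seq_len(nd)] >= 0.05 * sse[seq_len(nd)])
  k <- if (length(cand)) max(cand) + 1L else 1L
  list(k = as.integer(k), sse = sse)
}

#' Cluster the projected landscape
#'
#' Seeded k-means with multiple restarts, plus the deterministic
#' cluster-to-colour naming used throughout: the cluster whose average code
#' has negative right-left polar-requirement asymmetry (high polar
#' requirement in the two left columns) is "blue"; the cluster holding the
#' standard code is "green"; the remaining clusters are "red", "orange", ...
#' by decreasing occupancy inside the reference slice.
#'
#' @param points projected coordinates (fit subset).
#' @param k cluster count.
#' @param costs costs parallel to \code{points} (for the naming slice).
#' @param dpr right-left asymmetry per sample (see \code{\link{deltaPR}});
#'   when supplied, cluster asymmetry is the mean over members.
#' @param projection the fitted \linkS4class{LandscapeProjection} (locates
#'   the standard code).
#' @param slice naming/occupancy slice.
#' @param seed,nstart k-means controls.
#' @return a \linkS4class{ClusterModel}.
#' @export
clusterCodes <- function(points, k, costs = NULL, dpr = NULL,
                         projection = NULL, slice = c(2.5, 2.7),
                         seed = 1L, nstart = 50L) {
  points <- as.matrix(points)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(points, k, nstart = nstart,
                                       iter.max = 100L))
  colors <- rep(NA_character_, k)
  if (!is.null(costs) && !is.null(dpr) && !is.null(projection)) {
    inSlice <- costs >= slice[1] & costs < slice[2]
    occ <- tabulate(km$cluster[inSlice], k)
    meanDpr <- vapply(seq_len(k), function(j)
      mean(dpr[km$cluster == j]), numeric(1))
    blue <- which.min(meanDpr)
    if (!meanDpr[blue] < 0) blue <- NA_integer_
    sgcPt <- projectCodes(projection, vectorizeCodes(sgcCode()))
    d2 <- colSums((t(km$centers) - as.numeric(sgcPt[1, seq_len(ncol(points))]))^2)
    if (!is.na(blue)) d2[blue] <- Inf
    green <- which.min(d2)
    rest <- setdiff(seq_len(k), c(blue, green))
    rest <- rest[order(occ[rest], decreasing = TRUE)]
    restNames <- c("red", "orange", "purple", "brown", "pink", "gray")
    if (!is.na(blue)) colors[blue] <- "blue"
    colors[green] <- "green"
    colors[rest] <- restNames[seq_along(rest)]
    colors[is.na(colors)] <- "other"
  }
  new("ClusterModel", k = as.integer(k), centers = km$centers,
      labels = km$cluster, colors = colors, sse = km$tot.withinss)
}

#' Cluster occupancy in a cost slice
#'
#' Fractions of samples per cluster among samples whose cost falls in the
#' slice. Multicanonical samples are ensemble-weighted within a narrow
#' slice, so raw within-slice counts estimate the clusters' phase-volume
#' shares; GA-derived samples are counted raw deliberately, since the bias
#' between the two is the object of study.
#'
#' @param model a \linkS4class{ClusterModel} fitted on the samples.
#' @param costs sample costs.
#' @param slice lower/upper cost bounds.
#' @return named numeric occupancy fractions (sum to 1).
#' @export
clusterOccupancy <- function(model, costs, slice = c(2.5, 2.7)) {
  sel <- costs >= slice[1] & costs < slice[2]
  if (!any(sel)) stop("no samples in the requested cost slice")
  occ <- tabulate(model@labels[sel], model@k)
  frac <- occ / sum(occ)
  names(frac) <- ifelse(is.na(model@colors), seq_len(model@k), model@colors)
  frac
}

#' Assign new samples to fitted clusters
#'
#' Nearest-centre labels for points that were not part of the k-means fit
#' (e.g. GA-derived codes placed on the multicanonical projection).
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param points coordinates in the model's projection space.
#' @return integer labels.
#' @export
assignClusters <- function(model, points) {
  points <- as.matrix(points)[, seq_len(ncol(model@centers)), drop = FALSE]
  d <- outer(rowSums(points^2), rowSums(model@centers^2), "+") -
    2 * points %*% t(model@centers)
  max.col(-d)
}

#' Average code of a cluster
#'
#' Per-codon mean property value over a set of codes - the "average
#' structure" of a landscape peak, displayed as the standard 16 x 4 codon
#' table.
#'
#' @param codes codes (as accepted by \code{\link{vectorizeCodes}}).
#' @param scale a \linkS4class{PropertyScale}.
#' @return numeric vector of 64 per-codon means, with a
#'   \code{codeTable}-ready layout available via \code{\link{codeTable}}.
#' @export
averageCode <- function(codes, scale = polarRequirement()) {
  v <- vectorizeCodes(codes, scale, stopValue = NA_real_)
  colMeans(v)
}

#' Codon-table layout of a 64-vector
#'
#' Reshapes a per-codon vector into the familiar 16-row (first and third
#' base) by 4-column (second base) codon table.
#'
#' @param x numeric or character vector of length 64 in codon-index order.
#' @return a 16 x 4 matrix with informative dimnames.
#' @export
codeTable <- function(x) {
  stopifnot(length(x) == 64L)
  # row = 4*(first base) + third base, col = second base
  idx <- seq_len(64) - 1L
  b1 <- idx %/% 16L; b2 <- (idx %/% 4L) %% 4L; b3 <- idx %% 4L
  m <- matrix(NA, 16, 4)
  m[cbind(4L * b1 + b3 + 1L, b2 + 1L)] <- x
  rownames(m) <- paste0(rep(RNA_BASES, each = 4), "_", rep(RNA_BASES, 4))
  colnames(m) <- RNA_BASES
  m
}

#' Stacked-slab landscape export
#'
#' Slices samples into cost slabs of the given width (ordered by decreasing
#' cost) and attaches their projected coordinates - the piled-up scatterplot
#' representation of the landscape. Empty slabs are preserved in the
#' ordering.
#'
#' @param points projected coordinates.
#' @param costs parallel costs.
#' @param slabWidth slab thickness in cost units.
#' @return data frame with slab index, slab cost bounds, and coordinates;
#'   the slab levels (including empty ones) are in the \code{"slabs"}
#'   attribute.
#' @export
landscapeStack <- function(points, costs, slabWidth = 0.5) {
  points <- as.matrix(points)
  lo <- floor(min(costs) / slabWidth) * slabWidth
  hi <- ceiling(max(costs) / slabWidth) * slabWidth
  edges <- seq(hi, lo, by = -slabWidth)
  nSlab <- length(edges) - 1L
  slab <- nSlab - (floor((costs - lo) / slabWidth)) # 1 = highest cost
  slab[slab < 1L] <- 1L; slab[slab > nSlab] <- nSlab
  out <- data.frame(slab = as.integer(slab),
                    slabUpper = edges[slab], slabLower = edges[slab + 1L])
  for (j in seq_len(ncol(points)))
    out[[paste0("PC", j)]] <- points[, j]
  out <- out[order(out$slab), , drop = FALSE]
  attr(out, "slabs") <- data.frame(slab = seq_len(nSlab),
                                   upper = edges[-length(edges)],
                                   lower = edges[-1])
  out
}
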