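# The misreading cost: TS/TV-weighted single-base error probabilities, the
# squared property-difference penalty (with pluggable alternatives), and the
# incremental single-flip update used by the Monte Carlo kernels.

# weight of misreading by a single change at position p (1..3) from b to b2:
# 3rd base any change 1; 1st base TS 1, TV 0.5; 2nd base TS 0.5, TV 0.1.
.misreadWeight <- function(p, b, b2) {
  ts <- isTransition(b, b2)
  if (p == 3L) 1
  else if (p == 1L) ifelse(ts, 1, 0.5)
  else ifelse(ts, 0.5, 0.1)
}

# all 576 weighted ordered codon pairs (each codon has exactly 9 single-base
# neighbours; double/triple changes carry weight 0 and are omitted)
.misreadPairs <- local({
  from <- integer(0); to <- integer(0); w <- numeric(0)
  split3 <- strsplit(.codons, "")
  for (i in 1:64) {
    b <- split3[[i]]
    for (p in 1:3) {
      for (nb in setdiff(RNA_BASES, b[p])) {
        b2 <- b; b2[p] <- nb
        j <- match(paste(b2, collapse = ""), .codons)
        from <- c(from, i); to <- c(to, j)
        w <- c(w, .misreadWeight(p, b[p], nb))
      }
    }
  }
  list(from = from, to = to, w = w)
})

#' The single-base misreading model
#'
#' Raw misreading weights over all ordered single-base codon neighbour
#' pairs: 1 for any change in the 3rd base, 1 (transition) or 0.5
#' (transversion) in the 1st base, 0.5 / 0.1 in the 2nd base, and 0 for
#' double or triple changes. The normalisation slot holds the total raw
#' weight over ordered sense-sense pairs (stop codons at the standard
#' positions excluded), the denominator of the cost.
#'
#' @return a \linkS4class{MisreadingModel}.
#' @export
misreadingWeights <- function() {
  p <- .misreadPairs
  stops <- sgcStopPositions()
  sense <- !(p$from %in% stops) & !(p$to %in% stops)
  new("MisreadingModel", from = p$from, to = p$to, weight = p$w,
      normalization = sum(p$w[sense]))
}

#' Substitution penalty constructors
#'
#' \code{propertyPenalty} is the squared difference of a property scale
#' (polar requirement by default). \code{matrixPenalty} wraps an explicit
#' symmetric penalty matrix; \code{scorePenalty} derives one from a
#' substitution score matrix as d = max(score) - score, symmetrised - a
#' monotone-decreasing transform appropriate for similarity scores such as
#' BLOSUM62 (an approximation used for the landscape-robustness variant).
#'
#' @param scale a \linkS4class{PropertyScale}.
#' @param d symmetric 20x20 matrix with amino-acid dimnames.
#' @param score substitution score matrix (at least the 20 standard amino
#'   acids; extra rows/columns are dropped).
#' @param name label.
#' @return a \linkS4class{SubstitutionPenalty}.
#' @export
propertyPenalty <- function(scale = polarRequirement())
  new("PropertyPenalty", scale = scale)

#' @rdname propertyPenalty
#' @export
matrixPenalty <- function(d, name = "matrix") {
  d <- d[AA_ORDER, AA_ORDER]
  new("MatrixPenalty", d = (d + t(d)) / 2, name = name)
}

#' @rdname propertyPenalty
#' @export
scorePenalty <- function(score, name = "score-derived") {
  s <- score[AA_ORDER, AA_ORDER]
  s <- (s + t(s)) / 2
  matrixPenalty(max(s) - s, name = name)
}

#' @rdname propertyPenalty
#' @param penalty a \linkS4class{SubstitutionPenalty}.
#' @return \code{penaltyMatrix}: the 20x20 numeric penalty matrix in
#'   \code{AA_ORDER}.
#' @export
penaltyMatrix <- function(penalty) {
  if (is(penalty, "PropertyPenalty")) {
    v <- penalty@scale@values[AA_ORDER]
    m <- outer(v, v, function(x, y) (x - y)^2)
    dimnames(m) <- list(AA_ORDER, AA_ORDER)
    m
  } else penalty@d
}

#' Cost configuration
#'
#' @param penalty substitution penalty (squared polar-requirement difference
#'   by default).
#' @param c0 cost of misreading an amino acid as the terminal signal.
#' @param c1 cost of misreading the terminal signal as an amino acid. With
#'   the default \code{c0 = c1 = 0}, stop-involving codon pairs contribute
#'   nothing and are excluded from the normalisation as well.
#' @param freq optional named amino-acid frequencies; when supplied, each
#'   misreading term is weighted by the frequency of the source amino acid
#'   (the frequency-weighted cost variant).
#' @return a \linkS4class{CostConfig}.
#' @export
costConfig <- function(penalty = propertyPenalty(), c0 = 0, c1 = 0,
                       freq = numeric(0)) {
  if (length(freq)) freq <- freq[AA_ORDER] / sum(freq[AA_ORDER])
  new("CostConfig", penalty = penalty, c0 = c0, c1 = c1, freq = freq)
}

#' Misreading cost of a genetic code
#'
#' The weight-normalised mean substitution penalty over ordered single-error
#' codon pairs:
#' cost(a) = sum_{c,c'} P(c'|c) d(a(c), a(c')), with P proportional to the
#' TS/TV misreading weights and normalised over the counted pairs. Under the
#' default \code{c0 = c1 = 0} only sense-sense pairs are counted; the
#' standard code scores 2.63.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param config a \linkS4class{CostConfig}.
#' @return numeric cost.
#' @examples
#' codeCost(sgcCode())  # 2.628
#' @export
codeCost <- function(code, config = costConfig()) {
  a <- code@assignments
  if (!all(a %in% c(AA_ORDER, STOP_SYMBOL)))
    stop("code contains symbols outside the amino-acid alphabet")
  d <- penaltyMatrix(config@penalty)
  p <- .misreadPairs
  af <- a[p$from]; at <- a[p$to]
  ss <- af != STOP_SYMBOL & at != STOP_SYMBOL
  srcw <- if (length(config@freq)) {
    fw <- rep(1, length(af))
    fw[af != STOP_SYMBOL] <- config@freq[af[af != STOP_SYMBOL]] * 20
    fw
  } else rep(1, length(af))
  num <- sum(p$w[ss] * srcw[ss] * d[cbind(af[ss], at[ss])])
  den <- sum(p$w[ss] * srcw[ss])
  if (config@c0 != 0 || config@c1 != 0) {
    toStop <- af != STOP_SYMBOL & at == STOP_SYMBOL
    fromStop <- af == STOP_SYMBOL
    num <- num + config@c0 * sum(p$w[toStop] * srcw[toStop]) +
      config@c1 * sum(p$w[fromStop] * srcw[fromStop])
    den <- den + sum(p$w[toStop] * srcw[toStop]) +
      sum(p$w[fromStop] * srcw[fromStop])
  }
  num / den
}

#' Incremental cost change of a single-codon flip
#'
#' Returns \code{codeCost(flipped) - codeCost(code)} touching only the nine
#' neighbours of the flipped codon, the O(1) update that makes long Monte
#' Carlo chains affordable. Only sense positions may be flipped.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param position codon index (1..64) of a sense codon.
#' @param newSymbol replacement amino acid (one-letter), different from the
#'   current one.
#' @param config a \linkS4class{CostConfig} (default stop costs only).
#' @return numeric cost difference.
#' @export
deltaCost <- function(code, position, newSymbol, config = costConfig()) {
  if (position %in% sgcStopPositions())
    stop("stop positions are pinned and cannot be flipped")
  if (!newSymbol %in% AA_ORDER) stop("unknown amino acid: ", newSymbol)
  cur <- code@assignments[position]
  if (identical(cur, newSymbol)) stop("newSymbol equals the current symbol")
  ctx <- .fullContext(config = config)
  sense <- setdiff(1:64, sgcStopPositions())
  ai <- .codeToInt(code)
  pos0 <- match(position, sense) - 1L
  .cpp_delta(ai, pos0, match(newSymbol, AA_ORDER) - 1L, ctx)
}

# ---- internal: the kernel cost context -------------------------------------

# integer encoding of the 61 sense positions of a GeneticCode (0-based AA)
.codeToInt <- function(code) {
  sense <- setdiff(1:64, sgcStopPositions())
  match(code@assignments[sense], AA_ORDER) - 1L
}

.intToCode <- function(x) {
  a <- character(64)
  a[sgcStopPositions()] <- STOP_SYMBOL
  a[setdiff(1:64, sgcStopPositions())] <- AA_ORDER[x + 1L]
  geneticCode(a)
}

# Cost context shared with the compiled kernels: sense-sense neighbour table
# (0-based sense indices), penalty matrix, total pair weight, and the
# per-symbol multiplicity floors. Assumes c0 = c1 = 0 (stop pairs dropped).
.fullContext <- function(constraints = ensembleConstraints(),
                         config = costConfig()) {
  if (config@c0 != 0 || config@c1 != 0)
    stop("the sampling kernels assume c0 = c1 = 0")
  stops <- sgcStopPositions()
  sense <- setdiff(1:64, stops)
  p <- .misreadPairs
  keep <- p$from %in% sense & p$to %in% sense
  from <- match(p$from[keep], sense)
  to <- match(p$to[keep], sense)
  w <- p$w[keep]
  K <- max(table(from))
  nbr <- matrix(-1L, K, 61)
  nbw <- matrix(0, K, 61)
  for (i in seq_along(from)) {
    k <- which(nbr[, from[i]] == -1L)[1]
    nbr[k, from[i]] <- to[i] - 1L
    nbw[k, from[i]] <- w[i]
  }
  list(nPos = 61L, nAA = 20L, d = unname(penaltyMatrix(config@penalty)),
       nbr = nbr, nbw = nbw, Wtot = sum(w),
       minCount = unname(.minCountVector(constraints)))
}

# right/left column indicator for the 61 sense codons: 1 when the 2nd base is
# A or G (the right half of the codon table), 0 for U or C
.senseSideMask <- function() {
  sense <- setdiff(1:64, sgcStopPositions())
  b2 <- substr(.codons[sense], 2, 2)
  as.integer(b2 %in% c("A", "G"))
}

#' Read a substitution score matrix
#'
#' Parses the standard whitespace-separated square matrix format (BLOSUM/PAM
#' style, `#` comments, single-letter row and column labels).
#'
#' @param path file path.
#' @return numeric matrix with row/column names.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(m) <- vapply(rows, `[`, "", 1)
  colnames(m) <- header
  m
}
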