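# Canonical codon indexing, the standard code fixture, the polar-requirement
# scale, and the random-ensemble constraints.

#' Canonical alphabets
#'
#' \code{AA_ORDER} fixes the internal ordering of the 20 standard amino acids
#' (one-letter codes, classical biochemical order); \code{STOP_SYMBOL} is the
#' stop sign used in 64-character code serialisations; \code{RNA_BASES} is the
#' base ordering U, C, A, G that underlies the codon enumeration.
#'
#' @format Character vectors.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname AA_ORDER
#' @export
STOP_SYMBOL <- "*"

#' @rdname AA_ORDER
#' @export
RNA_BASES <- c("U", "C", "A", "G")

# all 64 codons in enumeration order: UUU, UUC, ..., GGG (first base slowest)
.codons <- local({
  g <- expand.grid(b3 = RNA_BASES, b2 = RNA_BASES, b1 = RNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
})

# standard genetic code in codon-index order
.SGC_STRING <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

# Woese's polar-requirement scale (chromatographic hydrophilicity), the
# classic values used throughout the error-minimisation literature. Asp and
# Glu carry the two largest values, which is what motivates the >= 2
# multiplicity constraint on them.
.POLAR_REQUIREMENT <- c(
  A = 7.0, R = 9.1, N = 10.0, D = 13.0, C = 4.8, Q = 8.6, E = 12.5,
  G = 7.9, H = 8.4, I = 4.9, L = 4.9, K = 10.1, M = 5.3, F = 5.0,
  P = 6.6, S = 7.5, T = 6.6, W = 5.2, Y = 5.4, V = 5.6)

#' Codon indexing
#'
#' Maps base triples to codon indices and back, following the enumeration
#' from UUU (index 1) to GGG (index 64) with the first base varying slowest
#' and base order U, C, A, G; i.e.
#' \code{index = 16 b1 + 4 b2 + b3 + 1} with U=0, C=1, A=2, G=3.
#'
#' @param triple character vector of 3-base codons over U/C/A/G (T is
#'   accepted and read as U).
#' @param index integer vector in 1..64.
#' @return \code{codonIndex}: integer indices; \code{codonTriple}: codon
#'   strings.
#' @examples
#' codonIndex("UUU")  # 1
#' codonIndex("GGG")  # 64
#' codonTriple(codonIndex("AUG"))
#' @export
codonIndex <- function(triple) {
  triple <- toupper(gsub("T", "U", triple))
  bad <- !grepl("^[UCAG]{3}$", triple)
  if (any(bad))
    stop("not a valid base triple: ", paste(triple[bad], collapse = ", "))
  match(triple, .codons)
}

#' @rdname codonIndex
#' @export
codonTriple <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L | index > 64L))
    stop("codon index must lie in 1..64")
  .codons[index]
}

#' Transition or transversion?
#'
#' A base interchange is a transition when it stays within the purines
#' (A, G) or within the pyrimidines (C, U), and a transversion otherwise.
#'
#' @param b1,b2 single bases (distinct).
#' @return logical: \code{TRUE} for a transition.
#' @examples
#' isTransition("A", "G")  # TRUE
#' isTransition("A", "C")  # FALSE
#' @export
isTransition <- function(b1, b2) {
  b1 <- toupper(gsub("T", "U", b1)); b2 <- toupper(gsub("T", "U", b2))
  ok <- b1 %in% RNA_BASES & b2 %in% RNA_BASES
  if (!all(ok)) stop("unknown base symbol")
  if (any(b1 == b2)) stop("b1 and b2 must differ (no self-interchange)")
  purine <- c(U = FALSE, C = FALSE, A = TRUE, G = TRUE)
  purine[b1] == purine[b2]
}

#' Construct a genetic code
#'
#' @param x a 64-character string or a character vector of 64 one-letter
#'   symbols (stop = \code{"*"}).
#' @return a \linkS4class{GeneticCode}.
#' @export
geneticCode <- function(x) {
  if (length(x) == 1L && nchar(x) == 64L) x <- strsplit(x, "")[[1]]
  new("GeneticCode", assignments = as.character(x))
}

#' The standard genetic code
#'
#' The canonical 64-codon table with its three stop codons (UAA, UAG, UGA)
#' and 61 sense codons; Asp and Glu each appear exactly twice.
#'
#' @return a \linkS4class{GeneticCode}.
#' @export
sgcCode <- function() geneticCode(.SGC_STRING)

#' @rdname sgcCode
#' @return \code{sgcStopPositions}: the three stop codon indices.
#' @export
sgcStopPositions <- function() which(strsplit(.SGC_STRING, "")[[1]] == STOP_SYMBOL)

#' Code accessors
#'
#' @param code a \linkS4class{GeneticCode}.
#' @return \code{codeString}: the 64-character serialisation;
#'   \code{codeAssignments}: the character vector of symbols.
#' @export
codeString <- function(code) paste(code@assignments, collapse = "")

#' @rdname codeString
#' @export
codeAssignments <- function(code) code@assignments

#' The polar-requirement scale
#'
#' Woese's chromatographic polar-requirement values for the 20 amino acids.
#' Asp (13.0) and Glu (12.5) hold the two largest values.
#'
#' @return a \linkS4class{PropertyScale}.
#' @export
polarRequirement <- function()
  new("PropertyScale", values = .POLAR_REQUIREMENT, name = "polar requirement")

#' @rdname polarRequirement
#' @param scale a \linkS4class{PropertyScale}.
#' @export
scaleValues <- function(scale) scale@values

#' Construct a property scale
#'
#' @param values named numeric over the 20 one-letter amino-acid codes.
#' @param name label.
#' @export
propertyScale <- function(values, name = "custom")
  new("PropertyScale", values = values[AA_ORDER], name = name)

#' Ensemble constraints
#'
#' Defaults encode the admissibility conditions of the constrained random
#' ensemble: stops pinned to the standard positions, all 20 amino acids
#' present, and at least two Asp and two Glu. The relaxed ensemble uses
#' \code{minAsp = minGlu = 1}.
#'
#' @param minAsp,minGlu minimum multiplicities for Asp and Glu.
#' @param requireAll20 require every amino acid at least once.
#' @return an \linkS4class{EnsembleConstraints}.
#' @export
ensembleConstraints <- function(minAsp = 2L, minGlu = 2L, requireAll20 = TRUE)
  new("EnsembleConstraints", stopPositionsFixed = TRUE,
      requireAll20 = requireAll20,
      minAsp = as.integer(minAsp), minGlu = as.integer(minGlu))

# per-symbol minimum multiplicity vector implied by the constraints
.minCountVector <- function(constraints) {
  mc <- if (constraints@requireAll20) rep(1L, 20L) else rep(0L, 20L)
  names(mc) <- AA_ORDER
  mc["D"] <- max(mc["D"], constraints@minAsp)
  mc["E"] <- max(mc["E"], constraints@minGlu)
  mc
}

#' Validate a genetic code against ensemble constraints
#'
#' Violations are data, not errors: the return value is a character vector
#' naming each failed condition, empty when the code is admissible.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param constraints an \linkS4class{EnsembleConstraints}.
#' @return character vector of violation descriptions.
#' @examples
#' validateCode(sgcCode())  # character(0)
#' @export
validateCode <- function(code, constraints = ensembleConstraints()) {
  a <- code@assignments
  out <- character(0)
  stopsAt <- which(a == STOP_SYMBOL)
  if (!identical(stopsAt, sgcStopPositions()))
    out <- c(out, "stop codons must sit exactly at the standard positions (condition 2)")
  counts <- table(factor(a[a != STOP_SYMBOL], levels = AA_ORDER))
  mc <- .minCountVector(constraints)
  missing20 <- names(counts)[counts < 1 & mc >= 1]
  missing20 <- setdiff(missing20, c("D", "E"))
  if (length(missing20))
    out <- c(out, paste0("missing amino acid(s): ",
                         paste(missing20, collapse = ", "), " (condition 3)"))
  if (counts["D"] < mc["D"])
    out <- c(out, sprintf("Asp multiplicity %d < %d (condition 4)",
                          counts["D"], mc["D"]))
  if (counts["E"] < mc["E"])
    out <- c(out, sprintf("Glu multiplicity %d < %d (condition 4)",
                          counts["E"], mc["E"]))
  out
}

# ---- exact ensemble counting -----------------------------------------------

# Exact count of assignments of n positions to symbols with per-symbol
# minimum multiplicities minCount (values 0, 1 or >=2 supported). Symbols
# with minimum >= 2 are handled by explicit multiplicity convolution; the
# remaining surjectivity constraint by inclusion-exclusion. All arithmetic is
# exact (internal bignum).
.countAssignments <- function(n, minCount) {
  hi <- which(minCount >= 2L)
  n1 <- sum(minCount == 1L)
  kFree <- n1 + sum(minCount == 0L)
  powCache <- new.env(parent = emptyenv())
  bigPowC <- function(base, e) {
    key <- paste0("p", base, "_", e)
    if (is.null(powCache[[key]]))
      powCache[[key]] <- .bigPow(.bigFromInt(base), e)
    powCache[[key]]
  }
  # G(r) = #functions from r positions to the kFree remaining symbols that
  # cover all n1 surjectivity-constrained ones (inclusion-exclusion)
  surjCache <- new.env(parent = emptyenv())
  surj <- function(r) {
    key <- paste0("s", r)
    if (!is.null(surjCache[[key]])) return(surjCache[[key]])
    pos <- .bigZero(); neg <- .bigZero()
    for (i in 0:n1) {
      if (kFree - i == 0 && r > 0) next
      term <- .bigMul(.bigBinom(n1, i), bigPowC(kFree - i, r))
      if (i %% 2 == 0) pos <- .bigAdd(pos, term) else neg <- .bigAdd(neg, term)
    }
    surjCache[[key]] <- .bigSub(pos, neg)
    surjCache[[key]]
  }
  if (length(hi) == 0L) return(surj(n))
  # convolve over the explicit multiplicities of the floor->=2 symbols
  rec <- function(idx, nLeft, mult) {
    if (idx > length(hi)) return(.bigMul(mult, surj(nLeft)))
    later <- if (idx < length(hi)) sum(minCount[hi[(idx + 1L):length(hi)]]) else 0L
    tot <- .bigZero()
    m <- minCount[hi[idx]]
    kMax <- nLeft - later - n1
    if (kMax < m) return(tot)
    for (k in m:kMax) {
      tot <- .bigAdd(tot, rec(idx + 1L, nLeft - k,
                              .bigMul(mult, .bigBinom(nLeft, k))))
    }
    tot
  }
  rec(1L, n, .bigFromInt(1))
}

#' Exact size of the constrained random-code ensemble
#'
#' Counts, by explicit multiplicity convolution plus inclusion-exclusion with
#' exact integer arithmetic, the assignments of the 61 sense codons to 20
#' amino acids that satisfy the ensemble constraints (surjectivity and the
#' Asp/Glu multiplicity floors). The default constraints give about 6.1e78
#' codes, i.e. on the order of 1e79.
#'
#' @param constraints an \linkS4class{EnsembleConstraints}; alternatively
#'   supply \code{minCount} directly (per-symbol integer floors) together
#'   with \code{nFree} for toy systems.
#' @param nFree number of freely assignable positions (61 sense codons).
#' @param minCount optional explicit per-symbol minimum multiplicities.
#' @return a list with \code{count} (exact decimal string), \code{log10}
#'   (numeric base-10 logarithm) and \code{countNumeric} (possibly
#'   overflowing to \code{Inf} for display only).
#' @examples
#' countEnsemble(nFree = 4, minCount = c(1L, 1L))$count  # "14"
#' @export
countEnsemble <- function(constraints = ensembleConstraints(), nFree = 61L,
                          minCount = NULL) {
  if (is.null(minCount)) minCount <- unname(.minCountVector(constraints))
  big <- .countAssignments(as.integer(nFree), as.integer(minCount))
  list(count = .bigToString(big), log10 = .bigLog10(big),
       countNumeric = suppressWarnings(as.numeric(.bigToString(big))))
}
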