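# Plain-text serialisation: code batches (CSV), property scales (CSV),
# weight functions and density-of-states (TSV with JSON metadata sidecars).

#' Read and write code batches
#'
#' Batches stream to CSV with one row per code: the cost and the
#' 64-character serialisation in codon-index order.
#'
#' @param x a \linkS4class{CodeSample} with retained codes.
#' @param path output file.
#' @export
writeCodes <- function(x, path) {
  if (!ncol(x@codes)) stop("batch holds no retained codes")
  strs <- vapply(seq_len(ncol(x@codes)),
                 function(i) codeString(.intToCode(x@codes[, i])), "")
  utils::write.csv(data.frame(cost = x@costs, code = strs),
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeCodes
#' @param ensemble label for the reconstructed batch.
#' @return \code{readCodes}: a \linkS4class{CodeSample}.
#' @export
readCodes <- function(path, ensemble = "file") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  codes <- vapply(df$code, function(s) .codeToInt(geneticCode(s)),
                  integer(61), USE.NAMES = FALSE)
  new("CodeSample", codes = codes, costs = df$cost, seed = NA_integer_,
      ensemble = ensemble)
}

#' Code JSON serialisation
#'
#' A single code as a JSON object mapping codon triples to symbols.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param path file path.
#' @export
writeCodeJSON <- function(code, path) {
  obj <- as.list(stats::setNames(code@assignments, .codons))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname writeCodeJSON
#' @export
readCodeJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  geneticCode(unlist(obj)[.codons])
}

#' Read and write property scales
#'
#' Two-column CSV (amino_acid, value).
#'
#' @param scale a \linkS4class{PropertyScale}.
#' @param path file path.
#' @param name label for the reconstructed scale.
#' @export
writePropertyScale <- function(scale, path) {
  utils::write.csv(data.frame(amino_acid = names(scale@values),
                              value = unname(scale@values)),
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname writePropertyScale
#' @export
readPropertyScale <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  propertyScale(stats::setNames(df$value, df$amino_acid), name = name)
}

# shared TSV + JSON-sidecar writer for gridded log curves
.writeGridded <- function(grid, values, valueName, path, meta) {
  df <- data.frame(bin_left = grid@lower + (seq_len(grid@nBins) - 1L) * grid@width,
                   bin_right = grid@lower + seq_len(grid@nBins) * grid@width)
  df[[valueName]] <- values
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write and read multicanonical weights and density-of-states curves
#'
#' TSV with columns bin_left, bin_right and the log value, plus a JSON
#' metadata sidecar (\code{<path>.json}) carrying the grid, seed and run
#' diagnostics.
#'
#' @param weight a \linkS4class{WeightFunction}.
#' @param path file path.
#' @export
writeWeights <- function(weight, path)
  .writeGridded(weight@grid, weight@logw, "log_weight", path,
                c(list(lower = weight@grid@lower, upper = weight@grid@upper,
                       width = weight@grid@width),
                  weight@diagnostics[setdiff(names(weight@diagnostics),
                                             "finalCode")]))

#' @rdname writeWeights
#' @export
readWeights <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  grid <- costGrid(df$bin_left[1], df$bin_right[nrow(df)],
                   df$bin_right[1] - df$bin_left[1])
  new("WeightFunction", grid = grid, logw = df$log_weight,
      visited = rep(TRUE, grid@nBins),
      diagnostics = meta[setdiff(names(meta), c("lower", "upper", "width"))])
}

#' @rdname writeWeights
#' @param dos a \linkS4class{DOSEstimate}.
#' @export
writeDOS <- function(dos, path)
  .writeGridded(dos@grid, dos@logdos, "log_dos", path,
                list(lower = dos@grid@lower, upper = dos@grid@upper,
                     width = dos@grid@width, mode = dos@mode))

#' @rdname writeWeights
#' @export
readDOS <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  grid <- costGrid(df$bin_left[1], df$bin_right[nrow(df)],
                   df$bin_right[1] - df$bin_left[1])
  new("DOSEstimate", grid = grid, logdos = df$log_dos,
      mode = as.character(meta$mode), visited = !is.na(df$log_dos))
}
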