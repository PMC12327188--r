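#' Read a genetic map file
#'
#' Supports the PLINK 4-column layout (chrom, id, cM, bp) and the
#' deCODE-style 3-column layout (chrom, bp, cM).  A header line is
#' detected and skipped automatically.
#'
#' @param path path to a whitespace/tab separated map file.
#' @param format one of \code{"auto"}, \code{"plink"}, \code{"decode"}.
#' @return A \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path, format = c("auto", "plink", "decode")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 3L) stop("genetic map must have at least 3 columns")
  if (format == "auto") format <- if (ncol(dt) >= 4L) "plink" else "decode"
  if (format == "plink") {
    gm <- geneticMap(chrom = dt[[1L]], cM = as.numeric(dt[[3L]]),
                     bp = as.numeric(dt[[4L]]))
  } else {
    gm <- geneticMap(chrom = dt[[1L]], bp = as.numeric(dt[[2L]]),
                     cM = as.numeric(dt[[3L]]))
  }
  gm
}

#' Write a genetic map file
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path output path.
#' @param format \code{"plink"} (chrom, id, cM, bp) or \code{"decode"}
#'   (chrom, bp, cM).
#' @export
writeGeneticMap <- function(map, path, format = c("plink", "decode")) {
  format <- match.arg(format)
  m <- map@map
  if (format == "plink") {
    out <- data.frame(chrom = m$chrom,
                      id = sprintf("%s_%d", m$chrom, as.integer(m$bp)),
                      cM = sprintf("%.6f", m$cM), bp = as.integer(m$bp))
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  } else {
    out <- data.frame(chrom = m$chrom, bp = as.integer(m$bp),
                      cM = sprintf("%.6f", m$cM))
    data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  }
  invisible(path)
}

#' @rdname interpolateCM
#' @export
setGeneric("interpolateCM",
           function(map, chrom, bp) standardGeneric("interpolateCM"))

#' Interpolate genetic position (cM) at physical positions
#'
#' Piecewise-linear interpolation between map points; queries beyond the
#' first or last map point of a chromosome are clamped to the endpoint cM.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom single chromosome name (must be present in the map).
#' @param bp numeric vector of physical positions.
#' @return numeric vector of cM positions.
#' @export
setMethod("interpolateCM", "GeneticMap", function(map, chrom, bp) {
  m <- map@map[map@map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(m) == 0L)
    stop(sprintf("chromosome '%s' not present in genetic map", chrom))
  if (nrow(m) == 1L) return(rep(m$cM, length(bp)))
  approx(m$bp, m$cM, xout = bp, rule = 2L, ties = "ordered")$y
})

#' Interpolate physical position (bp) at genetic positions
#'
#' Inverse of \code{\link{interpolateCM}}.  Flat map intervals (zero
#' recombination) are resolved to the left end; queries beyond the map are
#' clamped.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom single chromosome name.
#' @param cM numeric vector of genetic positions.
#' @return numeric vector of bp positions.
#' @export
interpolateBp <- function(map, chrom, cM) {
  m <- map@map[map@map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(m) == 0L)
    stop(sprintf("chromosome '%s' not present in genetic map", chrom))
  if (nrow(m) == 1L) return(rep(m$bp, length(cM)))
  approx(m$cM, m$bp, xout = cM, rule = 2L, ties = "ordered")$y
}

#' Chromosome cM spans of a genetic map
#'
#' @param map a \linkS4class{GeneticMap}.
#' @return data.frame with chrom, startCM, endCM, lengthCM.
#' @export
chromSpansCM <- function(map) {
  m <- map@map
  chs <- unique(m$chrom)
  out <- do.call(rbind, lapply(chs, function(ch) {
    sub <- m[m$chrom == ch, ]
    data.frame(chrom = ch, startCM = min(sub$cM), endCM = max(sub$cM),
               stringsAsFactors = FALSE)
  }))
  out$lengthCM <- out$endCM - out$startCM
  out
}

#' A uniform-rate genetic map (1 cM per Mb)
#'
#' Convenience constructor for simulated chromosomes with equal mutation
#' and recombination rates per bp, giving a constant cM/Mb relationship.
#'
#' @param chromLengthsCM named or unnamed numeric vector of chromosome
#'   lengths in cM; names default to "1", "2", ...
#' @param cmPerMb map density (default 1 cM/Mb).
#' @return A \linkS4class{GeneticMap} with two map points per chromosome.
#' @export
uniformGeneticMap <- function(chromLengthsCM, cmPerMb = 1) {
  nms <- names(chromLengthsCM)
  if (is.null(nms)) nms <- as.character(seq_along(chromLengthsCM))
  geneticMap(chrom = rep(nms, each = 2L),
             bp = as.vector(vapply(chromLengthsCM, function(l)
               c(1, l / cmPerMb * 1e6), numeric(2L))),
             cM = as.vector(vapply(chromLengthsCM, function(l)
               c(0, l), numeric(2L))))
}
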