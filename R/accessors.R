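#' Construct a GeneticMap
#'
#' @param chrom character vector of chromosome names (one per map point).
#' @param bp integer/numeric physical positions (1-based, strictly
#'   increasing within chromosome).
#' @param cM genetic positions in centimorgans (non-decreasing within
#'   chromosome).
#' @return A \linkS4class{GeneticMap}.
#' @examples
#' gm <- geneticMap(chrom = "1", bp = c(100, 300), cM = c(0, 2))
#' interpolateCM(gm, "1", 200)
#' @export
geneticMap <- function(chrom, bp, cM) {
  df <- data.frame(chrom = as.character(chrom), bp = as.numeric(bp),
                   cM = as.numeric(cM), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  new("GeneticMap", map = df)
}

#' Construct a PhasedHaplotypes object
#'
#' @param alleles integer or raw matrix, 2N x M (row 2*(i-1)+h is haplotype
#'   h of sample i).
#' @param samples character vector of N sample identifiers.
#' @param chrom chromosome of each marker (length M, or length 1 recycled).
#' @param pos physical marker positions (bp).
#' @param map optional \linkS4class{GeneticMap} used to attach cM
#'   coordinates; when NULL, cM is NA.
#' @return A \linkS4class{PhasedHaplotypes}.
#' @export
phasedHaplotypes <- function(alleles, samples, chrom, pos, map = NULL) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  if (!is.raw(alleles)) {
    stopifnot(all(alleles >= 0 & alleles <= 255, na.rm = TRUE))
    storage.mode(alleles) <- "integer"
    alleles <- matrix(as.raw(alleles), nrow = nrow(alleles))
  }
  M <- ncol(alleles)
  chrom <- as.character(rep_len(chrom, M))
  pos <- as.numeric(pos)
  cM <- rep(NA_real_, M)
  if (!is.null(map) && M > 0) {
    for (ch in unique(chrom)) {
      j <- chrom == ch
      cM[j] <- interpolateCM(map, ch, pos[j])
    }
  }
  new("PhasedHaplotypes", samples = as.character(samples), chrom = chrom,
      pos = pos, cM = cM, alleles = alleles)
}

#' Construct a ClusterFieldSet
#'
#' @param clusters integer matrix (positions x 2N) or vector (one
#'   position) of cluster identifiers.
#' @param chrom,bp,cM position coordinates (one per row of
#'   \code{clusters}).
#' @param samples sample identifiers (N).
#' @return A \linkS4class{ClusterFieldSet}.
#' @export
clusterFieldSet <- function(clusters, chrom, bp, cM, samples) {
  if (!is.matrix(clusters)) clusters <- matrix(clusters, nrow = 1L)
  storage.mode(clusters) <- "integer"
  new("ClusterFieldSet", chrom = as.character(rep_len(chrom, nrow(clusters))),
      bp = as.numeric(bp), cM = as.numeric(cM), clusters = clusters,
      samples = as.character(samples))
}

#' @rdname nSamples
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of samples / markers / positions
#'
#' @param x a \linkS4class{PhasedHaplotypes} or \linkS4class{ClusterFieldSet}.
#' @return integer count.
#' @export
setMethod("nSamples", "PhasedHaplotypes", function(x) length(x@samples))

#' @rdname nSamples
#' @export
setMethod("nSamples", "ClusterFieldSet", function(x) length(x@samples))

#' @rdname nSamples
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname nSamples
#' @export
setMethod("nMarkers", "PhasedHaplotypes", function(x) length(x@pos))

#' @rdname nSamples
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname nSamples
#' @export
setMethod("sampleIds", "PhasedHaplotypes", function(x) x@samples)

#' @rdname nSamples
#' @export
setMethod("sampleIds", "ClusterFieldSet", function(x) x@samples)

#' Integer view of the haplotype allele matrix
#'
#' @param x a \linkS4class{PhasedHaplotypes}.
#' @return integer matrix 2N x M of allele indices.
#' @export
alleleMatrix <- function(x) {
  stopifnot(is(x, "PhasedHaplotypes"))
  a <- x@alleles
  matrix(as.integer(a), nrow = nrow(a), dimnames = dimnames(a))
}

#' Marker metadata of a PhasedHaplotypes object
#'
#' @param x a \linkS4class{PhasedHaplotypes}.
#' @return data.frame with chrom, pos (bp) and cM per marker.
#' @export
markerTable <- function(x) {
  stopifnot(is(x, "PhasedHaplotypes"))
  data.frame(chrom = x@chrom, pos = x@pos, cM = x@cM,
             stringsAsFactors = FALSE)
}

#' Cluster-assignment matrix of a ClusterFieldSet
#'
#' @param x a \linkS4class{ClusterFieldSet}.
#' @return integer matrix, positions x 2N.
#' @export
clusterMatrix <- function(x) {
  stopifnot(is(x, "ClusterFieldSet"))
  x@clusters
}

#' Position metadata of a ClusterFieldSet
#'
#' @param x a \linkS4class{ClusterFieldSet}.
#' @return data.frame with chrom, bp and cM per position.
#' @export
fieldPositions <- function(x) {
  stopifnot(is(x, "ClusterFieldSet"))
  data.frame(chrom = x@chrom, bp = x@bp, cM = x@cM, stringsAsFactors = FALSE)
}

#' Subset a ClusterFieldSet by position index
#' @param x a \linkS4class{ClusterFieldSet}
#' @param i,j,...,drop position indices (j, drop ignored)
#' @export
setMethod("[", "ClusterFieldSet", function(x, i, j, ..., drop = FALSE) {
  new("ClusterFieldSet", chrom = x@chrom[i], bp = x@bp[i], cM = x@cM[i],
      clusters = x@clusters[i, , drop = FALSE], samples = x@samples)
})

#' Length of a ClusterFieldSet (number of positions)
#' @param x a \linkS4class{ClusterFieldSet}
#' @export
setMethod("length", "ClusterFieldSet", function(x) length(x@chrom))

#' Construct an OUModel
#'
#' @param alpha decay parameter of the scan-statistic autocorrelation
#'   (per cM, > 0); see \code{\link{estimateAlpha}}.
#' @param spacing test-grid interval in cM.
#' @param chromLengths scanned chromosome lengths in cM.
#' @return An \linkS4class{OUModel}.
#' @export
ouModel <- function(alpha, spacing = 0.1, chromLengths) {
  new("OUModel", alpha = as.numeric(alpha), spacing = as.numeric(spacing),
      chromLengths = as.numeric(chromLengths))
}

#' Accessors for VCFit
#' @param x a \linkS4class{VCFit}
#' @return numeric estimates / log-likelihood.
#' @export
varianceComponents <- function(x) {
  stopifnot(is(x, "VCFit"))
  c(sigmaA2 = x@sigmaA2, sigmaQ2 = x@sigmaQ2, sigmaE2 = x@sigmaE2)
}

#' @rdname varianceComponents
#' @export
restrictedLogLikValue <- function(x) {
  stopifnot(is(x, "VCFit"))
  x@loglik
}

#' @rdname varianceComponents
#' @export
fixedEffects <- function(x) {
  stopifnot(is(x, "VCFit"))
  x@beta
}
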