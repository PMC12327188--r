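#' Clustering parameters for multi-individual IBD detection
#'
#' L is the haplotype length threshold: two haplotypes are directly
#' clustered at a focal position when they share an identical allele
#' sequence over a marker interval of at least L cM that contains the
#' position.  T is the trimming threshold: the shared interval must also
#' reach at least T cM beyond the focal position on each side (an
#' interval running into a chromosome end satisfies the requirement on
#' that side).  T < L/2 is enforced.  Larger L and T impose a more
#' stringent standard and can only refine the partition.
#'
#' @param L haplotype length threshold in cM (> 0).
#' @param T trimming threshold in cM (0 < T <= L/2; the boundary value
#'   T = L/2 is the most stringent usable trimming for a given L).
#' @return list with elements L and T.
#' @export
clusteringParams <- function(L = 2, T = 0.5) {
  if (!(L > 0)) stop("L must be positive")
  if (!(T > 0 && T <= L / 2)) stop("T must satisfy 0 < T <= L/2")
  list(L = L, T = T)
}

#' Multi-individual IBD clustering at a focal position
#'
#' Partitions the 2N haplotypes into IBD clusters at a genomic position:
#' the transitive closure of the pairwise relation "identical allele
#' sequence over a marker interval of total length >= L cM that contains
#' the focal position and reaches >= T cM on each side of it".  A
#' haplotype related to no other is a singleton.  Cluster identifiers are
#' assigned in order of first haplotype index (cosmetic; only the
#' partition is meaningful).
#'
#' @param haps a \linkS4class{PhasedHaplotypes} (single chromosome or the
#'   chromosome selected by \code{chrom}).
#' @param map a \linkS4class{GeneticMap}.
#' @param params from \code{\link{clusteringParams}}.
#' @param focalCM focal genetic position(s) in cM; each must lie within
#'   the chromosome's cM span.
#' @param chrom chromosome to cluster on (defaults to the first).
#' @return A \linkS4class{ClusterFieldSet} with one row per focal position.
#' @export
clusterAtPosition <- function(haps, map, params, focalCM,
                              chrom = haps@chrom[1L]) {
  sel <- haps@chrom == chrom
  if (!any(sel)) stop(sprintf("no markers on chromosome %s", chrom))
  cm <- haps@cM[sel]
  if (anyNA(cm)) cm <- interpolateCM(map, chrom, haps@pos[sel])
  H <- haps@alleles[, sel, drop = FALSE]
  span <- chromSpansCM(map)
  span <- span[span$chrom == chrom, , drop = FALSE]
  if (nrow(span) == 0L) stop(sprintf("chromosome %s not in map", chrom))
  out <- matrix(NA_integer_, length(focalCM), nrow(H))
  bp <- numeric(length(focalCM))
  for (k in seq_along(focalCM)) {
    f <- focalCM[k]
    if (f < span$startCM || f > span$endCM)
      stop(sprintf("focal position %.3f cM outside chromosome %s (%.3f-%.3f cM)",
                   f, chrom, span$startCM, span$endCM))
    focal <- which.min(abs(cm - f))
    out[k, ] <- cluster_at_position_cpp(H, cm, focal - 1L, params$L,
                                        params$T)
    bp[k] <- haps@pos[sel][focal]
  }
  clusterFieldSet(out, chrom = chrom, bp = bp, cM = focalCM,
                  samples = haps@samples)
}

#' Scan a chromosome (or genome) on a regular cM grid
#'
#' Produces one cluster field per grid point from the chromosome start to
#' its end at the given spacing (a chromosome shorter than the spacing
#' yields a single field at its start).
#'
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @param map a \linkS4class{GeneticMap}.
#' @param params from \code{\link{clusteringParams}}.
#' @param spacingCM grid interval in cM (> 0).
#' @param chroms chromosomes to scan (default: all in \code{haps}).
#' @return A \linkS4class{ClusterFieldSet} over all grid positions.
#' @export
clusterFieldScan <- function(haps, map, params, spacingCM = 0.1,
                             chroms = unique(haps@chrom)) {
  if (!(spacingCM > 0)) stop("spacingCM must be positive")
  pieces <- lapply(chroms, function(ch) {
    span <- chromSpansCM(map)
    span <- span[span$chrom == ch, , drop = FALSE]
    grid <- seq(span$startCM, span$endCM, by = spacingCM)
    sel <- haps@chrom == ch
    cm <- haps@cM[sel]
    if (anyNA(cm)) cm <- interpolateCM(map, ch, haps@pos[sel])
    H <- haps@alleles[, sel, drop = FALSE]
    M <- ncol(H)
    # one pass of maximal-run detection serves every grid point: a pair
    # clusters at a position iff one of its maximal identical runs of
    # length >= L covers the focal marker and reaches T on each side
    runs <- detect_segments_cpp(H, cm, seq_len(M) - 1L, params$L / 2,
                                params$L, 1L, FALSE)
    scm <- cm[runs$lIdx + 1L]; ecm <- cm[runs$rIdx + 1L]
    atL <- runs$lIdx == 0L; atR <- runs$rIdx == M - 1L
    n2 <- nrow(H)
    clmat <- matrix(NA_integer_, length(grid), n2)
    bp <- numeric(length(grid))
    for (k in seq_along(grid)) {
      focal <- which.min(abs(cm - grid[k]))
      fm <- cm[focal]
      qual <- runs$lIdx + 1L <= focal & runs$rIdx + 1L >= focal &
        (ecm >= fm + params$T | atR) & (scm <= fm - params$T | atL)
      clmat[k, ] <- partition_from_edges(n2, runs$hap1[qual] + 1L,
                                         runs$hap2[qual] + 1L)
      bp[k] <- haps@pos[sel][focal]
    }
    clusterFieldSet(clmat, chrom = ch, bp = bp, cM = grid,
                    samples = haps@samples)
  })
  combineClusterFields(pieces)
}

#' Concatenate ClusterFieldSets over positions
#' @param pieces list of \linkS4class{ClusterFieldSet}s with identical
#'   samples.
#' @return a single \linkS4class{ClusterFieldSet}.
#' @export
combineClusterFields <- function(pieces) {
  stopifnot(length(pieces) >= 1L)
  samples <- pieces[[1L]]@samples
  for (p in pieces) stopifnot(identical(p@samples, samples))
  clusterFieldSet(do.call(rbind, lapply(pieces, clusterMatrix)),
                  chrom = unlist(lapply(pieces, function(p) p@chrom)),
                  bp = unlist(lapply(pieces, function(p) p@bp)),
                  cM = unlist(lapply(pieces, function(p) p@cM)),
                  samples = samples)
}
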