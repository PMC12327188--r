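#' Allocation matrix of a cluster field
#'
#' The N x K allocation matrix A has entry (i, k) equal to the proportion
#' (0, 1/2 or 1) of individual i's two haplotypes assigned to IBD cluster
#' k at the field's position.  Columns belonging to singleton clusters may
#' be dropped without changing any off-diagonal entry of the local IBD
#' matrix (the diagonal is forced to 1 downstream).
#'
#' @param field a single-position \linkS4class{ClusterFieldSet} (or an
#'   integer vector of 2N cluster identifiers).
#' @param dropSingletons drop columns of clusters containing one haplotype.
#' @return sparse N x K Matrix.
#' @export
allocationMatrix <- function(field, dropSingletons = TRUE) {
  ids <- if (is(field, "ClusterFieldSet")) {
    stopifnot(length(field) == 1L)
    as.vector(field@clusters[1L, ])
  } else as.integer(field)
  n2 <- length(ids)
  if (n2 %% 2L != 0L) stop("cluster field must have 2N entries")
  N <- n2 %/% 2L
  ids <- canonicalClusterIds(ids)
  if (dropSingletons) {
    tab <- tabulate(ids)
    keep <- which(tab > 1L)
    if (length(keep) == 0L)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(N, 0L)))
    sel <- ids %in% keep
    A <- Matrix::sparseMatrix(i = ((seq_len(n2) - 1L) %/% 2L + 1L)[sel],
                              j = match(ids, keep)[sel], x = 0.5,
                              dims = c(N, length(keep)))
  } else {
    A <- Matrix::sparseMatrix(i = (seq_len(n2) - 1L) %/% 2L + 1L,
                              j = ids, x = 0.5,
                              dims = c(N, max(ids)))
  }
  A
}

#' Local IBD matrix at one position
#'
#' Computes the local relatedness matrix Phi = 2 A A' from the allocation
#' matrix A of a cluster field and forces the diagonal to exactly 1: entry
#' (i, j) is then the proportion of alleles shared IBD by individuals i
#' and j at the position.  The construction guarantees symmetry and
#' positive semidefiniteness.  Under the outbred-population model an
#' individual's two haplotypes are never IBD with each other, so
#' off-diagonal entries are 0, 1/2 or 1; should self-IBD occur in the
#' input, the affected entries are capped at 1.
#'
#' @param field a single-position \linkS4class{ClusterFieldSet}, an
#'   integer vector of 2N cluster identifiers, or an allocation matrix.
#' @return sparse symmetric N x N Matrix with unit diagonal.
#' @export
localIBDMatrix <- function(field) {
  A <- if (is(field, "Matrix") || (is.matrix(field) && !is.vector(field)))
    field else allocationMatrix(field, dropSingletons = TRUE)
  if (is(field, "ClusterFieldSet") || is.atomic(field)) {
    ids <- if (is(field, "ClusterFieldSet")) as.vector(field@clusters[1L, ])
           else as.integer(field)
    if (anyNA(ids)) stop("malformed cluster field: unassigned haplotypes")
  }
  N <- nrow(A)
  Phi <- 2 * Matrix::tcrossprod(A)
  Phi <- as(Phi, "generalMatrix")
  Phi@x[Phi@x > 1] <- 1
  Matrix::diag(Phi) <- 1
  Matrix::forceSymmetric(Matrix::drop0(Phi))
}

#' Region IBD matrix by averaging positional matrices
#'
#' The local IBD matrix of a genomic region is the elementwise mean of
#' local IBD matrices computed at selected positions within the region
#' (for 0.05 cM power-study regions: the start and end positions).  Means
#' of symmetric PSD matrices with unit diagonal retain all three
#' properties.
#'
#' @param fields a \linkS4class{ClusterFieldSet} with >= 1 position, or a
#'   list of local IBD matrices.
#' @return sparse symmetric N x N Matrix.
#' @export
regionIBDMatrix <- function(fields) {
  mats <- if (is(fields, "ClusterFieldSet")) {
    if (length(fields) < 1L) stop("need at least one position")
    lapply(seq_len(length(fields)), function(i) localIBDMatrix(fields[i]))
  } else fields
  Ns <- vapply(mats, nrow, integer(1L))
  if (length(unique(Ns)) != 1L)
    stop("inconsistent sample size across positional matrices")
  out <- Reduce(`+`, mats) / length(mats)
  Matrix::forceSymmetric(Matrix::drop0(out))
}

#' Global IBD matrix from kinship coefficients
#'
#' Psi has unit diagonal and off-diagonal entries equal to twice the
#' kinship coefficient, with coefficients below the sparsity threshold
#' (default 0.044, relationships beyond third degree) set to zero.
#'
#' @param kin data.frame with sample1, sample2, kinship (in [0, 0.5]).
#' @param samples character vector giving sample order (defines N).
#' @param threshold kinship sparsity cutoff.
#' @return sparse symmetric N x N Matrix.
#' @export
globalIBDMatrix <- function(kin, samples, threshold = 0.044) {
  validateKinship(kin)
  N <- length(samples)
  keep <- kin$kinship >= threshold
  i <- match(kin$sample1[keep], samples)
  j <- match(kin$sample2[keep], samples)
  if (anyNA(i) || anyNA(j))
    stop("kinship table contains samples absent from 'samples'")
  dup <- duplicated(paste(pmin(i, j), pmax(i, j)))
  i2 <- pmin(i, j)[!dup]; j2 <- pmax(i, j)[!dup]
  x <- 2 * kin$kinship[keep][!dup]
  Psi <- Matrix::sparseMatrix(i = i2, j = j2, x = x, dims = c(N, N),
                              symmetric = TRUE)
  Matrix::diag(Psi) <- 1
  Matrix::forceSymmetric(Psi)
}

# interval utilities on a single chromosome: merge overlapping [s, e]
mergeIntervalsCM <- function(s, e) {
  if (length(s) == 0L) return(cbind(s = numeric(0), e = numeric(0)))
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1L]; me <- e[1L]
  outS <- numeric(0); outE <- numeric(0)
  for (k in seq_along(s)[-1L]) {
    if (s[k] <= me) me <- max(me, e[k])
    else { outS <- c(outS, ms); outE <- c(outE, me); ms <- s[k]; me <- e[k] }
  }
  cbind(s = c(outS, ms), e = c(outE, me))
}

intersectIntervalsCM <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(cbind(s = numeric(0), e = numeric(0)))
  outS <- numeric(0); outE <- numeric(0)
  for (k in seq_len(nrow(a))) {
    lo <- pmax(a[k, 1L], b[, 1L]); hi <- pmin(a[k, 2L], b[, 2L])
    sel <- lo < hi
    outS <- c(outS, lo[sel]); outE <- c(outE, hi[sel])
  }
  cbind(s = outS, e = outE)
}

unionIntervalsCM <- function(a, b) {
  mergeIntervalsCM(c(a[, 1L], b[, 1L]), c(a[, 2L], b[, 2L]))
}

intervalLength <- function(a) if (nrow(a) == 0L) 0 else sum(a[, 2L] - a[, 1L])

#' Kinship coefficients from pairwise IBD segments
#'
#' For each sample pair, segments of the four haplotype-pair combinations
#' are merged per chromosome (in cM space); positions where both of one
#' individual's haplotypes are IBD with both of the other's (in either
#' pairing) count as IBD2, positions with any remaining sharing as IBD1.
#' With p1 and p2 the genome proportions in each state, the kinship
#' coefficient is p1/4 + p2/2.
#'
#' @param segments data.frame as from \code{\link{readIbdSegments}} (cM
#'   coordinates are derived from the map).
#' @param map a \linkS4class{GeneticMap} defining the genome extent.
#' @return data.frame sample1, sample2, kinship (pairs with sharing only).
#' @export
kinshipFromSegments <- function(segments, map) {
  spans <- chromSpansCM(map)
  G <- sum(spans$lengthCM)
  if (G <= 0) stop("genetic map spans zero length")
  if (nrow(segments) == 0L)
    return(data.frame(sample1 = character(0), sample2 = character(0),
                      kinship = numeric(0), stringsAsFactors = FALSE))
  segs <- segments
  segs$scm <- NA_real_; segs$ecm <- NA_real_
  for (ch in unique(segs$chrom)) {
    j <- segs$chrom == ch
    segs$scm[j] <- interpolateCM(map, ch, segs$start_bp[j])
    segs$ecm[j] <- interpolateCM(map, ch, segs$end_bp[j])
  }
  # orient pairs canonically
  flip <- segs$sample1 > segs$sample2
  tmp <- segs$sample1[flip]; segs$sample1[flip] <- segs$sample2[flip]
  segs$sample2[flip] <- tmp
  tmph <- segs$hap1[flip]; segs$hap1[flip] <- segs$hap2[flip]
  segs$hap2[flip] <- tmph
  pairKey <- paste(segs$sample1, segs$sample2, sep = "\r")
  out <- lapply(split(seq_len(nrow(segs)), pairKey), function(rows) {
    sub <- segs[rows, , drop = FALSE]
    ibd1len <- 0; ibd2len <- 0
    for (ch in unique(sub$chrom)) {
      sc <- sub[sub$chrom == ch, , drop = FALSE]
      combo <- function(h1, h2) {
        sel <- sc$hap1 == h1 & sc$hap2 == h2
        mergeIntervalsCM(sc$scm[sel], sc$ecm[sel])
      }
      u11 <- combo(1L, 1L); u12 <- combo(1L, 2L)
      u21 <- combo(2L, 1L); u22 <- combo(2L, 2L)
      ibd2 <- unionIntervalsCM(intersectIntervalsCM(u11, u22),
                               intersectIntervalsCM(u12, u21))
      ibd2 <- mergeIntervalsCM(ibd2[, 1L], ibd2[, 2L])
      anyIbd <- mergeIntervalsCM(c(u11[, 1L], u12[, 1L], u21[, 1L], u22[, 1L]),
                                 c(u11[, 2L], u12[, 2L], u21[, 2L], u22[, 2L]))
      ibd2len <- ibd2len + intervalLength(ibd2)
      ibd1len <- ibd1len + intervalLength(anyIbd) - intervalLength(ibd2)
    }
    data.frame(sample1 = sub$sample1[1L], sample2 = sub$sample2[1L],
               kinship = (ibd1len / G) / 4 + (ibd2len / G) / 2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Block partition of the combined sparsity graph
#'
#' Connected components of the graph whose edges are the nonzero
#' off-diagonal entries of Psi and Phi.  Permuting individuals by blocks
#' renders the variance matrix block-diagonal, so restricted-likelihood
#' evaluation factorizes over blocks.
#'
#' @param psi,phi sparse symmetric N x N Matrices (either may be NULL).
#' @return list of integer index vectors (disjoint, covering 1..N).
#' @export
blockPartition <- function(psi, phi = NULL) {
  N <- nrow(if (is.null(psi)) phi else psi)
  if (!is.null(psi) && !is.null(phi) && nrow(phi) != N)
    stop("psi and phi have different sizes")
  edges <- function(m) {
    if (is.null(m)) return(NULL)
    tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
    sel <- tm@i != tm@j & tm@x != 0
    cbind(tm@i[sel] + 1L, tm@j[sel] + 1L)
  }
  E <- rbind(edges(psi), edges(phi))
  if (is.null(E)) E <- matrix(integer(0), 0L, 2L)
  roots <- partition_from_edges(N, E[, 1L], E[, 2L])
  unname(split(seq_len(N), roots))
}

# Build the block structure consumed by the C++ REML routines:
# singleton individuals are aggregated, non-trivial blocks carry dense
# copies of their Psi / Phi submatrices.
remlPrepare <- function(psi, phi, partition = NULL) {
  N <- nrow(psi)
  if (is.null(phi)) phi <- Matrix::Diagonal(N)
  if (is.null(partition)) partition <- blockPartition(psi, phi)
  sizes <- lengths(partition)
  singles <- unlist(partition[sizes == 1L], use.names = FALSE)
  if (is.null(singles)) singles <- integer(0)
  blocks <- lapply(partition[sizes > 1L], function(idx) {
    list(idx = as.integer(idx),
         Psi = as.matrix(psi[idx, idx, drop = FALSE]),
         Phi = as.matrix(phi[idx, idx, drop = FALSE]))
  })
  names(blocks) <- NULL
  list(singles = as.integer(singles), blocks = blocks, N = N)
}
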