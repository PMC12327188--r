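#' Read / write multi-individual IBD cluster fields
#'
#' The internal cluster-field format is a plain TSV with a header row:
#' columns \code{chrom}, \code{bp}, \code{cM}, then 2N integer cluster
#' identifiers in sample order (haplotype 1 then haplotype 2 per sample),
#' one row per genomic position.  cM values are written with 6 decimal
#' digits.  \code{readIbdClusterOutput} accepts the same layout without
#' the three coordinate headers, i.e. converter input from an external
#' clustering tool can be adapted by naming its coordinate columns.
#'
#' @param path file path.
#' @param samples optional sample identifiers; defaults to "S1", ... as
#'   inferred from the column count.
#' @return \code{readClusterFields}: a \linkS4class{ClusterFieldSet}.
#' @export
readClusterFields <- function(path, samples = NULL) {
  nf <- count.fields(path, sep = "\t")
  if (length(nf) == 0L) stop("empty cluster-field file")
  if (any(nf != nf[1L]))
    stop(sprintf("cluster-field row with wrong number of identifiers at line %d (expected %d fields, found %d)",
                 which(nf != nf[1L])[1L], nf[1L], nf[nf != nf[1L]][1L]))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 5L || !all(c("chrom", "bp", "cM") %in% names(dt)[1:3]))
    stop("cluster-field file must start with columns chrom, bp, cM")
  n2 <- ncol(dt) - 3L
  if (n2 %% 2L != 0L)
    stop("cluster-field file must have an even number of haplotype columns")
  if (is.null(samples)) {
    samples <- unique(sub("_[12]$", "", names(dt)[-(1:3)]))
    if (length(samples) != n2 / 2L)
      samples <- sprintf("S%d", seq_len(n2 / 2L))
  }
  if (2L * length(samples) != n2)
    stop(sprintf("file has %d haplotype columns but %d samples were given",
                 n2, length(samples)))
  cl <- as.matrix(dt[, -(1:3), drop = FALSE])
  dimnames(cl) <- NULL
  clusterFieldSet(cl, chrom = as.character(dt$chrom), bp = dt$bp, cM = dt$cM,
                  samples = samples)
}

#' @param fields a \linkS4class{ClusterFieldSet} to write.
#' @rdname readClusterFields
#' @export
writeClusterFields <- function(fields, path) {
  cl <- fields@clusters
  hapNames <- as.vector(rbind(paste0(fields@samples, "_1"),
                              paste0(fields@samples, "_2")))
  df <- data.frame(chrom = fields@chrom, bp = fields@bp,
                   cM = sprintf("%.6f", fields@cM), stringsAsFactors = FALSE)
  cldf <- as.data.frame(cl)
  names(cldf) <- hapNames
  data.table::fwrite(cbind(df, cldf), path, sep = "\t")
  invisible(path)
}

#' Compare cluster fields as partitions
#'
#' Cluster identifiers are arbitrary labels; two assignments are the same
#' clustering when they induce the same partition of the 2N haplotypes.
#'
#' @param a,b integer vectors of cluster identifiers (equal length), or
#'   single-position \linkS4class{ClusterFieldSet}s.
#' @return logical.
#' @export
sameClustering <- function(a, b) {
  if (is(a, "ClusterFieldSet")) a <- as.vector(a@clusters)
  if (is(b, "ClusterFieldSet")) b <- as.vector(b@clusters)
  if (length(a) != length(b)) return(FALSE)
  all(canonicalClusterIds(a) == canonicalClusterIds(b))
}

#' Canonical relabeling of cluster identifiers
#'
#' Relabels so that identifiers are assigned in order of first occurrence
#' (first haplotype index), starting at 1.  Two assignments induce the
#' same partition iff their canonical relabelings are identical.
#'
#' @param ids integer vector of cluster identifiers.
#' @return integer vector of canonical identifiers.
#' @export
canonicalClusterIds <- function(ids) {
  match(ids, unique(ids))
}
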