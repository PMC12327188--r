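#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric tcrossprod crossprod
#' @importFrom stats approx rnorm runif var pchisq pt quantile cor lm coef sd
#' @importFrom utils count.fields head tail
#' @useDynLib ibdscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GeneticMap: piecewise-linear bp/cM correspondence
#'
#' Holds, per chromosome, sorted arrays of physical positions (bp, 1-based)
#' and genetic positions (cM).  Interpolation between map points is
#' piecewise linear; queries beyond the map ends are clamped to the
#' endpoint cM value so that no position receives a negative or
#' extrapolated genetic coordinate.
#'
#' @slot map data.frame with columns \code{chrom} (character),
#'   \code{bp} (numeric, strictly increasing within chromosome) and
#'   \code{cM} (numeric, non-decreasing within chromosome).
#' @exportClass GeneticMap
setClass("GeneticMap", representation(map = "data.frame"))

setValidity("GeneticMap", function(object) {
  m <- object@map
  if (!all(c("chrom", "bp", "cM") %in% names(m)))
    return("map must have columns chrom, bp, cM")
  if (nrow(m) == 0L) return("empty genetic map")
  if (any(m$bp < 1)) return("bp positions must be >= 1")
  if (any(m$cM < 0)) return("cM positions must be >= 0")
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (is.unsorted(sub$bp, strictly = TRUE))
      return(sprintf("bp not strictly increasing on chromosome %s", ch))
    if (is.unsorted(sub$cM))
      return(sprintf("cM not non-decreasing on chromosome %s", ch))
  }
  TRUE
})

#' PhasedHaplotypes: complete phased allele matrix
#'
#' Stores a 2N x M haplotype allele matrix over allele indices for N
#' samples and M markers.  Haplotype h (h in 1,2) of sample i is row
#' 2*(i-1)+h.  Alleles are stored as a raw matrix to keep large simulated
#' chromosomes compact; use \code{\link{alleleMatrix}} for an integer view.
#'
#' @slot samples character vector of N sample identifiers.
#' @slot chrom character vector of M marker chromosomes.
#' @slot pos numeric vector of M marker positions (bp, 1-based).
#' @slot cM numeric vector of M marker genetic positions (may be NA when no
#'   map has been attached).
#' @slot alleles raw matrix, 2N rows x M columns.
#' @exportClass PhasedHaplotypes
setClass("PhasedHaplotypes",
  representation(samples = "character", chrom = "character",
                 pos = "numeric", cM = "numeric", alleles = "matrix"))

setValidity("PhasedHaplotypes", function(object) {
  M <- length(object@pos)
  if (length(object@chrom) != M || length(object@cM) != M)
    return("chrom, pos and cM must have equal length")
  if (!is.raw(object@alleles)) return("alleles must be a raw matrix")
  if (ncol(object@alleles) != M)
    return("alleles must have one column per marker")
  if (nrow(object@alleles) != 2L * length(object@samples))
    return("alleles must have two rows per sample")
  for (ch in unique(object@chrom)) {
    if (is.unsorted(object@pos[object@chrom == ch]))
      return(sprintf("markers not sorted by position on chromosome %s", ch))
  }
  TRUE
})

#' ClusterFieldSet: per-position multi-individual IBD cluster assignments
#'
#' One row per genomic position; at each position every one of the 2N
#' haplotypes carries a small non-negative integer cluster identifier.
#' Haplotypes with equal identifier at a position are mutually IBD there.
#' Identifiers are arbitrary labels: only the induced partition is
#' meaningful, and equality of fields is defined as partition equality
#' (see \code{\link{sameClustering}}).
#'
#' @slot chrom character vector, one per position.
#' @slot bp numeric vector of physical positions.
#' @slot cM numeric vector of genetic positions.
#' @slot clusters integer matrix, positions x 2N; column 2*(i-1)+h is
#'   haplotype h of sample i.
#' @slot samples character vector of N sample identifiers.
#' @exportClass ClusterFieldSet
setClass("ClusterFieldSet",
  representation(chrom = "character", bp = "numeric", cM = "numeric",
                 clusters = "matrix", samples = "character"))

setValidity("ClusterFieldSet", function(object) {
  P <- length(object@chrom)
  if (length(object@bp) != P || length(object@cM) != P)
    return("chrom, bp and cM must have equal length")
  if (nrow(object@clusters) != P)
    return("clusters must have one row per position")
  if (ncol(object@clusters) != 2L * length(object@samples))
    return("clusters must have 2 columns per sample")
  if (P > 0 && (anyNA(object@clusters) || any(object@clusters < 0L)))
    return("cluster identifiers must be non-negative integers")
  TRUE
})

#' VCFit: a restricted-maximum-likelihood variance-component fit
#'
#' @slot beta numeric vector of GLS fixed-effect estimates at the optimum.
#' @slot sigmaA2 genome-wide additive variance (>= 0).
#' @slot sigmaQ2 location-specific IBD variance (>= 0; fixed at 0 under
#'   the null).
#' @slot sigmaE2 residual variance (> 0).
#' @slot loglik restricted log-likelihood at the optimum (constant
#'   \code{-((N-p)/2) log(2 pi)} included, identical under both
#'   hypotheses so it cancels in the test statistic).
#' @slot converged logical convergence flag.
#' @slot iterations total optimizer iterations across starts.
#' @exportClass VCFit
setClass("VCFit",
  representation(beta = "numeric", sigmaA2 = "numeric", sigmaQ2 = "numeric",
                 sigmaE2 = "numeric", loglik = "numeric",
                 converged = "logical", iterations = "integer"))

#' OUModel: modified Ornstein-Uhlenbeck scan-statistic model
#'
#' Describes the null correlation structure of LOD-score statistics along a
#' scanned genome: standardized statistics form an OU process with
#' autocorrelation \code{exp(-alpha * d)} at distance d cM, restarting
#' independently on each chromosome; observed statistics are the squared,
#' positively truncated process.
#'
#' @slot alpha decay parameter (per cM, > 0).
#' @slot spacing test-grid interval in cM.
#' @slot chromLengths numeric vector of scanned chromosome lengths (cM).
#' @exportClass OUModel
setClass("OUModel",
  representation(alpha = "numeric", spacing = "numeric",
                 chromLengths = "numeric"))

setValidity("OUModel", function(object) {
  if (length(object@alpha) != 1L || object@alpha <= 0)
    return("alpha must be a single positive number")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@chromLengths) < 1L || any(object@chromLengths < 0))
    return("chromLengths must be non-negative")
  TRUE
})

setMethod("show", "GeneticMap", function(object) {
  m <- object@map
  cat("GeneticMap:", length(unique(m$chrom)), "chromosome(s),",
      nrow(m), "map points\n")
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    cat(sprintf("  %s: %d points, %.0f-%.0f bp, %.3f-%.3f cM\n", ch,
                nrow(sub), min(sub$bp), max(sub$bp), min(sub$cM), max(sub$cM)))
  }
  invisible(object)
})

setMethod("show", "PhasedHaplotypes", function(object) {
  cat("PhasedHaplotypes:", length(object@samples), "samples,",
      length(object@pos), "markers on",
      length(unique(object@chrom)), "chromosome(s)\n")
  invisible(object)
})

setMethod("show", "ClusterFieldSet", function(object) {
  cat("ClusterFieldSet:", length(object@chrom), "position(s),",
      length(object@samples), "samples\n")
  if (length(object@chrom) > 0) {
    k <- apply(object@clusters, 1L, function(z) length(unique(z)))
    cat("  clusters per position:", paste(range(k), collapse = "-"), "\n")
  }
  invisible(object)
})

setMethod("show", "VCFit", function(object) {
  cat(sprintf(
    "VCFit: sigma_a2=%.4g sigma_Q2=%.4g sigma_e2=%.4g logLik=%.4f %s\n",
    object@sigmaA2, object@sigmaQ2, object@sigmaE2, object@loglik,
    if (object@converged) "(converged)" else "(NOT converged)"))
  invisible(object)
})

setMethod("show", "OUModel", function(object) {
  cat(sprintf("OUModel: alpha=%.4g /cM, spacing=%.3g cM, genome=%.1f cM (%d chromosome(s))\n",
              object@alpha, object@spacing, sum(object@chromLengths),
              length(object@chromLengths)))
  invisible(object)
})
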