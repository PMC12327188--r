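#' Read a pairwise IBD segment table (hap-ibd style)
#'
#' Expects tab-separated columns: sample1, haplotype1 (1/2), sample2,
#' haplotype2, chromosome, start_bp, end_bp and optionally length_cM.
#' When the length column is absent it is recomputed from the supplied
#' genetic map.  A header line is detected and skipped.
#'
#' @param path file path (possibly empty).
#' @param map optional \linkS4class{GeneticMap}, required when the file
#'   has no length column.
#' @return data.frame with columns sample1, hap1, sample2, hap2, chrom,
#'   start_bp, end_bp, length_cM.
#' @export
readIbdSegments <- function(path, map = NULL) {
  empty <- data.frame(sample1 = character(0), hap1 = integer(0),
                      sample2 = character(0), hap2 = integer(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), length_cM = numeric(0),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 7L) stop("IBD segment file must have >= 7 columns")
  out <- data.frame(sample1 = as.character(dt[[1L]]),
                    hap1 = as.integer(dt[[2L]]),
                    sample2 = as.character(dt[[3L]]),
                    hap2 = as.integer(dt[[4L]]),
                    chrom = as.character(dt[[5L]]),
                    start_bp = as.numeric(dt[[6L]]),
                    end_bp = as.numeric(dt[[7L]]),
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 8L) {
    out$length_cM <- as.numeric(dt[[8L]])
  } else {
    if (is.null(map))
      stop("segment file has no length column and no map was supplied")
    out$length_cM <- NA_real_
  }
  if (!is.null(map)) {
    recompute <- is.na(out$length_cM)
    if (any(recompute)) {
      for (ch in unique(out$chrom[recompute])) {
        j <- recompute & out$chrom == ch
        out$length_cM[j] <- interpolateCM(map, ch, out$end_bp[j]) -
          interpolateCM(map, ch, out$start_bp[j])
      }
    }
  }
  if (any(out$start_bp >= out$end_bp))
    stop("IBD segment with non-positive physical length")
  if (any(out$length_cM < 0, na.rm = TRUE))
    stop("IBD segment with negative genetic length")
  out
}

#' Write a pairwise IBD segment table
#' @param segments data.frame as returned by \code{\link{readIbdSegments}}.
#' @param path output path.
#' @export
writeIbdSegments <- function(segments, path) {
  data.table::fwrite(segments, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a kinship coefficient table (IBDkin style)
#'
#' Expects tab-separated columns with the first two columns holding the
#' sample pair and a \code{kinship} column (or third column) holding the
#' kinship coefficient in [0, 0.5].  Self-pairs are rejected.
#'
#' @param path file path.
#' @return data.frame with columns sample1, sample2, kinship.
#' @export
readKinship <- function(path) {
  empty <- data.frame(sample1 = character(0), sample2 = character(0),
                      kinship = numeric(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE)
  if (nrow(dt) == 0L) return(empty)
  kcol <- if ("kinship" %in% tolower(names(dt)))
    which(tolower(names(dt)) == "kinship")[1L] else 3L
  out <- data.frame(sample1 = as.character(dt[[1L]]),
                    sample2 = as.character(dt[[2L]]),
                    kinship = as.numeric(dt[[kcol]]),
                    stringsAsFactors = FALSE)
  validateKinship(out)
  out
}

validateKinship <- function(kin) {
  if (any(kin$kinship < 0 | kin$kinship > 0.5))
    stop("kinship coefficients must lie in [0, 0.5]")
  if (any(kin$sample1 == kin$sample2))
    stop("kinship table must not contain self-pairs")
  invisible(kin)
}

#' Write a kinship table
#' @param kin data.frame with sample1, sample2, kinship.
#' @param path output path.
#' @export
writeKinship <- function(kin, path) {
  data.table::fwrite(kin, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
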