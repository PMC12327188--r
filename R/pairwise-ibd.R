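#' Parameters for the pairwise IBD segment detector
#'
#' Seed-and-extend detection of identical-by-state runs between haplotype
#' pairs, evaluated on the marker set passing the minor-allele-count
#' filter.  Two presets mirror common choices: \code{"sequence"} (seed
#' 0.5 cM, extension 0.2 cM, output >= 2 cM, minor allele count >= 100)
#' and \code{"array"} (seed 1 cM, extension 0.1 cM, >= 50 markers in a
#' seed, output >= 3 cM).
#'
#' @param preset \code{"sequence"}, \code{"array"}, or NULL for explicit
#'   values.
#' @param minSeedCM minimum seed length (cM).
#' @param minExtendCM minimum extension length (cM); retained for
#'   interface completeness — in the error-free detector every maximal
#'   identical run is recovered whole, so extension granularity does not
#'   affect output.
#' @param minOutputCM minimum reported segment length (cM).
#' @param minMinorAlleleCount markers with minor allele count below this
#'   are ignored.
#' @param minSeedMarkers minimum number of (filtered) markers in a
#'   reported segment.
#' @return parameter list.
#' @export
pairwiseDetectorParams <- function(preset = NULL, minSeedCM = 0.5,
                                   minExtendCM = 0.2, minOutputCM = 2,
                                   minMinorAlleleCount = 100,
                                   minSeedMarkers = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sequence", "array"))
    if (preset == "sequence") {
      minSeedCM <- 0.5; minExtendCM <- 0.2; minOutputCM <- 2
      minMinorAlleleCount <- 100; minSeedMarkers <- 1L
    } else {
      minSeedCM <- 1; minExtendCM <- 0.1; minOutputCM <- 3
      minMinorAlleleCount <- 1; minSeedMarkers <- 50L
    }
  }
  stopifnot(minSeedCM > 0, minExtendCM > 0, minOutputCM > 0,
            minMinorAlleleCount >= 0, minSeedMarkers >= 1L)
  list(minSeedCM = minSeedCM, minExtendCM = minExtendCM,
       minOutputCM = minOutputCM,
       minMinorAlleleCount = minMinorAlleleCount,
       minSeedMarkers = as.integer(minSeedMarkers))
}

#' Detect pairwise IBD segments between all haplotype pairs
#'
#' For every pair of haplotypes from different individuals, finds maximal
#' identical-allele-sequence runs over the markers passing the
#' minor-allele-count filter, and reports runs of total length at least
#' \code{minOutputCM} containing at least \code{minSeedMarkers} markers.
#' Runs are located by hashing grid-aligned windows of half the minimum
#' output length (every qualifying run fully covers at least one such
#' window) and extending matches outward, so runtime scales with the
#' amount of sharing rather than the number of pairs times markers.
#'
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @param map a \linkS4class{GeneticMap}.
#' @param params from \code{\link{pairwiseDetectorParams}}.
#' @return data.frame: sample1, hap1, sample2, hap2, chrom, start_bp,
#'   end_bp, length_cM.
#' @export
detectPairwiseSegments <- function(haps, map,
                                   params = pairwiseDetectorParams("sequence")) {
  out <- list()
  for (ch in unique(haps@chrom)) {
    sel <- haps@chrom == ch
    cm <- haps@cM[sel]
    if (anyNA(cm)) cm <- interpolateCM(map, ch, haps@pos[sel])
    H <- haps@alleles[, sel, drop = FALSE]
    af <- alt_freq_cpp(H)
    mac <- pmin(af, 1 - af) * nrow(H)
    keep <- which(mac >= params$minMinorAlleleCount) - 1L
    res <- detect_segments_cpp(H, cm, keep, params$minOutputCM / 2,
                               params$minOutputCM, params$minSeedMarkers)
    if (length(res$hap1) == 0L) next
    pos <- haps@pos[sel]
    li <- keep[res$lIdx + 1L] + 1L
    ri <- keep[res$rIdx + 1L] + 1L
    h1 <- res$hap1 + 1L; h2 <- res$hap2 + 1L
    out[[ch]] <- data.frame(
      sample1 = haps@samples[(h1 - 1L) %/% 2L + 1L],
      hap1 = (h1 - 1L) %% 2L + 1L,
      sample2 = haps@samples[(h2 - 1L) %/% 2L + 1L],
      hap2 = (h2 - 1L) %% 2L + 1L,
      chrom = ch, start_bp = pos[li], end_bp = pos[ri],
      length_cM = cm[ri] - cm[li], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(sample1 = character(0), hap1 = integer(0),
                      sample2 = character(0), hap2 = integer(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), length_cM = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
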