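#' Read phased genotypes from a VCF file
#'
#' All GT fields must be phased ("|" separator) and complete; an unphased
#' or missing genotype is a hard error naming the offending record.
#' Multi-allelic records are passed through with allele indices preserved.
#'
#' @param path path to a VCF (v4.x) file, plain text or gzipped.
#' @param region optional region filter \code{"chrom"} or
#'   \code{"chrom:start-end"} (1-based inclusive bp).
#' @param map optional \linkS4class{GeneticMap} to attach cM coordinates.
#' @return A \linkS4class{PhasedHaplotypes}.
#' @export
readPhasedVcf <- function(path, region = NULL, map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) # single-record VCFs collapse to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype columns")
  samples <- colnames(gt)[-1L]
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    rg <- parseRegion(region)
    keep <- chrom == rg$chrom
    if (!is.na(rg$start)) keep <- keep & pos >= rg$start & pos <= rg$end
  }
  N <- length(samples)
  if (!any(keep)) {
    return(phasedHaplotypes(matrix(raw(0), nrow = 2L * N, ncol = 0L),
                            samples = samples, chrom = character(0),
                            pos = numeric(0), map = map))
  }
  chrom <- chrom[keep]; pos <- pos[keep]
  gtfmt <- gt[keep, 1L, drop = TRUE]
  gsub_gt <- gt[keep, -1L, drop = FALSE]
  # strip FORMAT fields beyond GT
  gtIdx <- vapply(strsplit(gtfmt, ":", fixed = TRUE),
                  function(f) match("GT", f), integer(1L))
  if (anyNA(gtIdx)) stop("VCF FORMAT without GT field")
  M <- length(pos)
  H <- matrix(raw(0), nrow = 2L * N, ncol = M)
  for (j in seq_len(M)) {
    cells <- gsub_gt[j, ]
    if (gtIdx[j] != 1L || any(grepl(":", cells, fixed = TRUE)))
      cells <- vapply(strsplit(cells, ":", fixed = TRUE), `[[`, character(1L),
                      gtIdx[j])
    bad <- is.na(cells) | cells == "." | grepl("\\.", cells)
    if (any(bad))
      stop(sprintf("missing genotype at %s:%d (sample %s)", chrom[j],
                   as.integer(pos[j]), samples[which(bad)[1L]]))
    unph <- grepl("/", cells, fixed = TRUE)
    if (any(unph))
      stop(sprintf("unphased genotype at %s:%d (sample %s)", chrom[j],
                   as.integer(pos[j]), samples[which(unph)[1L]]))
    parts <- strsplit(cells, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop(sprintf("non-diploid genotype at %s:%d", chrom[j],
                   as.integer(pos[j])))
    al <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(al))
      stop(sprintf("malformed genotype at %s:%d", chrom[j],
                   as.integer(pos[j])))
    H[, j] <- as.raw(al)
  }
  phasedHaplotypes(H, samples = samples, chrom = chrom, pos = pos, map = map)
}

parseRegion <- function(region) {
  if (is.list(region)) {
    return(list(chrom = as.character(region$chrom),
                start = if (is.null(region$start)) NA_real_ else region$start,
                end = if (is.null(region$end)) NA_real_ else region$end))
  }
  if (!grepl(":", region, fixed = TRUE))
    return(list(chrom = region, start = NA_real_, end = NA_real_))
  chrom <- sub(":.*", "", region)
  rng <- sub(".*:", "", region)
  se <- as.numeric(strsplit(rng, "-", fixed = TRUE)[[1L]])
  list(chrom = chrom, start = se[1L], end = if (length(se) > 1L) se[2L]
       else se[1L])
}

#' Write phased genotypes to a VCF file
#'
#' Emits a minimal VCF v4.2 with biallelic-style REF/ALT placeholders
#' (A/C for allele indices 0/1; higher indices become additional ALT
#' alleles) and phased GT fields.
#'
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @param path output path (plain text).
#' @export
writePhasedVcf <- function(haps, path) {
  N <- nSamples(haps); M <- nMarkers(haps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", haps@samples), collapse = "\t")), con)
  if (M == 0L) return(invisible(path))
  A <- alleleMatrix(haps)
  letters4 <- c("A", "C", "G", "T")
  oddIdx <- seq(1L, 2L * N, by = 2L)
  for (j in seq_len(M)) {
    al <- A[, j]
    nAl <- max(al) + 1L
    alt <- if (nAl >= 2L) paste(letters4[2:min(nAl, 4L)], collapse = ",")
           else "C"
    g <- paste(al[oddIdx], al[oddIdx + 1L], sep = "|")
    writeLines(paste(c(haps@chrom[j], as.integer(haps@pos[j]),
                       sprintf("m%d", j), "A", alt, ".", "PASS", ".", "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}
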