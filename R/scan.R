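#' Prepare reusable structures for genome scanning
#'
#' Deduplicates the cluster fields by partition (IBD state changes slowly
#' along the genome, so consecutive grid positions often share one
#' partition and hence one local IBD matrix), builds the local IBD matrix
#' and block structure for each unique partition, and the null-model
#' block structure.  The returned object is reused across phenotype
#' replicates, which is what makes replicate-heavy experiments feasible.
#'
#' @param fields a \linkS4class{ClusterFieldSet} at the test positions.
#' @param psi sparse symmetric global IBD matrix.
#' @param covariates optional fixed-effect covariate matrix.
#' @return an opaque list consumed by \code{\link{genomeScan}} and the
#'   experiment drivers.
#' @export
prepareScan <- function(fields, psi, covariates = NULL) {
  N <- length(fields@samples)
  if (nrow(psi) != N) stop("psi does not match the cluster fields")
  X <- matrix(1, N, 1L)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  P <- length(fields)
  keys <- vapply(seq_len(P), function(i)
    paste(canonicalClusterIds(fields@clusters[i, ]), collapse = ","),
    character(1L))
  uni <- !duplicated(keys)
  uniqueRows <- which(uni)
  posToUnique <- match(keys, keys[uni])
  tp <- as(as(psi, "generalMatrix"), "TsparseMatrix")
  off <- tp@i != tp@j
  preps <- lapply(uniqueRows, function(i) {
    scan_prepare_cpp(N, as.integer(fields@clusters[i, ]),
                     tp@i[off], tp@j[off], tp@x[off])
  })
  list(fields = fields, psi = psi, X = X, preps = preps,
       posToUnique = posToUnique, prep0 = remlPrepare(psi, NULL), N = N)
}

# W statistics for phenotype replicates: returns list with matrices
# W, conv (R x P over positions) and the shared null fits
scanW <- function(prep, Y, keepSigmas = FALSE) {
  Y <- as.matrix(Y)
  R <- ncol(Y)
  ll0 <- numeric(R); conv0 <- numeric(R)
  theta0 <- matrix(0, R, 2L)
  for (r in seq_len(R)) {
    f0 <- fit_reml_cpp(prep$prep0, prep$X, Y[, r], TRUE)
    ll0[r] <- f0$loglik
    conv0[r] <- as.numeric(isTRUE(f0$converged))
    theta0[r, ] <- c(f0$sigmaA2, f0$sigmaE2)
  }
  U <- length(prep$preps)
  Wu <- matrix(NA_real_, R, U)
  convU <- matrix(0, R, U)
  sig <- if (keepSigmas) array(NA_real_, c(R, U, 3L)) else NULL
  for (u in seq_len(U)) {
    res <- fit_w_multi_cpp(prep$preps[[u]], prep$X, Y, ll0, conv0, theta0)
    Wu[, u] <- res[, 1L]
    convU[, u] <- res[, 4L]
    if (keepSigmas) sig[, u, ] <- res[, 5:7]
  }
  list(W = Wu[, prep$posToUnique, drop = FALSE],
       conv = convU[, prep$posToUnique, drop = FALSE],
       Wunique = Wu, ll0 = ll0, conv0 = conv0, sigmas = sig)
}

#' Genome-wide IBD mapping scan
#'
#' Runs the variance-component LOD test at every position of the test
#' grid.  When \code{spacingCM} and \code{map} are given, the grid runs
#' from each chromosome's start to its end at that spacing and each grid
#' point is tested with the nearest cluster field (IBD states change
#' slowly, so the nearest available field within half a grid step — or
#' failing that, the nearest overall — stands in for the exact position);
#' otherwise tests are performed at the field positions themselves.
#'
#' @param fields a \linkS4class{ClusterFieldSet}.
#' @param psi sparse symmetric global IBD matrix.
#' @param y numeric trait vector.
#' @param covariates optional fixed-effect covariates.
#' @param spacingCM optional test grid spacing in cM.
#' @param map \linkS4class{GeneticMap} (required with \code{spacingCM}).
#' @param prep optionally a precomputed \code{\link{prepareScan}} object.
#' @return data.frame: chrom, cM, bp, W, lod, p, sigma_a2, sigma_Q2,
#'   sigma_e2, converged — sorted by genome position.
#' @export
genomeScan <- function(fields, psi, y, covariates = NULL, spacingCM = NULL,
                       map = NULL, prep = NULL) {
  if (!is.null(spacingCM)) {
    if (is.null(map)) stop("spacingCM requires a genetic map")
    fields <- nearestFields(fields, map, spacingCM)
  }
  if (is.null(prep)) prep <- prepareScan(fields, psi, covariates)
  if (length(y) != prep$N)
    stop(sprintf("trait length %d does not match sample count %d",
                 length(y), prep$N))
  res <- scanW(prep, matrix(y, ncol = 1L), keepSigmas = TRUE)
  W <- res$W[1L, ]
  conv <- res$conv[1L, ] > 0.5
  pos <- fieldPositions(prep$fields)
  out <- data.frame(chrom = pos$chrom, cM = pos$cM, bp = pos$bp, W = W,
                    lod = W / (2 * log(10)), p = mixturePValue(W),
                    sigma_a2 = res$sigmas[1L, prep$posToUnique, 1L],
                    sigma_Q2 = res$sigmas[1L, prep$posToUnique, 2L],
                    sigma_e2 = res$sigmas[1L, prep$posToUnique, 3L],
                    converged = conv, stringsAsFactors = FALSE)
  out$W[!conv] <- NA_real_
  out$p[!conv] <- NA_real_
  if (any(!conv))
    message(sprintf("%d position(s) did not converge and report NA",
                    sum(!conv)))
  out[order(out$chrom, out$cM), , drop = FALSE]
}

# resolve a cM grid to the nearest available cluster fields
nearestFields <- function(fields, map, spacingCM) {
  pieces <- list()
  for (ch in unique(fields@chrom)) {
    span <- chromSpansCM(map)
    span <- span[span$chrom == ch, , drop = FALSE]
    grid <- seq(span$startCM, span$endCM, by = spacingCM)
    sel <- which(fields@chrom == ch)
    idx <- sel[vapply(grid, function(g) which.min(abs(fields@cM[sel] - g)),
                      integer(1L))]
    far <- abs(fields@cM[idx] - grid) > 0.5 * spacingCM
    piece <- fields[idx]
    piece@cM <- grid
    pieces[[ch]] <- piece
  }
  combineClusterFields(pieces)
}

#' Two-step genome scan
#'
#' Coarse pass at \code{coarseCM} intervals; on each chromosome the top
#' \code{topK} positions by ascending p-value seed zoom windows of
#' \code{windowCM} centered on them (overlapping windows are merged);
#' a fine pass at \code{fineCM} intervals covers the windows.  Returns
#' the union of both passes with stage labels.
#'
#' @param fields a \linkS4class{ClusterFieldSet} (fine-resolution fields).
#' @param psi global IBD matrix.
#' @param y trait vector.
#' @param map \linkS4class{GeneticMap}.
#' @param covariates optional covariates.
#' @param coarseCM,fineCM,topK,windowCM two-step parameters.
#' @return data.frame as \code{\link{genomeScan}} plus a \code{stage}
#'   column.
#' @export
twoStepScan <- function(fields, psi, y, map, covariates = NULL,
                        coarseCM = 1, fineCM = 0.1, topK = 10L,
                        windowCM = 1) {
  coarse <- genomeScan(fields, psi, y, covariates, spacingCM = coarseCM,
                       map = map)
  coarse$stage <- "coarse"
  finePieces <- list()
  for (ch in unique(coarse$chrom)) {
    sub <- coarse[coarse$chrom == ch, , drop = FALSE]
    k <- min(topK, nrow(sub))
    seeds <- sub$cM[order(sub$p)][seq_len(k)]
    win <- mergeIntervalsCM(seeds - windowCM / 2, seeds + windowCM / 2)
    span <- chromSpansCM(map)
    span <- span[span$chrom == ch, , drop = FALSE]
    grid <- unlist(lapply(seq_len(nrow(win)), function(i)
      seq(max(win[i, 1L], span$startCM), min(win[i, 2L], span$endCM),
          by = fineCM)))
    grid <- sort(unique(round(grid, 9)))
    sel <- which(fields@chrom == ch)
    idx <- sel[vapply(grid, function(g) which.min(abs(fields@cM[sel] - g)),
                      integer(1L))]
    piece <- fields[idx]
    piece@cM <- grid
    finePieces[[ch]] <- piece
  }
  fineFields <- combineClusterFields(finePieces)
  fine <- genomeScan(fineFields, psi, y, covariates)
  fine$stage <- "fine"
  out <- rbind(coarse, fine)
  out[order(out$chrom, out$cM, out$stage), , drop = FALSE]
}

#' Single-variant regression comparator
#'
#' Tests every marker in a region with simple linear regression of the
#' phenotype on the minor-allele copy number (two-sided t-test on the
#' slope) and returns the minimum p-value across markers, the
#' conventional comparator for array-data scans.  Monomorphic markers
#' are skipped.  No relatedness adjustment is applied (appropriate when
#' chromosomes are simulated independently, so relatedness is not
#' preserved across the genome).
#'
#' @param haps a \linkS4class{PhasedHaplotypes} (e.g. a SNP-array panel).
#' @param y phenotype vector.
#' @param region list(chrom, startCM, endCM); NULL tests all markers.
#' @return list: minP, bestIdx (marker column in haps), n, perMarker
#'   (data.frame idx, beta, t, p).
#' @export
singleVariantComparator <- function(haps, y, region = NULL) {
  idx <- seq_len(nMarkers(haps))
  if (!is.null(region)) {
    idx <- which(haps@chrom == region$chrom & haps@cM >= region$startCM &
                   haps@cM <= region$endCM)
  }
  if (length(idx) == 0L)
    return(list(minP = NA_real_, bestIdx = NA_integer_, n = 0L,
                perMarker = data.frame(idx = integer(0), beta = numeric(0),
                                       t = numeric(0), p = numeric(0))))
  q <- minorDosage(haps, idx)
  n <- length(y)
  qc <- sweep(q, 2L, colMeans(q))
  sxx <- colSums(qc^2)
  poly <- sxx > 0
  if (!all(poly))
    message(sprintf("skipping %d monomorphic marker(s)", sum(!poly)))
  yc <- y - mean(y)
  syy <- sum(yc^2)
  b <- colSums(qc * yc)[poly] / sxx[poly]
  sse <- pmax(syy - b^2 * sxx[poly], 0)
  s2 <- sse / (n - 2L)
  tt <- b / sqrt(s2 / sxx[poly])
  p <- 2 * pt(-abs(tt), df = n - 2L)
  per <- data.frame(idx = idx[poly], beta = b, t = tt, p = p)
  best <- which.min(p)
  list(minP = if (length(p)) min(p) else NA_real_,
       bestIdx = if (length(p)) per$idx[best] else NA_integer_,
       n = sum(poly), perMarker = per)
}

#' Genome-wide type-I-error experiment
#'
#' Simulates phenotype replicates under the null (Y = g + e with
#' g ~ N(0, Psi)), scans the genome at the field positions, derives a
#' per-replicate genome-wide threshold (decay-parameter estimate from the
#' replicate's own scan followed by the Monte-Carlo max-statistic
#' threshold), and reports family-wise rejection rates for the OU-based
#' threshold and the Bonferroni threshold 0.05 / (number of tests).
#'
#' @param fields cluster fields at the scan grid (regular spacing).
#' @param psi global IBD matrix.
#' @param nReplicates phenotype replicates.
#' @param seed RNG seed (controls phenotypes and threshold simulations).
#' @param spacingCM grid spacing of \code{fields}.
#' @param covariates optional covariates (also used in generation when
#'   \code{covariateCoefs} given).
#' @param covariateCoefs generation coefficients for covariates.
#' @param ouReps Monte-Carlo replicates per threshold.
#' @param level genome-wide significance level.
#' @param prep optional precomputed \code{\link{prepareScan}} object.
#' @return an experiment report: list with per-replicate data.frame
#'   \code{replicates}, summary \code{rates} (with 95\% binomial CIs),
#'   and \code{provenance}.
#' @export
type1Experiment <- function(fields, psi, nReplicates = 1000L, seed = 1L,
                            spacingCM = 0.1, covariates = NULL,
                            covariateCoefs = NULL, ouReps = 10000L,
                            level = 0.95, prep = NULL) {
  if (is.null(prep)) prep <- prepareScan(fields, psi, covariates)
  Y <- simulatePhenotypes(psi, nReplicates, seed = seed,
                          covariates = covariates,
                          covariateCoefs = covariateCoefs)
  res <- scanW(prep, Y)
  chromIdx <- prep$fields@chrom
  chromLens <- vapply(split(prep$fields@cM, chromIdx),
                      function(cm) max(cm) - min(cm), numeric(1L))
  P <- length(prep$fields)
  bonf <- 0.05 / P
  rows <- lapply(seq_len(nReplicates), function(r) {
    w <- res$W[r, ]
    stats <- split(w, chromIdx)
    af <- estimateAlpha(stats, spacing = spacingCM)
    thr <- genomeThreshold(ouModel(af$alphaHat, spacingCM, chromLens),
                           nReplicates = ouReps, level = level,
                           seed = seed + 7L * r)
    minP <- min(mixturePValue(w))
    data.frame(replicate = r, alphaHat = af$alphaHat, pStar = thr$pStar,
               minP = minP, rejectOU = minP <= thr$pStar,
               rejectBonf = minP <= bonf)
  })
  reps <- do.call(rbind, rows)
  report(reps, c(ou = "rejectOU", bonferroni = "rejectBonf"),
         provenance = list(seed = seed, nReplicates = nReplicates,
                           spacingCM = spacingCM, nTests = P,
                           bonferroni = bonf, ouReps = ouReps,
                           level = level))
}

report <- function(reps, rateCols, provenance) {
  rates <- do.call(rbind, lapply(names(rateCols), function(nm) {
    x <- reps[[rateCols[[nm]]]]
    x <- x[!is.na(x)]
    ci <- stats::binom.test(sum(x), length(x))$conf.int
    data.frame(method = nm, rate = mean(x), lower = ci[1L], upper = ci[2L],
               n = length(x), stringsAsFactors = FALSE)
  }))
  structure(list(replicates = reps, rates = rates, provenance = provenance),
            class = "ibdscanReport")
}

#' @export
print.ibdscanReport <- function(x, ...) {
  cat("Experiment report (", nrow(x$replicates), " replicates)\n", sep = "")
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Power experiment for MAF-classified causal regions
#'
#' Per replicate: select a 0.05 cM causal region of the target MAF class,
#' simulate a phenotype with the class effect-size rule, test the region
#' with the variance-component test using the region IBD matrix (average
#' of the local matrices at the region's start and end positions), and
#' declare detection at the supplied genome-wide threshold.  In parallel
#' the single-variant comparator is run over the region's markers in the
#' SNP-array panel (causal variants excluded from the array) against the
#' conventional threshold \code{svThreshold}.
#'
#' @param haps sequence-data \linkS4class{PhasedHaplotypes}.
#' @param map \linkS4class{GeneticMap}.
#' @param psi global IBD matrix.
#' @param class MAF class label.
#' @param params clustering parameters (\code{\link{clusteringParams}}).
#' @param pStar genome-wide p-value threshold for the IBD test.
#' @param nReplicates number of replicates.
#' @param seed RNG seed.
#' @param arrayHaps SNP-array \linkS4class{PhasedHaplotypes}; by default
#'   built per replicate from \code{haps} excluding that replicate's
#'   causal variants (MAF >= 1\%, up to \code{arrayPerChrom} markers).
#' @param arrayPerChrom array density per chromosome.
#' @param svThreshold single-variant genome-wide threshold (5e-8).
#' @param fields optional precomputed \linkS4class{ClusterFieldSet} (e.g.
#'   the 0.1 cM scan fields); region endpoints then use the nearest
#'   available cluster output instead of clustering per replicate.
#' @return an experiment report (see \code{\link{type1Experiment}}).
#' @export
powerExperiment <- function(haps, map, psi, class, params,
                            pStar, nReplicates = 100L, seed = 1L,
                            arrayHaps = NULL, arrayPerChrom = 30000L,
                            svThreshold = 5e-8, varPerVariant = 0.05,
                            arrayMafMin = 0.01, classBounds = NULL,
                            fields = NULL) {
  maf <- minorAlleleFreq(haps)
  arrayOK <- maf >= arrayMafMin
  rows <- lapply(seq_len(nReplicates), function(r) {
    spec <- selectCausalRegion(haps, class, seed = seed + 13L * r,
                               varPerVariant = varPerVariant,
                               bounds = classBounds)
    y <- simulatePhenotypes(psi, 1L, seed = seed + 13L * r + 5L,
                            spec = spec, haps = haps)[, 1L]
    endFields <- if (is.null(fields)) {
      clusterAtPosition(haps, map, params, c(spec$startCM, spec$endCM),
                        chrom = spec$chrom)
    } else {
      sel <- which(fields@chrom == spec$chrom)
      idx <- sel[c(which.min(abs(fields@cM[sel] - spec$startCM)),
                   which.min(abs(fields@cM[sel] - spec$endCM)))]
      fields[unique(idx)]
    }
    phi <- regionIBDMatrix(endFields)
    tst <- lodTest(vcModelSpec(y, psi, phi))
    # array panel for the comparator: exclude this replicate's causal set
    region <- list(chrom = spec$chrom, startCM = spec$startCM,
                   endCM = spec$endCM)
    arr <- arrayHaps
    if (is.null(arr)) {
      ok <- arrayOK
      ok[spec$causalIdx] <- FALSE
      keep <- integer(0)
      withSeed(seed + 13L * r + 9L, {
        for (ch in unique(haps@chrom)) {
          idx <- which(ok & haps@chrom == ch)
          keep <- c(keep, if (length(idx) <= arrayPerChrom) idx
                    else sort(sample(idx, arrayPerChrom)))
        }
      })
      arr <- subsetMarkers(haps, sort(keep))
    }
    sv <- singleVariantComparator(arr, y, region)
    data.frame(replicate = r, chrom = spec$chrom, startCM = spec$startCM,
               nCausal = length(spec$causalIdx), W = tst$W, p = tst$p,
               detectIBD = !is.na(tst$p) & tst$p <= pStar,
               svMinP = sv$minP,
               detectSV = !is.na(sv$minP) & sv$minP <= svThreshold)
  })
  reps <- do.call(rbind, rows)
  report(reps, c(ibd_mapping = "detectIBD", single_variant = "detectSV"),
         provenance = list(seed = seed, nReplicates = nReplicates,
                           class = class, pStar = pStar,
                           svThreshold = svThreshold,
                           varPerVariant = varPerVariant,
                           arrayMafMin = arrayMafMin))
}
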