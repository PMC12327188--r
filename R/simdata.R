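#' Simulation configuration for the synthetic population
#'
#' Defaults describe the full-scale study conditions: 5,000 individuals,
#' 30 chromosomes of 100 cM, mutation and recombination both at 1e-8 per
#' bp per generation (hence a uniform 1 cM/Mb map), and a demography
#' approximating the history of a large outbred (UK-like) population as
#' three epochs: ancestral size 10,000 with a deeper 24,000 epoch, then
#' exponential growth to 1,000,000 over the last 300 generations.  The
#' \code{"scaled"} demography is a constant population of 10,000 chosen so
#' that desk-scale samples (a few hundred individuals) retain roughly the
#' same per-position fraction of individuals inside multi-individual IBD
#' clusters as the full-scale study — the quantity that governs how much
#' information each variance-component test carries; all sizes scale
#' down.
#'
#' @param nIndividuals diploid sample size.
#' @param nChromosomes number of independently simulated chromosomes.
#' @param chromLengthCM chromosome length in cM (all equal).
#' @param mutationRate,recombinationRate per bp per generation/meiosis.
#' @param demography \code{"uk-like"}, \code{"scaled"}, or a list passed
#'   through to the simulator backend (fields type/ne/...).
#' @param seed RNG seed for the backend.
#' @return configuration list.
#' @export
simConfig <- function(nIndividuals = 5000L, nChromosomes = 30L,
                      chromLengthCM = 100, mutationRate = 1e-8,
                      recombinationRate = 1e-8, demography = "uk-like",
                      seed = 1L) {
  if (is.character(demography)) {
    demography <- switch(match.arg(demography, c("uk-like", "scaled")),
      "uk-like" = list(type = "growth", ne_ancestral = 10000,
                       ne_present = 1e6, t_growth = 300,
                       ne_deep = 24000, t_deep = 5000),
      "scaled" = list(type = "constant", ne = 10000))
  }
  list(nIndividuals = as.integer(nIndividuals),
       nChromosomes = as.integer(nChromosomes),
       chromLengthCM = chromLengthCM, mutationRate = mutationRate,
       recombinationRate = recombinationRate, demography = demography,
       seed = as.integer(seed))
}

pythonBackend <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) return(NULL)
  ok <- suppressWarnings(system2(py, c("-c", shQuote("import msprime")),
                                 stdout = FALSE, stderr = FALSE))
  if (!identical(ok, 0L)) return(NULL)
  py
}

#' Simulate a phased population with the coalescent backend
#'
#' Runs the bundled msprime driver to simulate phased whole-chromosome
#' haplotypes under the configured demography; chromosomes are
#' independent.  The genetic map is uniform (cM/Mb ratio implied by the
#' equal mutation and recombination rates) and is returned explicitly so
#' that downstream code never assumes uniformity.  Deterministic given
#' the config seed.  When no python/msprime backend is available, falls
#' back to the structured fixture generator with a warning (returning
#' cluster fields and kinship instead of haplotypes).
#'
#' @param config from \code{\link{simConfig}}.
#' @param dir working directory for backend files (default: tempdir).
#' @return list with elements \code{haps} (\linkS4class{PhasedHaplotypes})
#'   and \code{map} (\linkS4class{GeneticMap}); or, in fallback mode, the
#'   structured-fixture list with an attribute \code{backend = "fixture"}.
#' @export
simulatePopulation <- function(config, dir = NULL) {
  py <- pythonBackend()
  if (is.null(py)) {
    warning("python/msprime backend unavailable; falling back to the structured fixture generator")
    fx <- generateStructuredFixture(config$nIndividuals,
                                    structuredClusterSpec(),
                                    seed = config$seed)
    attr(fx, "backend") <- "fixture"
    return(fx)
  }
  if (is.null(dir)) dir <- tempfile("simpop")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cmPerMb <- config$recombinationRate * 1e6 * 100
  cfg <- list(n = config$nIndividuals,
              chromosomes = rep(config$chromLengthCM, config$nChromosomes),
              cm_per_mb = cmPerMb,
              mutation_rate = config$mutationRate,
              recombination_rate = config$recombinationRate,
              demography = config$demography, seed = config$seed)
  cfgPath <- file.path(dir, "config.json")
  writeLines(miniJSON(cfg), cfgPath)
  script <- system.file("python", "simulate_population.py",
                        package = "ibdscan")
  status <- system2(py, c(shQuote(script), shQuote(cfgPath), shQuote(dir)),
                    stdout = file.path(dir, "backend.log"),
                    stderr = file.path(dir, "backend.log"))
  if (!identical(status, 0L))
    stop("simulator backend failed; see ", file.path(dir, "backend.log"))
  chroms <- as.character(seq_len(config$nChromosomes))
  map <- uniformGeneticMap(
    stats::setNames(rep(config$chromLengthCM, config$nChromosomes), chroms),
    cmPerMb = cmPerMb)
  pieces <- lapply(seq_len(config$nChromosomes), function(k) {
    parse_hap_text_cpp(file.path(dir, sprintf("chr%d.haps.txt", k)))
  })
  H <- do.call(cbind, lapply(pieces, `[[`, "H"))
  pos <- unlist(lapply(pieces, `[[`, "pos"))
  chrom <- rep(chroms, vapply(pieces, function(p) length(p$pos), integer(1L)))
  samples <- sprintf("S%d", seq_len(config$nIndividuals))
  list(haps = phasedHaplotypes(H, samples = samples, chrom = chrom,
                               pos = pos, map = map),
       map = map)
}

# minimal JSON serializer for the backend config (scalars, vectors, lists)
miniJSON <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x)))
      return(paste0("[", paste(vapply(x, miniJSON, character(1L)),
                               collapse = ","), "]"))
    return(paste0("{", paste(sprintf('"%s":%s', names(x),
                                     vapply(x, miniJSON, character(1L))),
                             collapse = ","), "}"))
  }
  if (is.character(x)) return(sprintf('"%s"', x))
  if (length(x) > 1L)
    return(paste0("[", paste(vapply(as.list(x), miniJSON, character(1L)),
                             collapse = ","), "]"))
  if (is.integer(x)) return(sprintf("%d", x))
  sprintf("%.10g", x)
}

#' Specification for the structured cluster/kinship fixture generator
#'
#' Desk-scale stand-in for the sparse-cluster regime of a large outbred
#' population: at each position a configurable fraction of haplotypes is
#' grouped into small IBD clusters (the rest are singletons), and a
#' fraction of individuals form related pairs with kinship drawn from
#' close-relative values.  The default related fraction is deliberately
#' high (a relative-enriched cohort) so that the genome-wide variance
#' component is strongly identified — a precondition for the boundary
#' asymptotics of the variance-component test to apply at moderate N.
#'
#' @param nPositions number of positions.
#' @param spacingCM grid spacing.
#' @param chrom chromosome label.
#' @param clusteredFraction target fraction of haplotypes in non-singleton
#'   clusters at each position.
#' @param sizeProbs named probabilities of non-singleton cluster sizes.
#' @param relatedFraction fraction of individuals in related pairs.
#' @param kinshipValues kinship values sampled for related pairs.
#' @return specification list.
#' @export
structuredClusterSpec <- function(nPositions = 1L, spacingCM = 0.1,
                                  chrom = "1", clusteredFraction = 0.3,
                                  sizeProbs = c("2" = 0.45, "3" = 0.25,
                                                "4" = 0.15, "5" = 0.1,
                                                "6" = 0.05),
                                  relatedFraction = 0.4,
                                  kinshipValues = c(0.125, 0.25)) {
  list(nPositions = as.integer(nPositions), spacingCM = spacingCM,
       chrom = chrom, clusteredFraction = clusteredFraction,
       sizeProbs = sizeProbs, relatedFraction = relatedFraction,
       kinshipValues = kinshipValues)
}

#' Generate a structured cluster-field and kinship fixture
#'
#' Directly emits cluster fields and a kinship table with known ground
#' truth, so the variance-component test and the multiple-testing
#' adjustment can be exercised in seconds without a coalescent backend.
#' Deterministic given the seed.
#'
#' @param nIndividuals number of individuals N.
#' @param clusterSpec from \code{\link{structuredClusterSpec}}.
#' @param seed RNG seed.
#' @return list with fields (\linkS4class{ClusterFieldSet}), kinship
#'   (data.frame), samples (character).
#' @export
generateStructuredFixture <- function(nIndividuals,
                                      clusterSpec = structuredClusterSpec(),
                                      seed = 1L) {
  N <- as.integer(nIndividuals)
  n2 <- 2L * N
  samples <- sprintf("S%d", seq_len(N))
  sizes <- as.integer(names(clusterSpec$sizeProbs))
  withSeed(seed, {
    cl <- matrix(0L, clusterSpec$nPositions, n2)
    for (p in seq_len(clusterSpec$nPositions)) {
      unassigned <- sample.int(n2)
      target <- clusterSpec$clusteredFraction * n2
      assigned <- 0L
      nextId <- 1L
      ids <- integer(n2)
      while (assigned < target && length(unassigned) >= 2L) {
        s <- sample(sizes, 1L, prob = clusterSpec$sizeProbs)
        # outbred population: a cluster never holds both haplotypes of
        # one individual, so draw members from distinct individuals
        mem <- integer(0)
        used <- integer(0)
        for (h in unassigned) {
          ind <- (h - 1L) %/% 2L
          if (ind %in% used) next
          mem <- c(mem, h); used <- c(used, ind)
          if (length(mem) == s) break
        }
        if (length(mem) < 2L) break
        unassigned <- setdiff(unassigned, mem)
        ids[mem] <- nextId
        nextId <- nextId + 1L
        assigned <- assigned + length(mem)
      }
      ids[ids == 0L] <- seq.int(nextId, length.out = sum(ids == 0L))
      cl[p, ] <- ids
    }
    nRelated <- floor(clusterSpec$relatedFraction * N / 2)
    kin <- if (nRelated > 0L) {
      pairIdx <- matrix(sample.int(N, 2L * nRelated), ncol = 2L)
      data.frame(sample1 = samples[pairIdx[, 1L]],
                 sample2 = samples[pairIdx[, 2L]],
                 kinship = sample(clusterSpec$kinshipValues, nRelated,
                                  replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample1 = character(0), sample2 = character(0),
                 kinship = numeric(0), stringsAsFactors = FALSE)
    }
  })
  cm <- (seq_len(clusterSpec$nPositions) - 1L) * clusterSpec$spacingCM
  fields <- clusterFieldSet(cl, chrom = clusterSpec$chrom,
                            bp = cm * 1e6 + 1, cM = cm, samples = samples)
  list(fields = fields, kinship = kin, samples = samples)
}

#' Minor allele frequencies of a haplotype panel
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @return numeric vector of per-marker minor allele frequencies (the
#'   minor allele is whichever of reference/alternate is rarer; all
#'   non-reference alleles are pooled at multi-allelic sites).
#' @export
minorAlleleFreq <- function(haps) {
  af <- alt_freq_cpp(haps@alleles)
  pmin(af, 1 - af)
}

#' MAF class bounds
#'
#' Classes partition (0, 0.5]: common (0.10, 0.5], low-frequency
#' (0.01, 0.10], rare (0.0005, 0.01], ultra-rare (0, 0.0005].  At reduced
#' sample sizes the ultra-rare bound can fall below the resolution
#' 1/(2N); \code{nHaplotypes} then raises the bound to 2.5/2N so the
#' class means "at most two copies in the sample" (the full-scale
#' definition's intent: present but effectively untypeable variants).
#'
#' @param class one of "common", "low_frequency", "rare", "ultra_rare".
#' @param nHaplotypes optional haplotype count 2N for the scaled bound.
#' @return numeric c(lower, upper]; variants with lower < MAF <= upper.
#' @export
mafClassBounds <- function(class = c("common", "low_frequency", "rare",
                                     "ultra_rare"), nHaplotypes = NULL) {
  class <- match.arg(class)
  ultra <- 0.0005
  if (!is.null(nHaplotypes) && 1 / nHaplotypes > ultra)
    ultra <- min(2.5 / nHaplotypes, 0.005)  # keep a non-empty rare class
  switch(class,
         common = c(0.10, 0.5),
         low_frequency = c(0.01, 0.10),
         rare = c(ultra, 0.01),
         ultra_rare = c(0, ultra))
}

#' Select a causal region and build a phenotype specification
#'
#' Tiles each chromosome into windows of \code{regionLengthCM} and keeps
#' windows containing enough variants of the target MAF class (>= 4 for
#' common/low-frequency, half designated causal; >= 8 for rare/ultra-rare,
#' a random quarter causal).  One qualifying window is chosen uniformly.
#' Effect sizes follow the per-variant equal-variance rule
#' \eqn{\theta_l = \sqrt{c / (2\,\mathrm{MAF}_l(1-\mathrm{MAF}_l))}}
#' (default c = 0.05, so each causal variant contributes 0.05 to the
#' trait variance); \code{thetaRule = "linear"} instead uses
#' \eqn{\theta_l = c / (2\,\mathrm{MAF}_l(1-\mathrm{MAF}_l))}.
#'
#' @param haps a \linkS4class{PhasedHaplotypes} (cM coordinates attached).
#' @param class target MAF class (see \code{\link{mafClassBounds}}).
#' @param seed RNG seed.
#' @param regionLengthCM causal region length (default 0.05 cM).
#' @param varPerVariant variance contribution c per causal variant.
#' @param thetaRule "sqrt" (default) or "linear".
#' @param scaledBounds use sample-size-adapted ultra-rare bound.
#' @param bounds optional explicit MAF bounds c(lower, upper] overriding
#'   the class defaults (used by desk-scale studies whose typeability
#'   threshold shifts the class boundaries).
#' @return list: chrom, startCM, endCM, markerIdx (columns of haps),
#'   causalIdx, maf, theta, class, seed.
#' @export
selectCausalRegion <- function(haps, class, seed = 1L,
                               regionLengthCM = 0.05, varPerVariant = 0.05,
                               thetaRule = c("sqrt", "linear"),
                               scaledBounds = TRUE, bounds = NULL) {
  thetaRule <- match.arg(thetaRule)
  maf <- minorAlleleFreq(haps)
  if (is.null(bounds))
    bounds <- mafClassBounds(class, if (scaledBounds) nrow(haps@alleles))
  inClass <- maf > bounds[1L] & maf <= bounds[2L] & maf > 0
  minCount <- if (class %in% c("common", "low_frequency")) 4L else 8L
  frac <- if (class %in% c("common", "low_frequency")) 0.5 else 0.25
  cand <- list()
  for (ch in unique(haps@chrom)) {
    sel <- which(haps@chrom == ch & inClass)
    if (length(sel) == 0L) next
    cms <- haps@cM[sel]
    tile <- floor(cms / regionLengthCM)
    tab <- table(tile)
    good <- as.integer(names(tab)[tab >= minCount])
    for (t in good)
      cand[[length(cand) + 1L]] <- list(chrom = ch, tile = t,
                                        idx = sel[tile == t])
  }
  if (length(cand) == 0L)
    stop("no region with enough ", class,
         " variants; simulate a larger population")
  withSeed(seed, {
    pick <- cand[[sample.int(length(cand), 1L)]]
    k <- max(1L, floor(length(pick$idx) * frac))
    causal <- sort(sample(pick$idx, k))
  })
  mafC <- maf[causal]
  theta <- if (thetaRule == "sqrt")
    sqrt(varPerVariant / (2 * mafC * (1 - mafC)))
  else varPerVariant / (2 * mafC * (1 - mafC))
  list(chrom = pick$chrom, startCM = pick$tile * regionLengthCM,
       endCM = (pick$tile + 1L) * regionLengthCM, markerIdx = pick$idx,
       causalIdx = causal, maf = mafC, theta = theta, class = class,
       seed = seed)
}

#' Minor-allele dosages for selected markers
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @param markerIdx marker column indices.
#' @return N x k integer matrix of minor-allele copy numbers (0, 1, 2).
#' @export
minorDosage <- function(haps, markerIdx) {
  af <- alt_freq_cpp(haps@alleles)[markerIdx]
  minor_dosage_cpp(haps@alleles, as.integer(markerIdx) - 1L, af <= 0.5)
}

# lower-triangular factors for sampling N(0, Psi) blockwise, with the
# diagonal-jitter repair policy for near-PSD thresholded matrices
psiFactors <- function(psi, partition = NULL) {
  if (is.null(partition)) partition <- blockPartition(psi, NULL)
  sizes <- lengths(partition)
  blocks <- partition[sizes > 1L]
  facs <- lapply(blocks, function(idx) {
    M <- as.matrix(psi[idx, idx, drop = FALSE])
    for (jit in c(0, 1e-8, 1e-6)) {
      L <- tryCatch(t(chol(M + diag(jit, nrow(M)))), error = function(e) NULL)
      if (!is.null(L)) {
        if (jit > 0)
          message(sprintf("PSD repair: added diagonal jitter %g to a %d-block",
                          jit, nrow(M)))
        return(L)
      }
    }
    stop("block not positive definite even after jitter")
  })
  list(singles = unlist(partition[sizes == 1L], use.names = FALSE),
       blocks = blocks, factors = facs)
}

#' Simulate phenotypes under the null or a causal-region model
#'
#' Null model: Y = g + e with g ~ N(0, Psi) (drawn by block-wise Cholesky
#' factorization) and e standard normal.  With a causal specification the
#' model is Y = X c + g + sum_l theta_l q_l + e, where q_l are
#' minor-allele dosages of the causal variants.  Deterministic given seed.
#'
#' @param psi sparse symmetric global IBD matrix.
#' @param nReplicates number of phenotype replicates.
#' @param seed RNG seed.
#' @param spec optional causal specification from
#'   \code{\link{selectCausalRegion}} (requires \code{haps}).
#' @param haps the \linkS4class{PhasedHaplotypes} the causal
#'   specification refers to.
#' @param covariates optional N x c matrix of fixed-effect covariates.
#' @param covariateCoefs coefficients for the covariates.
#' @return N x nReplicates matrix of trait values.
#' @export
simulatePhenotypes <- function(psi, nReplicates = 1L, seed = 1L,
                               spec = NULL, haps = NULL, covariates = NULL,
                               covariateCoefs = NULL) {
  N <- nrow(psi)
  fac <- psiFactors(psi)
  fixedPart <- 0
  if (!is.null(spec)) {
    if (is.null(haps)) stop("causal spec requires haps")
    q <- minorDosage(haps, spec$causalIdx)
    fixedPart <- fixedPart + as.vector(q %*% spec$theta)
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    fixedPart <- fixedPart + as.vector(cv %*% covariateCoefs)
  }
  withSeed(seed, {
    Y <- matrix(0, N, nReplicates)
    for (r in seq_len(nReplicates)) {
      g <- numeric(N)
      z <- rnorm(N)
      if (length(fac$singles)) g[fac$singles] <- z[fac$singles]
      for (b in seq_along(fac$blocks)) {
        idx <- fac$blocks[[b]]
        g[idx] <- as.vector(fac$factors[[b]] %*% z[idx])
      }
      Y[, r] <- fixedPart + g + rnorm(N)
    }
    Y
  })
}

#' Down-sample sequence haplotypes to a SNP-array panel
#'
#' Excludes all variants with MAF below \code{mafMin} and all variants
#' associated with the simulated phenotype, then randomly selects up to
#' \code{nPerChromosome} variants per chromosome without replacement
#' (with a warning when fewer are available).  Deterministic given seed.
#'
#' @param haps sequence \linkS4class{PhasedHaplotypes}.
#' @param spec causal specification (its causal variants are removed);
#'   NULL for none.
#' @param nPerChromosome array density target (default 30,000).
#' @param mafMin MAF filter (default 0.01).
#' @param seed RNG seed.
#' @return a \linkS4class{PhasedHaplotypes} with the array markers.
#' @export
makeSnpArray <- function(haps, spec = NULL, nPerChromosome = 30000L,
                         mafMin = 0.01, seed = 1L) {
  maf <- minorAlleleFreq(haps)
  ok <- maf >= mafMin
  if (!is.null(spec)) ok[spec$causalIdx] <- FALSE
  keep <- integer(0)
  withSeed(seed, {
    for (ch in unique(haps@chrom)) {
      idx <- which(ok & haps@chrom == ch)
      if (length(idx) < nPerChromosome)
        warning(sprintf("chromosome %s: only %d qualifying variants (requested %d)",
                        ch, length(idx), nPerChromosome))
      take <- if (length(idx) <= nPerChromosome) idx
              else sort(sample(idx, nPerChromosome))
      keep <- c(keep, take)
    }
  })
  subsetMarkers(haps, sort(keep))
}

#' Subset markers of a PhasedHaplotypes object
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @param idx marker column indices to keep.
#' @return a \linkS4class{PhasedHaplotypes}.
#' @export
subsetMarkers <- function(haps, idx) {
  new("PhasedHaplotypes", samples = haps@samples, chrom = haps@chrom[idx],
      pos = haps@pos[idx], cM = haps@cM[idx],
      alleles = haps@alleles[, idx, drop = FALSE])
}

#' Subset samples of a PhasedHaplotypes object
#' @param haps a \linkS4class{PhasedHaplotypes}.
#' @param which sample indices (or names) to keep.
#' @return a \linkS4class{PhasedHaplotypes}.
#' @export
subsetSamples <- function(haps, which) {
  if (is.character(which)) which <- match(which, haps@samples)
  rows <- as.vector(rbind(2L * which - 1L, 2L * which))
  new("PhasedHaplotypes", samples = haps@samples[which],
      chrom = haps@chrom, pos = haps@pos, cM = haps@cM,
      alleles = haps@alleles[rows, , drop = FALSE])
}
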