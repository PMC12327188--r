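test_that("the structured fixture generator is reproducible with the
           requested cluster and kinship structure", {
  fx1 <- generateStructuredFixture(100, seed = 71)
  fx2 <- generateStructuredFixture(100, seed = 71)
  expect_identical(fx1$fields@clusters, fx2$fields@clusters)
  expect_identical(fx1$kinship, fx2$kinship)
  # all-singleton spec -> identity Phi
  fxS <- generateStructuredFixture(
    40, structuredClusterSpec(clusteredFraction = 0), seed = 72)
  expect_equal(as.matrix(localIBDMatrix(fxS$fields[1L])), diag(40L),
               ignore_attr = TRUE)
  # clustered fraction within sampling slack of the target
  sp <- structuredClusterSpec(clusteredFraction = 0.3)
  fx <- generateStructuredFixture(200, sp, seed = 73)
  ids <- as.vector(fx$fields@clusters[1L, ])
  frac <- mean(duplicated(ids) | duplicated(ids, fromLast = TRUE))
  expect_lt(abs(frac - 0.3), 0.05)
  # related fraction matches the spec
  expect_equal(nrow(fx$kinship), floor(0.4 * 200 / 2))
  # a cluster never holds both haplotypes of one individual
  odd <- seq(1L, length(ids), by = 2L)
  expect_false(any(ids[odd] == ids[odd + 1L]))
})

test_that("MAF classes partition (0, 0.5] and adapt the ultra-rare bound", {
  b <- lapply(c("ultra_rare", "rare", "low_frequency", "common"),
              mafClassBounds)
  expect_equal(b[[1L]], c(0, 0.0005))
  expect_equal(b[[2L]][2L], 0.01)
  expect_equal(b[[3L]], c(0.01, 0.10))
  expect_equal(b[[4L]], c(0.10, 0.5))
  # contiguous cover
  expect_equal(b[[1L]][2L], b[[2L]][1L])
  expect_equal(b[[2L]][2L], b[[3L]][1L])
  # scaled bound: with 1000 haplotypes, ultra-rare means <= 2 copies
  expect_equal(mafClassBounds("ultra_rare", 1000)[2L], 2.5 / 1000)
  expect_equal(mafClassBounds("rare", 1000)[1L], 2.5 / 1000)
  # capped so the rare class never collapses at tiny sample sizes
  expect_equal(mafClassBounds("ultra_rare", 100)[2L], 0.005)
})

test_that("causal-region selection follows the class counting rules", {
  set.seed(81)
  # panel with controlled MAFs: 60 diploid samples, one chromosome
  n2 <- 1200; M <- 600
  cm <- sort(runif(M, 0, 3))
  freqs <- rep(c(0.3, 0.05, 0.006, 0.004), length.out = M)
  H <- sapply(freqs, function(f) rbinom(n2, 1L, f))
  map <- geneticMap("1", bp = c(1, 3e6), cM = c(0, 3))
  haps <- phasedHaplotypes(H, samples = sprintf("S%d", 1:600), chrom = "1",
                           pos = round(cm * 1e6) + 1, map = map)
  spec <- selectCausalRegion(haps, "common", seed = 5)
  # half of the in-class variants in the region are causal
  maf <- minorAlleleFreq(haps)
  inRegion <- which(haps@cM >= spec$startCM & haps@cM < spec$endCM &
                      maf > 0.10)
  expect_equal(length(spec$causalIdx), floor(length(inRegion) / 2))
  expect_true(all(spec$causalIdx %in% inRegion))
  expect_gte(length(inRegion), 4L)
  # quarter rule for rare variants
  specR <- selectCausalRegion(haps, "rare", seed = 6)
  mafR <- maf[specR$causalIdx]
  bounds <- mafClassBounds("rare", n2)
  expect_true(all(mafR > bounds[1L] & mafR <= bounds[2L]))
  # effect sizes: theta^2 * 2 maf (1-maf) = varPerVariant
  expect_equal(specR$theta^2 * 2 * mafR * (1 - mafR),
               rep(0.05, length(mafR)), tolerance = 1e-10)
  # linear rule selectable
  specL <- selectCausalRegion(haps, "rare", seed = 6, thetaRule = "linear")
  expect_equal(specL$theta, 0.05 / (2 * mafR * (1 - mafR)),
               tolerance = 1e-10)
  # impossible class errors
  empty <- phasedHaplotypes(matrix(0L, n2, 4L), samples = haps@samples,
                            chrom = "1", pos = 1:4, map = map)
  expect_error(selectCausalRegion(empty, "common", seed = 1), "no region")
})

test_that("phenotype simulation adds the advertised variance", {
  # null model with Psi = I: Var(Y) ~ 2 and E[Y] ~ 0
  psi <- Matrix::Diagonal(400)
  Y <- simulatePhenotypes(psi, 50, seed = 91)
  expect_lt(abs(mean(Y)), 0.05)
  expect_lt(abs(var(as.vector(Y)) - 2), 0.1)
  # one causal variant at MAF 0.5 adds ~0.05 under the sqrt rule
  set.seed(92)
  H <- matrix(rbinom(800 * 40, 1L, 0.5), 800, 40)
  map <- geneticMap("1", bp = c(1, 1e6), cM = c(0, 1))
  haps <- phasedHaplotypes(H, samples = sprintf("S%d", 1:400), chrom = "1",
                           pos = seq(1, 1e6, length.out = 40), map = map)
  maf <- minorAlleleFreq(haps)
  j <- which.min(abs(maf - 0.5))
  spec <- list(causalIdx = j,
               theta = sqrt(0.05 / (2 * maf[j] * (1 - maf[j]))))
  Yc <- simulatePhenotypes(psi, 50, seed = 93, spec = spec, haps = haps)
  dv <- var(as.vector(Yc)) - var(as.vector(
    simulatePhenotypes(psi, 50, seed = 93)))
  expect_lt(abs(dv - 0.05), 0.06)
  # determinism
  expect_identical(simulatePhenotypes(psi, 3, seed = 94),
                   simulatePhenotypes(psi, 3, seed = 94))
})

test_that("phenotypes honor the relatedness structure of Psi", {
  kin <- data.frame(sample1 = "S1", sample2 = "S2", kinship = 0.25)
  psi <- globalIBDMatrix(kin, sprintf("S%d", 1:3))
  Y <- simulatePhenotypes(psi, 4000, seed = 95)
  cc <- cor(Y[1L, ], Y[2L, ])
  # corr = psi_12 / 2 (each of g and e contributes variance 1)
  expect_lt(abs(cc - 0.25), 0.05)
  expect_lt(abs(cor(Y[1L, ], Y[3L, ])), 0.05)
})

test_that("the SNP-array construction filters, excludes and caps", {
  set.seed(96)
  n2 <- 100; M <- 400
  freqs <- runif(M, 0, 0.5)
  H <- sapply(freqs, function(f) rbinom(n2, 1L, f))
  map <- geneticMap("1", bp = c(1, 4e6), cM = c(0, 4))
  haps <- phasedHaplotypes(H, samples = sprintf("S%d", 1:50), chrom = "1",
                           pos = round(seq(1, 4e6, length.out = M)),
                           map = map)
  maf <- minorAlleleFreq(haps)
  spec <- list(causalIdx = which(maf >= 0.2)[1:5])
  arr <- makeSnpArray(haps, spec, nPerChromosome = 100L, seed = 97)
  expect_equal(nMarkers(arr), 100L)
  expect_true(all(minorAlleleFreq(arr) >= 0.01))
  expect_false(any(haps@pos[spec$causalIdx] %in% arr@pos))
  # requesting more than available keeps everything, with a warning
  expect_warning(arrAll <- makeSnpArray(haps, spec,
                                        nPerChromosome = 10000L,
                                        seed = 98), "qualifying")
  expect_equal(nMarkers(arrAll), sum(maf >= 0.01) - 5L)
  # determinism
  arr2 <- makeSnpArray(haps, spec, nPerChromosome = 100L, seed = 97)
  expect_identical(arr@pos, arr2@pos)
})

test_that("the coalescent backend produces deterministic, independent
           chromosomes (or falls back gracefully)", {
  cfg <- simConfig(12, 2, 5, demography = "scaled", seed = 31)
  if (is.null(ibdscan:::pythonBackend())) {
    expect_warning(fx <- simulatePopulation(cfg), "fall")
    expect_true(!is.null(attr(fx, "backend")))
    succeed()
    return(invisible(NULL))
  }
  pop <- simulatePopulation(cfg)
  expect_s4_class(pop$haps, "PhasedHaplotypes")
  expect_equal(nSamples(pop$haps), 12L)
  expect_setequal(unique(pop$haps@chrom), c("1", "2"))
  # deterministic given the seed
  pop2 <- simulatePopulation(cfg)
  expect_identical(pop$haps@alleles, pop2$haps@alleles)
  # different seeds differ
  pop3 <- simulatePopulation(simConfig(12, 2, 5, demography = "scaled",
                                       seed = 32))
  expect_false(identical(pop$haps@alleles, pop3$haps@alleles))
  # site-frequency spectrum decreasing for the constant-size control
  maf <- minorAlleleFreq(pop$haps)
  counts <- table(cut(maf, c(0, 0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_true(counts[1L] > counts[4L])
})
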