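library(Matrix)

# a small multi-chromosome scan world built from structured fixtures;
# partitions persist over `persist` consecutive grid points so the scan
# statistics carry the genome-like autocorrelation the adjustment models
scanWorld <- function(N = 80, nPos = 21, spacing = 0.5, seed = 51,
                      persist = 4L) {
  set.seed(seed)
  stretch <- function(fx, chrom) {
    rows <- rep(seq_len(length(fx$fields)), each = persist)[seq_len(nPos)]
    cm <- (seq_len(nPos) - 1L) * spacing
    clusterFieldSet(fx$fields@clusters[rows, , drop = FALSE],
                    chrom = chrom, bp = cm * 1e6 + 1, cM = cm,
                    samples = fx$samples)
  }
  nDraw <- ceiling(nPos / persist)
  fx1 <- generateStructuredFixture(
    N, structuredClusterSpec(nPositions = nDraw, spacingCM = spacing,
                             chrom = "1"), seed = seed)
  fx2 <- generateStructuredFixture(
    N, structuredClusterSpec(nPositions = nDraw, spacingCM = spacing,
                             chrom = "2"), seed = seed + 1L)
  fields <- combineClusterFields(list(stretch(fx1, "1"), stretch(fx2, "2")))
  psi <- globalIBDMatrix(fx1$kinship, fx1$samples)
  map <- uniformGeneticMap(stats::setNames(rep((nPos - 1) * spacing, 2L),
                                           c("1", "2")))
  list(fields = fields, psi = psi, map = map, samples = fx1$samples)
}

test_that("the genome scan returns one calibrated row per grid point", {
  w <- scanWorld()
  y <- as.vector(simulatePhenotypes(w$psi, 1L, seed = 52))
  sc <- genomeScan(w$fields, w$psi, y)
  expect_equal(nrow(sc), length(w$fields))
  expect_true(all(sc$W >= 0, na.rm = TRUE))
  expect_equal(sc$p, mixturePValue(sc$W))
  expect_equal(sc$lod, sc$W / (2 * log(10)))
  # grid construction from a map: 10 cM at 0.5 -> 21 rows per chromosome
  sc2 <- genomeScan(w$fields, w$psi, y, spacingCM = 0.5, map = w$map)
  expect_equal(nrow(sc2), 42L)
  # mismatched sample sets are an error
  expect_error(genomeScan(w$fields, w$psi, y[-1L]), "match")
})

test_that("scans are invariant to consistent sample permutation", {
  w <- scanWorld(N = 50, nPos = 5)
  y <- as.vector(simulatePhenotypes(w$psi, 1L, seed = 53))
  sc <- genomeScan(w$fields, w$psi, y)
  perm <- sample.int(50)
  hapPerm <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  fieldsP <- clusterFieldSet(w$fields@clusters[, hapPerm, drop = FALSE],
                             chrom = w$fields@chrom, bp = w$fields@bp,
                             cM = w$fields@cM,
                             samples = w$samples[perm])
  scP <- genomeScan(fieldsP, w$psi[perm, perm], y[perm])
  expect_equal(scP$W, sc$W, tolerance = 1e-6)
})

test_that("pointwise null calibration holds across scan positions", {
  w <- scanWorld(N = 150, nPos = 11, seed = 57)
  Y <- simulatePhenotypes(w$psi, 40, seed = 58)
  prep <- prepareScan(w$fields, w$psi)
  res <- ibdscan:::scanW(prep, Y)
  pvals <- mixturePValue(as.vector(res$W))
  # dependence within replicates: loose check on the rejection rate
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.04)
})

test_that("the two-step scan finds what the full scan finds", {
  w <- scanWorld(N = 120, nPos = 21, spacing = 0.5, seed = 61)
  # implant a strong local effect at one interior field position
  target <- 8L
  Phi <- localIBDMatrix(as.vector(w$fields@clusters[target, ]))
  LP <- chol(as.matrix(Phi) + 1e-8 * diag(120))
  set.seed(62)
  y <- as.vector(simulatePhenotypes(w$psi, 1L, seed = 63)) +
    as.vector(t(LP) %*% rnorm(120)) * sqrt(3)
  full <- genomeScan(w$fields, w$psi, y)
  two <- twoStepScan(w$fields, w$psi, y, w$map, coarseCM = 2,
                     fineCM = 0.5, topK = 3L, windowCM = 2)
  expect_true(all(c("coarse", "fine") %in% two$stage))
  bestFull <- full[which.min(full$p), ]
  bestTwo <- two[which.min(two$p), ]
  expect_equal(bestTwo$chrom, bestFull$chrom)
  expect_lt(abs(bestTwo$cM - bestFull$cM), 1)
  # fine-stage statistics equal full-scan statistics at the same spots
  fine <- two[two$stage == "fine", ]
  shared <- merge(fine, full, by = c("chrom", "cM"))
  expect_gt(nrow(shared), 0L)
  expect_equal(shared$W.x, shared$W.y, tolerance = 1e-8)
  # a chromosome with fewer coarse positions than topK still works
  twoSmall <- twoStepScan(w$fields, w$psi, y, w$map, coarseCM = 4,
                          fineCM = 1, topK = 50L, windowCM = 2)
  expect_true(nrow(twoSmall) > 0L)
})

test_that("the single-variant comparator matches the textbook t-test", {
  # hand-computable 6-observation regression
  q <- c(0L, 1L, 2L, 0L, 1L, 2L)
  y <- c(0.1, 1.2, 2.3, -0.2, 0.9, 2.2)
  # haplotype rows per sample giving the dosages above
  H <- rbind(c(0L), c(0L), c(1L), c(0L), c(1L), c(1L),
             c(0L), c(0L), c(1L), c(0L), c(1L), c(1L))
  map <- geneticMap("1", bp = c(1, 2), cM = c(0, 0.001))
  haps <- phasedHaplotypes(H, samples = sprintf("S%d", 1:6), chrom = "1",
                           pos = 1L, map = map)
  expect_equal(as.vector(minorDosage(haps, 1L)), q)
  sv <- singleVariantComparator(haps, y)
  fit <- summary(lm(y ~ q))
  expect_equal(sv$minP, fit$coefficients["q", "Pr(>|t|)"],
               tolerance = 1e-10)
  # constructed winner: phenotype = 2 x dosage of one marker + tiny noise
  set.seed(65)
  H2 <- matrix(rbinom(40 * 20, 1L, 0.4), 40L, 20L)
  haps2 <- phasedHaplotypes(H2, samples = sprintf("S%d", 1:20),
                            chrom = "1",
                            pos = round(seq(1, 2e6, length.out = 20)),
                            map = geneticMap("1", c(1, 2e6), c(0, 2)))
  q7 <- as.vector(minorDosage(haps2, 7L))
  y2 <- 2 * q7 + rnorm(20, sd = 0.01)
  sv2 <- singleVariantComparator(haps2, y2)
  expect_equal(sv2$bestIdx, 7L)
  # monomorphic markers are skipped
  H3 <- cbind(H2, 0L)
  haps3 <- phasedHaplotypes(H3, samples = sprintf("S%d", 1:20),
                            chrom = "1",
                            pos = c(haps2@pos, 3e6),
                            map = geneticMap("1", c(1, 3e6), c(0, 3)))
  expect_message(sv3 <- singleVariantComparator(haps3, y2), "monomorphic")
  expect_equal(sv3$n, 20L)
})

test_that("null min-p behaves like an order statistic across markers", {
  set.seed(67)
  n <- 60
  H <- matrix(rbinom(2 * n * 20, 1L, 0.3), 2L * n, 20L)
  haps <- phasedHaplotypes(H, samples = sprintf("S%d", seq_len(n)),
                           chrom = "1",
                           pos = round(seq(1, 2e6, length.out = 20)),
                           map = geneticMap("1", c(1, 2e6), c(0, 2)))
  minps <- vapply(1:120, function(r)
    singleVariantComparator(haps, rnorm(n))$minP, numeric(1L))
  # stochastically bounded below by Beta(1, 20): median comparison
  expect_gt(median(minps), qbeta(0.5, 1, 20) * 0.5)
  expect_lt(mean(minps <= 0.05 / 20), 0.15)
})

test_that("type-I-error experiments reject at the right order of
           magnitude and reproduce from their seed", {
  w <- scanWorld(N = 100, nPos = 41, spacing = 0.25, seed = 71,
                 persist = 8L)
  ex <- type1Experiment(w$fields, w$psi, nReplicates = 30L, seed = 72,
                        spacingCM = 0.25, ouReps = 4000L)
  expect_s3_class(ex$replicates, "data.frame")
  expect_equal(nrow(ex$replicates), 30L)
  expect_true(all(ex$rates$rate >= 0 & ex$rates$rate <= 1))
  # Bonferroni never rejects more than the OU-based threshold
  expect_lte(ex$rates$rate[ex$rates$method == "bonferroni"],
             ex$rates$rate[ex$rates$method == "ou"])
  # positive dependence keeps the threshold above Bonferroni
  # (small slack for Monte-Carlo noise in the threshold itself)
  expect_true(all(ex$replicates$pStar > 0.95 * 0.05 / 82))
  expect_true(all(ex$replicates$pStar < 0.05))
  # reproducible end to end
  ex2 <- type1Experiment(w$fields, w$psi, nReplicates = 30L, seed = 72,
                         spacingCM = 0.25, ouReps = 4000L)
  expect_identical(ex$replicates, ex2$replicates)
})
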