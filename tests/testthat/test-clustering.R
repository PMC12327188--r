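test_that("maximal sharing yields one cluster, no sharing all singletons", {
  map <- geneticMap("1", bp = c(1, 10e6), cM = c(0, 10))
  n <- 12
  # all haplotypes identical over the whole chromosome
  H <- matrix(rep(sample(0:1, 200, TRUE), each = n), n, 200)
  pos <- round(seq(1, 10e6, length.out = 200))
  haps <- phasedHaplotypes(H, samples = sprintf("S%d", 1:(n / 2)),
                           chrom = "1", pos = pos, map = map)
  pr <- clusteringParams(2, 0.5)
  for (f in c(0, 3.7, 10)) {
    cl <- clusterMatrix(clusterAtPosition(haps, map, pr, f))[1L, ]
    expect_equal(length(unique(cl)), 1L)
  }
  # pairwise distinct at every marker -> all singletons
  H2 <- matrix(0:9, 10L, 200)
  haps2 <- phasedHaplotypes(H2, samples = sprintf("S%d", 1:5),
                            chrom = "1", pos = pos, map = map)
  cl2 <- clusterMatrix(clusterAtPosition(haps2, map, pr, 5))[1L, ]
  expect_equal(length(unique(cl2)), 10L)
  expect_error(clusterAtPosition(haps, map, pr, 11), "outside")
})

test_that("clusters merge transitively even without a common pairwise window", {
  # A==B on [0,3], B==C on [2,5]; L=2, T=0.5, focal 2.5 -> all merged
  map <- geneticMap("1", bp = c(1, 10e6), cM = c(0, 10))
  M <- 500
  cm <- seq(0, 10, length.out = M)
  set.seed(5)
  A <- sample(0:1, M, TRUE)
  B <- sample(0:1, M, TRUE)
  C <- sample(0:1, M, TRUE)
  D <- sample(0:1, M, TRUE)
  B[cm <= 3.05] <- A[cm <= 3.05]   # small margin so the marker grid
  C[cm >= 1.95 & cm <= 5.05] <- B[cm >= 1.95 & cm <= 5.05]  # covers [0,3], [2,5]
  H <- rbind(A, B, C, D)
  haps <- phasedHaplotypes(H, samples = c("S1", "S2"), chrom = "1",
                           pos = round(cm * 1e6) + 1, map = map)
  cl <- clusterMatrix(clusterAtPosition(haps, map, clusteringParams(2, 0.5),
                                        2.5))[1L, ]
  expect_equal(cl[1L], cl[2L])
  expect_equal(cl[2L], cl[3L])
  expect_false(cl[4L] == cl[1L])
  # sanity: A and C share no 2 cM window around 2.5 directly
  runAC <- rle(A == C)
  expect_true(max(runAC$lengths[runAC$values]) < sum(cm <= 2))
})

test_that("clustering matches the brute-force oracle across all settings", {
  pan <- sharedSegmentPanel(nHap = 40, nMarkers = 1000, nShared = 30)
  Hint <- pan$H
  for (L in c(2, 3)) {
    for (T in c(0.25, 0.5, 1)) {
      pr <- clusteringParams(L, T)
      for (f in c(0.05, 2.5, 5, 9.95)) {
        got <- clusterMatrix(clusterAtPosition(pan$haps, pan$map, pr,
                                               f))[1L, ]
        focal <- which.min(abs(pan$cm - f))
        want <- bruteForceClusters(Hint, pan$cm, focal, L, T)
        expect_true(sameClustering(got, want),
                    label = sprintf("L=%g T=%g focal=%g", L, T, f))
      }
    }
  }
})

test_that("increasing L or T only refines the partition", {
  pan <- sharedSegmentPanel(nHap = 30, nMarkers = 800, nShared = 25,
                            seed = 19)
  refines <- function(fine, coarse) {
    all(vapply(split(seq_along(fine), fine), function(g)
      length(unique(coarse[g])) == 1L, logical(1L)))
  }
  base <- clusterMatrix(clusterAtPosition(pan$haps, pan$map,
                                          clusteringParams(2, 0.25), 5))[1L, ]
  for (pr in list(clusteringParams(2, 0.5), clusteringParams(3, 0.25),
                  clusteringParams(3, 1))) {
    stricter <- clusterMatrix(clusterAtPosition(pan$haps, pan$map, pr,
                                                5))[1L, ]
    expect_true(refines(stricter, base))
  }
})

test_that("the grid scan covers the chromosome and matches per-position calls", {
  pan <- sharedSegmentPanel(nHap = 16, nMarkers = 400, nShared = 10,
                            seed = 23)
  pr <- clusteringParams(2, 0.5)
  fields <- clusterFieldScan(pan$haps, pan$map, pr, spacingCM = 0.1)
  expect_equal(length(fields), 101L)
  for (i in c(1L, 35L, 101L)) {
    single <- clusterAtPosition(pan$haps, pan$map, pr, fields@cM[i])
    expect_true(sameClustering(fields[i], single))
  }
  # spacing larger than the chromosome -> single field at the start
  one <- clusterFieldScan(pan$haps, pan$map, pr, spacingCM = 50)
  expect_equal(length(one), 1L)
  expect_equal(one@cM, 0)
})

test_that("pairwise segment detection matches the all-pairs run oracle", {
  pan <- sharedSegmentPanel(nHap = 20, nMarkers = 500, nShared = 15,
                            seed = 11, lenRange = c(1.5, 5))
  par <- pairwiseDetectorParams(minSeedCM = 0.5, minExtendCM = 0.2,
                                minOutputCM = 2, minMinorAlleleCount = 2,
                                minSeedMarkers = 1L)
  segs <- detectPairwiseSegments(pan$haps, pan$map, par)
  H <- pan$H; cm <- pan$cm; n <- nrow(H)
  af <- colMeans(H)
  keep <- which(pmin(af, 1 - af) * n >= 2)
  oracle <- character(0)
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    if ((a - 1L) %/% 2L == (b - 1L) %/% 2L) next
    r <- rle(H[a, keep] == H[b, keep])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      l <- keep[starts[i]]; rr <- keep[ends[i]]
      if (cm[rr] - cm[l] >= 2)
        oracle <- c(oracle, paste(a, b, round(cm[l] * 1e6) + 1,
                                  round(cm[rr] * 1e6) + 1))
    }
  }
  hapRow <- function(s, h) 2L * (as.integer(sub("S", "", s)) - 1L) + h
  got <- with(segs, paste(hapRow(sample1, hap1), hapRow(sample2, hap2),
                          start_bp, end_bp))
  expect_setequal(got, oracle)
})

test_that("short shared runs fall below the output threshold", {
  # two haplotypes identical over cM [1, 6] -> one 5 cM segment;
  # identical over only 1.5 cM -> nothing
  map <- geneticMap("1", bp = c(1, 10e6), cM = c(0, 10))
  M <- 1000
  cm <- seq(0.005, 9.995, length.out = M)
  set.seed(31)
  H <- matrix(sample(0:1, 4 * M, TRUE), 4, M)
  H[3, cm >= 1 & cm <= 6] <- H[1, cm >= 1 & cm <= 6]
  haps <- phasedHaplotypes(H, samples = c("S1", "S2"), chrom = "1",
                           pos = round(cm * 1e6) + 1, map = map)
  par <- pairwiseDetectorParams(minSeedCM = 0.5, minOutputCM = 2,
                                minMinorAlleleCount = 1, minSeedMarkers = 1L)
  segs <- detectPairwiseSegments(haps, map, par)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$length_cM, 5, tolerance = 0.05)
  H[3, ] <- sample(0:1, M, TRUE)
  H[3, cm >= 4 & cm <= 5.5] <- H[1, cm >= 4 & cm <= 5.5]
  haps2 <- phasedHaplotypes(H, samples = c("S1", "S2"), chrom = "1",
                            pos = round(cm * 1e6) + 1, map = map)
  expect_equal(nrow(detectPairwiseSegments(haps2, map, par)), 0L)
})
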