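test_that("phased VCF reading transcribes genotypes and preserves order", {
  path <- writeTestVcf()
  haps <- readPhasedVcf(path)
  expect_s4_class(haps, "PhasedHaplotypes")
  expect_equal(nSamples(haps), 2L)
  expect_equal(nMarkers(haps), 3L)
  A <- alleleMatrix(haps)
  expect_equal(dim(A), c(4L, 3L))
  # S1 rows 1-2, S2 rows 3-4; columns in VCF order
  expect_equal(A[, 1L], c(0L, 1L, 1L, 1L))
  expect_equal(A[, 2L], c(0L, 0L, 0L, 1L))
  expect_equal(A[, 3L], c(1L, 0L, 0L, 0L))
  expect_equal(markerTable(haps)$pos, c(100, 250, 900))
})

test_that("empty region query returns a 2N x 0 matrix without error", {
  haps <- readPhasedVcf(writeTestVcf(), region = "1:5000-6000")
  expect_equal(nMarkers(haps), 0L)
  expect_equal(nrow(haps@alleles), 4L)
  haps2 <- readPhasedVcf(writeTestVcf(), region = "1:200-1000")
  expect_equal(nMarkers(haps2), 2L)
})

test_that("missing and unphased genotypes are hard errors naming the site", {
  miss <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
            "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t./.")
  expect_error(readPhasedVcf(writeTestVcf(miss)), "100")
  unph <- sub("\\./\\.", "0/1", miss)
  expect_error(readPhasedVcf(writeTestVcf(unph)), "unphased")
})

test_that("VCF write/read round-trips the allele matrix", {
  pan <- sharedSegmentPanel(nHap = 8, nMarkers = 50, nShared = 2)
  path <- tempfile(fileext = ".vcf")
  writePhasedVcf(pan$haps, path)
  back <- readPhasedVcf(path, map = pan$map)
  expect_equal(alleleMatrix(back), alleleMatrix(pan$haps))
  expect_equal(back@pos, pan$haps@pos)
  expect_equal(back@samples, pan$haps@samples)
})

test_that("cM interpolation is piecewise linear with clamped ends", {
  gm <- geneticMap(chrom = "1", bp = c(100, 300), cM = c(0, 2))
  expect_equal(interpolateCM(gm, "1", 200), 1.0)
  expect_equal(interpolateCM(gm, "1", 100), 0.0)
  expect_equal(interpolateCM(gm, "1", 500), 2.0)  # clamped
  expect_equal(interpolateCM(gm, "1", 50), 0.0)   # clamped low
  expect_error(interpolateCM(gm, "2", 100), "not present")
  # vectorized, interior linearity
  expect_equal(interpolateCM(gm, "1", c(150, 250)), c(0.5, 1.5))
})

test_that("genetic map files round-trip in both layouts", {
  gm <- geneticMap(chrom = rep(c("1", "2"), each = 3L),
                   bp = rep(c(1, 5e5, 2e6), 2L),
                   cM = c(0, 0.61, 2.2, 0, 0.4, 1.9))
  for (fmt in c("plink", "decode")) {
    p <- tempfile()
    writeGeneticMap(gm, p, format = fmt)
    back <- readGeneticMap(p, format = fmt)
    expect_equal(back@map$bp, gm@map$bp)
    expect_equal(back@map$cM, gm@map$cM, tolerance = 1e-6)
  }
})

test_that("cluster fields round-trip through the TSV format", {
  cl <- matrix(c(1L, 1L, 2L, 3L, 2L, 2L,
                 7L, 7L, 2L, 2L, 5L, 5L), nrow = 2L, byrow = TRUE)
  fields <- clusterFieldSet(cl, chrom = "1", bp = c(1e5, 2e5),
                            cM = c(0.1, 0.2),
                            samples = c("A", "B", "C"))
  p <- tempfile(fileext = ".tsv")
  writeClusterFields(fields, p)
  back <- readClusterFields(p)
  expect_equal(clusterMatrix(back), clusterMatrix(fields))
  expect_equal(back@cM, fields@cM, tolerance = 1e-9)
  expect_true(sameClustering(back[1L], fields[1L]))
})

test_that("cluster-field rows with the wrong identifier count are errors", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tbp\tcM\tA_1\tA_2\tB_1\tB_2\tC_1\tC_2",
               "1\t100\t0.1\t1\t1\t2\t3\t2\t2",
               "1\t200\t0.2\t1\t1\t2\t3\t2"), p)
  expect_error(readClusterFields(p), "line 3")
})

test_that("cluster-field equality is partition equality", {
  expect_true(sameClustering(c(0L, 0L, 1L), c(7L, 7L, 2L)))
  expect_false(sameClustering(c(0L, 0L, 1L), c(7L, 2L, 2L)))
  expect_equal(canonicalClusterIds(c(9L, 9L, 4L, 9L)), c(1L, 1L, 2L, 1L))
})

test_that("IBD segment tables read with recomputed lengths and checks", {
  gm <- uniformGeneticMap(c("1" = 100))
  p <- tempfile()
  writeLines("S1\t1\tS2\t2\t1\t10000001\t15000001\t5.0", p)
  segs <- readIbdSegments(p, gm)
  expect_equal(segs$length_cM, 5.0)
  # missing length column, recomputed from map
  writeLines("S1\t1\tS2\t2\t1\t10000001\t15000001", p)
  segs2 <- readIbdSegments(p, gm)
  expect_equal(segs2$length_cM, 5.0, tolerance = 1e-6)
  # empty file
  file.create(p2 <- tempfile())
  expect_equal(nrow(readIbdSegments(p2, gm)), 0L)
  # duplicated pair, two disjoint segments: both retained
  writeLines(c("S1\t1\tS2\t2\t1\t10000001\t15000001\t5",
               "S1\t1\tS2\t2\t1\t30000001\t33000001\t3"), p)
  expect_equal(nrow(readIbdSegments(p, gm)), 2L)
  # negative-length segment
  writeLines("S1\t1\tS2\t2\t1\t15000001\t10000001\t-5", p)
  expect_error(readIbdSegments(p, gm))
})

test_that("kinship tables validate range and self-pairs", {
  p <- tempfile()
  writeLines(c("sample1\tsample2\tkinship", "A\tB\t0.25", "A\tC\t0.03"), p)
  kin <- readKinship(p)
  expect_equal(kin$kinship, c(0.25, 0.03))
  writeLines(c("sample1\tsample2\tkinship", "A\tA\t0.25"), p)
  expect_error(readKinship(p), "self-pairs")
  writeLines(c("sample1\tsample2\tkinship", "A\tB\t0.7"), p)
  expect_error(readKinship(p), "0.5")
})
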