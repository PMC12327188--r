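library(Matrix)

test_that("allocation matrix counts haplotype proportions", {
  # N=2: (hapA1, hapB1) cluster c1, hapA2 = c2, hapB2 = c3
  ids <- c(1L, 2L, 1L, 3L)
  A <- allocationMatrix(ids, dropSingletons = FALSE)
  expect_equal(dim(A), c(2L, 3L))
  expect_equal(as.matrix(A),
               matrix(c(0.5, 0.5, 0.5, 0, 0, 0.5), 2L, 3L),
               ignore_attr = TRUE)
  # both haplotypes of one individual in the same cluster -> entry 1
  A2 <- allocationMatrix(c(4L, 4L, 1L, 2L), dropSingletons = FALSE)
  expect_equal(max(A2), 1)
})

test_that("the local IBD matrix is 2AA' with forced unit diagonal", {
  ids <- c(1L, 2L, 1L, 3L)
  Phi <- localIBDMatrix(ids)
  expect_equal(Phi[1L, 2L], 0.5)  # 2 * (1/2 * 1/2)
  expect_equal(diag(as.matrix(Phi)), rep(1, 2L), ignore_attr = TRUE)
  # complete sharing -> off-diagonal 1
  Phi2 <- localIBDMatrix(c(1L, 2L, 1L, 2L))
  expect_equal(Phi2[1L, 2L], 1)
  # all singletons -> identity
  Phi3 <- localIBDMatrix(c(1L, 2L, 3L, 4L))
  expect_equal(as.matrix(Phi3), diag(2L), ignore_attr = TRUE)
})

test_that("dropping singleton columns never changes off-diagonals", {
  set.seed(41)
  for (rep in 1:5) {
    n2 <- 60
    ids <- sample.int(40, n2, replace = TRUE)
    full <- 2 * tcrossprod(allocationMatrix(ids, dropSingletons = FALSE))
    slim <- localIBDMatrix(ids)
    fullOff <- as.matrix(full); diag(fullOff) <- 1
    expect_equal(as.matrix(slim), pmin(fullOff, 1), ignore_attr = TRUE)
  }
})

test_that("local IBD matrices are symmetric PSD with entries in [0,1]", {
  set.seed(43)
  for (rep in 1:10) {
    # outbred-valid assignment: an individual's two haplotypes are in
    # distinct clusters (self-IBD is out of the model's domain)
    ids <- as.vector(vapply(seq_len(25), function(i)
      sample.int(18, 2L), integer(2L)))
    Phi <- localIBDMatrix(ids)
    expect_equal(max(abs(Phi - Matrix::t(Phi))), 0)
    expect_true(all(Phi@x >= 0 & Phi@x <= 1))
    ev <- min(eigen(as.matrix(Phi), symmetric = TRUE,
                    only.values = TRUE)$values)
    expect_gte(ev, -1e-10)
  }
})

test_that("region matrices are elementwise means with preserved properties", {
  fieldsEq <- clusterFieldSet(rbind(c(1L, 1L, 2L, 2L), c(5L, 5L, 9L, 9L)),
                              chrom = "1", bp = c(1, 2), cM = c(0, 0.05),
                              samples = c("A", "B"))
  R <- regionIBDMatrix(fieldsEq)  # same partition at both ends
  expect_equal(as.matrix(R), as.matrix(localIBDMatrix(fieldsEq[1L])))
  # identity + complete sharing -> mean 1/2
  mats <- list(Diagonal(2L), localIBDMatrix(c(1L, 2L, 1L, 2L)))
  R2 <- regionIBDMatrix(mats)
  expect_equal(R2[1L, 2L], 0.5)
  expect_equal(diag(as.matrix(R2)), rep(1, 2L), ignore_attr = TRUE)
  ev <- min(eigen(as.matrix(R2), symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(ev, -1e-12)
})

test_that("the global IBD matrix doubles and thresholds kinship", {
  kinEmpty <- data.frame(sample1 = character(0), sample2 = character(0),
                         kinship = numeric(0))
  expect_equal(as.matrix(globalIBDMatrix(kinEmpty, c("A", "B"))), diag(2L),
               ignore_attr = TRUE)
  kin <- data.frame(sample1 = c("A", "A"), sample2 = c("B", "C"),
                    kinship = c(0.25, 0.04))
  Psi <- globalIBDMatrix(kin, c("A", "B", "C"))
  expect_equal(Psi[1L, 2L], 0.5)
  expect_equal(Psi[1L, 3L], 0)      # below the 0.044 cutoff
  expect_equal(diag(as.matrix(Psi)), rep(1, 3L), ignore_attr = TRUE)
  bad <- data.frame(sample1 = "A", sample2 = "B", kinship = 0.6)
  expect_error(globalIBDMatrix(bad, c("A", "B")), "0.5")
})

test_that("kinship from segments follows the IBD1/IBD2 proportions", {
  gm <- uniformGeneticMap(stats::setNames(rep(100, 3), c("1", "2", "3")))
  seg <- function(s1, h1, s2, h2, ch, s, e)
    data.frame(sample1 = s1, hap1 = h1, sample2 = s2, hap2 = h2,
               chrom = ch, start_bp = s * 1e6 + 1, end_bp = e * 1e6 + 1,
               length_cM = e - s)
  # one combination over the full genome -> p1 = 1, kinship 0.25
  full <- do.call(rbind, lapply(c("1", "2", "3"), function(ch)
    seg("A", 1L, "B", 1L, ch, 0, 100)))
  expect_equal(kinshipFromSegments(full, gm)$kinship, 0.25, tolerance = 1e-9)
  # IBD2 genome-wide -> kinship 0.5
  full2 <- rbind(full, do.call(rbind, lapply(c("1", "2", "3"), function(ch)
    seg("A", 2L, "B", 2L, ch, 0, 100))))
  expect_equal(kinshipFromSegments(full2, gm)$kinship, 0.5, tolerance = 1e-9)
  # one 30 cM segment on a 300 cM genome -> kinship 0.025
  one <- seg("A", 1L, "B", 2L, "2", 10, 40)
  expect_equal(kinshipFromSegments(one, gm)$kinship, 0.025, tolerance = 1e-6)
  # overlapping duplicate segments merge before proportions
  dup <- rbind(one, seg("A", 1L, "B", 2L, "2", 20, 50))
  expect_equal(kinshipFromSegments(dup, gm)$kinship, 40 / 300 / 4,
               tolerance = 1e-6)
})

test_that("block partition equals graph connected components", {
  # hand case: single off-diagonal link
  Psi <- sparseMatrix(i = 1L, j = 2L, x = 0.5, dims = c(4L, 4L),
                      symmetric = TRUE)
  diag(Psi) <- 1
  bp <- blockPartition(Psi, NULL)
  expect_equal(sort(lengths(bp), decreasing = TRUE), c(2L, 1L, 1L))
  expect_true(any(vapply(bp, function(b) setequal(b, 1:2), logical(1L))))
  # psi = phi = identity -> N singletons
  expect_equal(lengths(blockPartition(Diagonal(5L), Diagonal(5L))),
               rep(1L, 5L))
  # random sparse fixtures agree with igraph's components
  skip_if_not_installed("igraph")
  set.seed(47)
  for (rep in 1:5) {
    N <- 30L
    E <- cbind(sample.int(N, 15, TRUE), sample.int(N, 15, TRUE))
    E <- E[E[, 1L] != E[, 2L], , drop = FALSE]
    M <- sparseMatrix(i = pmin(E[, 1L], E[, 2L]),
                      j = pmax(E[, 1L], E[, 2L]), x = 1,
                      dims = c(N, N), symmetric = TRUE, use.last.ij = TRUE)
    diag(M) <- 1
    got <- blockPartition(M, NULL)
    g <- igraph::graph_from_edgelist(E, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, N - max(E)))
    want <- unname(split(seq_len(N), igraph::components(g)$membership))
    key <- function(p) sort(vapply(p, function(b)
      paste(sort(b), collapse = ","), character(1L)))
    expect_equal(key(got), key(want))
  }
})
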