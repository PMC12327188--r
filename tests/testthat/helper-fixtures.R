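# Shared fixtures and independent oracles, built in code at test time.

# a small phased VCF fixture written to a temp file
writeTestVcf <- function(lines = NULL) {
  path <- tempfile(fileext = ".vcf")
  if (is.null(lines)) {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
      "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
      "1\t250\trs2\tG\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
      "1\t900\trs3\tT\tA\t.\tPASS\t.\tGT\t1|0\t0|0")
  }
  writeLines(lines, path)
  path
}

# random haplotype panel with implanted shared segments; returns a
# PhasedHaplotypes plus its map (chromosome 0-10 cM, uniform 1 cM/Mb)
sharedSegmentPanel <- function(nHap = 40, nMarkers = 1000, nShared = 30,
                               seed = 7, lenRange = c(1, 4)) {
  set.seed(seed)
  cm <- sort(runif(nMarkers, 0, 10))
  H <- matrix(sample(0:1, nHap * nMarkers, TRUE), nHap, nMarkers)
  for (k in seq_len(nShared)) {
    a <- sample(nHap, 1L)
    b <- sample(setdiff(seq_len(nHap), a), 1L)
    s <- runif(1, 0, 10 - lenRange[2L])
    e <- s + runif(1, lenRange[1L], lenRange[2L])
    idx <- which(cm >= s & cm <= e)
    H[b, idx] <- H[a, idx]
  }
  map <- geneticMap("1", bp = c(1, 10e6), cM = c(0, 10))
  list(haps = phasedHaplotypes(H, samples = sprintf("S%d",
                                                    seq_len(nHap / 2)),
                               chrom = "1", pos = round(cm * 1e6) + 1,
                               map = map),
       map = map, H = H, cm = cm)
}

# independent brute-force clustering oracle: test every haplotype pair
# against the L/T window criterion, then transitive closure
bruteForceClusters <- function(H, cm, focal, L, T) {
  n <- nrow(H); M <- ncol(H)
  parent <- seq_len(n)
  findRoot <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  fcm <- cm[focal]
  rT <- which(cm >= fcm + T)[1L]; if (is.na(rT)) rT <- M
  lhits <- which(cm <= fcm - T)
  lT <- if (length(lhits)) max(lhits) else 1L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (any(H[a, lT:rT] != H[b, lT:rT])) next
      l <- lT; r <- rT
      while (l > 1L && H[a, l - 1L] == H[b, l - 1L]) l <- l - 1L
      while (r < M && H[a, r + 1L] == H[b, r + 1L]) r <- r + 1L
      if (cm[r] - cm[l] >= L) {
        ra <- findRoot(a); rb <- findRoot(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  vapply(seq_len(n), findRoot, integer(1L))
}

# dense restricted log-likelihood, independent of the package's block
# implementation
denseRemlLL <- function(y, X, Psi, Phi, sa, sq, se) {
  N <- length(y); p <- ncol(X)
  V <- sa * Psi + sq * Phi + se * diag(N)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(-Inf)
  C <- t(X) %*% Vi %*% X
  beta <- tryCatch(solve(C, t(X) %*% Vi %*% y), error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  r <- y - X %*% beta
  as.numeric(-((N - p) / 2) * log(2 * pi) -
               0.5 * determinant(V)$modulus -
               0.5 * determinant(C)$modulus - 0.5 * t(r) %*% Vi %*% r)
}

# grid-then-polish REML maximizer over the variance parameters (dense):
# a wide log-spaced grid, then Nelder-Mead polish (with one restart) from
# the three best grid points, keeping the overall best.  The surface is
# multimodal with boundary modes, so the polish must be multi-started.
gridPolishREML <- function(y, X, Psi, Phi, fixQ = FALSE) {
  vy <- var(y)
  gr <- vy * c(0.002, 0.01, 0.05, 0.15, 0.3, 0.6, 1, 1.5, 2.5)
  qs <- if (fixQ) 0 else gr
  cand <- expand.grid(sa = gr, sq = qs, se = gr)
  cand$ll <- mapply(function(sa, sq, se)
    denseRemlLL(y, X, Psi, Phi, sa, sq, se),
    cand$sa, cand$sq, cand$se)
  cand <- cand[order(-cand$ll), , drop = FALSE]
  eps <- 1e-9 * vy
  polish <- function(par) {
    obj <- if (fixQ) {
      function(p) -denseRemlLL(y, X, Psi, Phi, exp(p[1L]), 0, exp(p[2L]))
    } else {
      function(p) -denseRemlLL(y, X, Psi, Phi, exp(p[1L]), exp(p[2L]),
                               exp(p[3L]))
    }
    p0 <- log(pmax(if (fixQ) par[c(1L, 3L)] else par, eps))
    o <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    -o$value
  }
  max(vapply(seq_len(min(8L, nrow(cand))), function(k)
    polish(as.numeric(cand[k, c("sa", "sq", "se")])), numeric(1L)))
}

# small structured test problem for the variance-component test
smallVCProblem <- function(N = 30, seed = 3, clusteredFraction = 0.5) {
  fx <- generateStructuredFixture(
    N, structuredClusterSpec(clusteredFraction = clusteredFraction),
    seed = seed)
  Phi <- localIBDMatrix(fx$fields[1L])
  Psi <- globalIBDMatrix(fx$kinship, fx$samples)
  list(fx = fx, Phi = Phi, Psi = Psi)
}
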