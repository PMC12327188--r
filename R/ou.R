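#' Correlation between scan statistics under the modified OU model
#'
#' For standardized statistics Z following a stationary
#' Ornstein-Uhlenbeck process with autocorrelation
#' \eqn{\rho = e^{-\alpha d}} at distance d cM, the observed statistics
#' are \eqn{W = Z^2 1\{Z > 0\}}.  With E W = 1/2 and Var W = 5/4,
#' bivariate-normal quadrant moments give the closed form
#' \deqn{f(\rho) = \frac{2\pi\rho^2 + 6\rho\sqrt{1-\rho^2}
#'       + (2+4\rho^2)\arcsin\rho}{5\pi},}
#' which is continuous, strictly increasing, with f(0) = 0 and f(1) = 1.
#' (The derivation is certified against a Monte-Carlo oracle in the test
#' suite.)
#'
#' @param alpha decay parameter (> 0); ignored when \code{rho} is given.
#' @param d non-negative distance(s) in cM.
#' @param rho optionally, the latent correlation(s) directly.
#' @return correlation(s) of W at the given separation, in [0, 1].
#' @export
modifiedOUCorr <- function(alpha = NULL, d = NULL, rho = NULL) {
  if (is.null(rho)) {
    if (is.null(alpha) || is.null(d))
      stop("supply either rho or both alpha and d")
    if (any(d < 0)) stop("distances must be non-negative")
    if (alpha <= 0) stop("alpha must be positive")
    rho <- exp(-alpha * d)
  }
  stopifnot(all(rho >= -1e-12 & rho <= 1 + 1e-12))
  rho <- pmin(pmax(rho, 0), 1)
  (2 * pi * rho^2 + 6 * rho * sqrt(pmax(0, 1 - rho^2)) +
     (2 + 4 * rho^2) * asin(rho)) / (5 * pi)
}

#' Invert the modified-OU correlation
#'
#' Solves f(rho) = fHat for rho in [0, 1] by bisection (f is continuous
#' and strictly increasing).  Values outside the attainable range [0, 1]
#' are clamped with a warning.
#'
#' @param fHat observed correlation(s) between W statistics.
#' @param tol bisection tolerance.
#' @return rho estimate(s) in [0, 1].
#' @export
invertCorr <- function(fHat, tol = 1e-10) {
  fHat <- as.numeric(fHat)
  if (any(fHat < 0 | fHat > 1)) {
    warning("observed correlation outside [0, 1]; clamping")
    fHat <- pmin(pmax(fHat, 0), 1)
  }
  lo <- rep(0, length(fHat)); hi <- rep(1, length(fHat))
  for (it in seq_len(ceiling(log2(1 / tol)) + 2L)) {
    mid <- (lo + hi) / 2
    below <- modifiedOUCorr(rho = mid) < fHat
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# per-chromosome, per-lag sufficient statistics of lagged pairs
# (n, sum x, sum y, sum x^2, sum y^2, sum xy), additive across chromosomes
lagSufficientStats <- function(stats, maxLag) {
  lapply(stats, function(w) {
    t(vapply(seq_len(maxLag), function(h) {
      n <- length(w) - h
      if (n < 1L) return(rep(0, 6))
      x <- w[seq_len(n)]; y <- w[seq_len(n) + h]
      c(n, sum(x), sum(y), sum(x^2), sum(y^2), sum(x * y))
    }, numeric(6L)))
  })
}

corFromStats <- function(s) {
  # s: maxLag x 6 pooled sufficient statistics
  n <- s[, 1L]
  cov <- s[, 6L] / n - (s[, 2L] / n) * (s[, 3L] / n)
  vx <- s[, 4L] / n - (s[, 2L] / n)^2
  vy <- s[, 5L] / n - (s[, 3L] / n)^2
  cov / sqrt(vx * vy)
}

#' Estimate the OU decay parameter from null scan statistics
#'
#' For each lag distance d (multiples of the grid spacing up to
#' \code{maxLagCM}), pools all within-chromosome pairs of statistics
#' spaced d apart (never straddling a chromosome boundary), computes
#' their sample correlation, inverts the modified-OU correlation to
#' \eqn{\hat\rho(d)}, and estimates alpha as the slope of the
#' no-intercept regression of \eqn{-\log\hat\rho(d)} on d.
#'
#' @param stats list of numeric vectors, one per chromosome: W statistics
#'   on a regular grid under the null hypothesis.
#' @param spacing grid spacing in cM.
#' @param maxLagCM largest lag distance used (default 1 cM).
#' @return list with alphaHat, and a data.frame (d, fHat, rhoHat) of the
#'   lag profile; lags with rhoHat = 0 are dropped with a warning.
#' @export
estimateAlpha <- function(stats, spacing = 0.1, maxLagCM = 1) {
  if (!is.list(stats)) stats <- list(stats)
  maxLag <- max(1L, round(maxLagCM / spacing))
  suff <- lagSufficientStats(stats, maxLag)
  pooled <- Reduce(`+`, suff)
  fHat <- corFromStats(pooled)
  d <- seq_len(maxLag) * spacing
  rhoHat <- invertCorr(pmin(pmax(fHat, 0), 1))
  usable <- rhoHat > 0
  if (!all(usable))
    warning("dropping lag(s) with zero correlation estimate")
  dd <- d[usable]; rr <- rhoHat[usable]
  if (length(dd) == 0L) stop("no usable lags to estimate alpha")
  alphaHat <- sum(dd * (-log(rr))) / sum(dd^2)
  list(alphaHat = alphaHat,
       profile = data.frame(d = d, fHat = fHat, rhoHat = rhoHat))
}

#' Bootstrap confidence interval for the decay parameter
#'
#' Resamples chromosomes with replacement, recomputes pooled lag
#' correlations from per-chromosome sufficient statistics, re-estimates
#' alpha in each replicate, and returns the percentile interval.
#'
#' @param stats list of per-chromosome W vectors (>= 2 chromosomes).
#' @param spacing grid spacing in cM.
#' @param maxLagCM largest lag distance.
#' @param nBoot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed (deterministic given seed).
#' @return list with lower, upper, alphaHat, nBoot.
#' @export
bootstrapAlphaCI <- function(stats, spacing = 0.1, maxLagCM = 1,
                             nBoot = 10000L, level = 0.95, seed = 1L) {
  if (!is.list(stats) || length(stats) < 2L)
    stop("chromosome-resampling bootstrap needs at least 2 chromosomes")
  nChr <- length(stats)
  maxLag <- max(1L, round(maxLagCM / spacing))
  suff <- lagSufficientStats(stats, maxLag)
  # flatten to nChr x (6 maxLag) for fast resampled pooling
  flat <- t(vapply(suff, as.vector, numeric(6L * maxLag)))
  d <- seq_len(maxLag) * spacing
  point <- estimateAlpha(stats, spacing, maxLagCM)$alphaHat
  withSeed(seed, {
    idx <- matrix(sample.int(nChr, nBoot * nChr, replace = TRUE),
                  nrow = nBoot)
  })
  alphas <- vapply(seq_len(nBoot), function(b) {
    pooled <- matrix(colSums(flat[idx[b, ], , drop = FALSE]),
                     nrow = maxLag)
    fHat <- corFromStats(pooled)
    rhoHat <- invertCorr(pmin(pmax(fHat, 0), 1))
    usable <- which(rhoHat > 0)
    if (length(usable) == 0L) return(NA_real_)
    sum(d[usable] * (-log(rhoHat[usable]))) / sum(d[usable]^2)
  }, numeric(1L))
  qs <- quantile(alphas, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  list(lower = qs[1L], upper = qs[2L], alphaHat = point, nBoot = nBoot)
}

#' Simulate the modified OU process along a genome
#'
#' Per chromosome, generates a stationary Gaussian AR(1) sequence with
#' lag-one correlation \eqn{r = e^{-\alpha\,\mathrm{spacing}}}
#' (\eqn{Z_0 \sim N(0,1)}, \eqn{Z_{k+1} = rZ_k + \sqrt{1-r^2}\,\eta_k}),
#' independent across chromosomes, and returns
#' \eqn{W_k = Z_k^2 1\{Z_k > 0\}}.
#'
#' @param model an \linkS4class{OUModel}.
#' @param seed RNG seed.
#' @return list of per-chromosome W vectors.
#' @export
simulateModifiedOU <- function(model, seed = 1L) {
  withSeed(seed, {
    r <- exp(-model@alpha * model@spacing)
    lapply(model@chromLengths, function(len) {
      nPos <- floor(len / model@spacing) + 1L
      z <- numeric(nPos)
      z[1L] <- rnorm(1L)
      if (nPos > 1L) {
        eta <- rnorm(nPos - 1L) * sqrt(1 - r^2)
        for (k in seq_len(nPos - 1L)) z[k + 1L] <- r * z[k] + eta[k]
      }
      ifelse(z > 0, z^2, 0)
    })
  })
}

#' Genome-wide significance threshold by Monte-Carlo max statistics
#'
#' Simulates the modified OU process over the scanned genome, records the
#' per-replicate maximum of W, takes the \code{level} quantile of the
#' maxima as the genome-wide critical value W*, and converts it to the
#' per-test p-value threshold \eqn{p^* = \tfrac12\Pr(\chi^2_1 \ge W^*)}.
#'
#' @param model an \linkS4class{OUModel}.
#' @param nReplicates Monte-Carlo replicates (default 10,000).
#' @param level genome-wide significance quantile (default 0.95).
#' @param seed RNG seed (deterministic given seed).
#' @return list with Wstar, pStar, nReplicates, level.
#' @export
genomeThreshold <- function(model, nReplicates = 10000L, level = 0.95,
                            seed = 1L) {
  r <- exp(-model@alpha * model@spacing)
  nPos <- as.integer(floor(model@chromLengths / model@spacing) + 1L)
  maxima <- withSeed(seed, ou_max_sim_cpp(as.integer(nReplicates), r, nPos))
  Wstar <- quantile(maxima, level, names = FALSE)
  list(Wstar = Wstar, pStar = mixturePValue(Wstar),
       nReplicates = nReplicates, level = level)
}

# evaluate expr with a local, restored RNG state
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
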