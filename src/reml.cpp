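// Restricted-likelihood evaluation and REML fitting for the
// three-variance-component model V = sigma_a^2 Psi + sigma_Q^2 Phi +
// sigma_e^2 I, exploiting the block-diagonal sparsity of Psi + Phi.
// Likelihood:  l = const - 1/2 ln|V| - 1/2 ln|X'V^-1 X|
//                 - 1/2 (y - X b)' V^-1 (y - X b),  b the GLS estimate,
// const = -((N - p)/2) ln(2 pi), fixed across hypotheses.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Block {
  uvec idx;      // 0-based individual indices
  mat Psi, Phi;  // dense local copies
  mat X;
  vec y;
};

struct RemlData {
  std::vector<Block> blocks;
  uvec singles;
  mat Xs;              // singleton design rows
  vec ys;              // singleton responses
  mat SXX;             // sum over singletons of x x'
  vec SXy;
  double Syy;
  int N, p;
  double cst;
};

static RemlData buildData(const Rcpp::List &prep, const arma::mat &X,
                          const arma::vec &y) {
  RemlData d;
  d.N = y.n_elem;
  d.p = X.n_cols;
  d.cst = -0.5 * (d.N - d.p) * std::log(2.0 * M_PI);
  Rcpp::IntegerVector singles = prep["singles"];
  d.singles = zeros<uvec>(singles.size());
  for (int i = 0; i < singles.size(); ++i) d.singles[i] = singles[i] - 1;
  d.Xs = X.rows(d.singles);
  d.ys = y.elem(d.singles);
  d.SXX = d.Xs.t() * d.Xs;
  d.SXy = d.Xs.t() * d.ys;
  d.Syy = dot(d.ys, d.ys);
  Rcpp::List blocks = prep["blocks"];
  for (int b = 0; b < blocks.size(); ++b) {
    Rcpp::List bl = blocks[b];
    Block blk;
    Rcpp::IntegerVector idx = bl["idx"];
    blk.idx = zeros<uvec>(idx.size());
    for (int i = 0; i < idx.size(); ++i) blk.idx[i] = idx[i] - 1;
    blk.Psi = Rcpp::as<mat>(bl["Psi"]);
    blk.Phi = Rcpp::as<mat>(bl["Phi"]);
    blk.X = X.rows(blk.idx);
    blk.y = y.elem(blk.idx);
    d.blocks.push_back(blk);
  }
  return d;
}

// Evaluate restricted log-likelihood; if grad is non-null also the
// gradient with respect to (sa, sq, se) on the natural scale.
static double remlEval(const RemlData &d, double sa, double sq, double se,
                       vec *grad, bool *ok) {
  *ok = true;
  const int p = d.p;
  const double v1 = sa + sq + se;
  if (!(v1 > 0) || !std::isfinite(v1)) { *ok = false; return -datum::inf; }
  const int n1 = d.singles.n_elem;
  double ld = n1 * std::log(v1);
  mat C = d.SXX / v1;
  vec Xty = d.SXy / v1;
  double yty = d.Syy / v1;
  std::vector<mat> chols(d.blocks.size());
  for (size_t b = 0; b < d.blocks.size(); ++b) {
    const Block &blk = d.blocks[b];
    mat V = sa * blk.Psi + sq * blk.Phi;
    V.diag() += se;  // Psi, Phi carry unit diagonals already removed below
    mat L;
    if (!chol(L, V, "lower")) {
      V.diag() += 1e-10 * v1;
      if (!chol(L, V, "lower")) { *ok = false; return -datum::inf; }
    }
    chols[b] = L;
    mat Zx = solve(trimatl(L), blk.X);
    vec zy = solve(trimatl(L), blk.y);
    C += Zx.t() * Zx;
    Xty += Zx.t() * zy;
    yty += dot(zy, zy);
    ld += 2.0 * accu(log(L.diag()));
  }
  mat Lc;
  if (!chol(Lc, C, "lower")) { *ok = false; return -datum::inf; }
  double ldC = 2.0 * accu(log(Lc.diag()));
  vec beta = solve(trimatu(Lc.t()), solve(trimatl(Lc), Xty));
  double q = yty - dot(beta, Xty);
  double ll = d.cst - 0.5 * (ld + ldC + q);
  if (grad) {
    mat Cinv = inv_sympd(C);
    vec g(3, fill::zeros);
    // singletons: dV/dtheta = I for all three components
    double rss1 = d.Syy - 2.0 * dot(beta, d.SXy) +
                  as_scalar(beta.t() * d.SXX * beta);
    double tr1 = n1 / v1 - accu(Cinv % d.SXX) / (v1 * v1);
    double gs = -0.5 * tr1 + 0.5 * rss1 / (v1 * v1);
    g.fill(gs);
    for (size_t b = 0; b < d.blocks.size(); ++b) {
      const Block &blk = d.blocks[b];
      const mat &L = chols[b];
      mat Vinv = L.t();
      Vinv = inv(trimatu(Vinv));
      Vinv = Vinv * Vinv.t();  // V^-1 = L^-T L^-1
      vec r = blk.y - blk.X * beta;
      vec u = Vinv * r;
      mat W = Vinv * blk.X;
      const mat *dots[2] = { &blk.Psi, &blk.Phi };
      for (int k = 0; k < 2; ++k) {
        const mat &Vd = *dots[k];
        double trVV = accu(Vinv % Vd);
        mat M = W.t() * Vd * W;
        double trCM = accu(Cinv % M);
        g[k] += -0.5 * (trVV - trCM) + 0.5 * as_scalar(u.t() * Vd * u);
      }
      // dV/dse = I
      double trVV = trace(Vinv);
      mat M = W.t() * W;
      double trCM = accu(Cinv % M);
      g[2] += -0.5 * (trVV - trCM) + 0.5 * dot(u, u);
    }
    *grad = g;
  }
  return ll;
}

// objective on the log-variance scale over an active subset
struct LogObj {
  const RemlData *d;
  vec theta;        // full natural-scale parameters (sa, sq, se)
  uvec active;      // indices of free parameters
  double phiFloor;  // log-scale floor; a coordinate resting here with a
                    // negative gradient is an effective boundary zero
  double eval(const vec &phi, vec &gphi, bool &ok, bool wantGrad = true) {
    vec th = theta;
    for (uword i = 0; i < active.n_elem; ++i)
      th[active[i]] = std::exp(phi[i]);
    vec g3;
    double ll = remlEval(*d, th[0], th[1], th[2], wantGrad ? &g3 : nullptr,
                         &ok);
    if (wantGrad) {
      gphi.set_size(active.n_elem);
      if (ok)
        for (uword i = 0; i < active.n_elem; ++i)
          gphi[i] = g3[active[i]] * th[active[i]];
    }
    return ll;
  }
};

// BFGS maximization on the log-variance scale (deterministic).
static double bfgsMax(LogObj &obj, vec &phi, int maxIter, double tol,
                      bool &converged, int &iters) {
  const uword k = phi.n_elem;
  bool ok;
  vec g;
  phi = clamp(phi, obj.phiFloor, 700.0);
  double f = obj.eval(phi, g, ok);
  if (!ok) { converged = false; return -datum::inf; }
  mat H = eye(k, k);
  converged = false;
  int it = 0;
  int smallSteps = 0;  // consecutive near-zero improvements (flat ridges:
                       // the value converges long before the gradient on
                       // weakly identified parameter combinations)
  std::vector<double> fhist;
  for (; it < maxIter; ++it) {
    // boundary-aware stationarity: coordinates pinned at the floor with
    // a downhill gradient count as converged (the component is zero)
    double gmax = 0.0;
    for (uword j = 0; j < k; ++j) {
      if (phi[j] <= obj.phiFloor + 1e-9 && g[j] < 0) continue;
      gmax = std::max(gmax, std::abs(g[j]));
    }
    if (gmax < tol) { converged = true; break; }
    vec pdir = H * g;              // ascent direction
    if (dot(pdir, g) <= 0) { H = eye(k, k); pdir = g; }
    double t = 1.0, fNew = -datum::inf;
    vec phiNew, gNew;
    bool okNew = false;
    const double slope = dot(g, pdir);
    for (int ls = 0; ls < 50; ++ls) {
      phiNew = phi + t * pdir;
      phiNew = clamp(phiNew, obj.phiFloor, 700.0);
      fNew = obj.eval(phiNew, gNew, okNew, false);  // value-only probe
      if (okNew && fNew >= f + 1e-4 * t * slope) break;
      t *= 0.5;
      okNew = false;
    }
    if (okNew) fNew = obj.eval(phiNew, gNew, okNew);  // gradient at step
    if (!okNew || fNew <= f + 1e-14 * std::abs(f)) {
      // no further progress
      double gm = 0.0;
      for (uword j = 0; j < k; ++j) {
        if (phi[j] <= obj.phiFloor + 1e-9 && g[j] < 0) continue;
        gm = std::max(gm, std::abs(g[j]));
      }
      if (gm < 1e-3) converged = true;
      break;
    }
    vec s = phiNew - phi;
    vec yv = gNew - g;  // note: gradient of ascent objective
    double sy = -dot(s, yv);  // curvature along step for maximization
    if (it == 0 && sy > 1e-12)   // Shanno-Phua scaling of the initial
      H = (sy / dot(yv, yv)) * eye(k, k);  // inverse Hessian
    double gain = fNew - f;
    phi = phiNew; f = fNew;
    fhist.push_back(f);
    if (gain < 1e-9 * (1.0 + std::abs(f))) {
      if (++smallSteps >= 2) { converged = true; ++it; break; }
    } else smallSteps = 0;
    // windowed value stop for slow crawls along flat ridges
    size_t h = fhist.size();
    if (h >= 6 && f - fhist[h - 6] < 1e-8 * (1.0 + std::abs(f))) {
      converged = true; ++it; break;
    }
    if (sy > 1e-12) {
      // BFGS update on the minimization form (negate gradient changes)
      vec yneg = -yv;
      double rho = 1.0 / dot(yneg, s);
      mat I = eye(k, k);
      H = (I - rho * s * yneg.t()) * H * (I - rho * yneg * s.t()) +
          rho * (s * s.t());
    }
    g = gNew;
  }
  iters = it;
  return f;
}

static Rcpp::List fitInternal(const RemlData &d, bool fixQ,
                              const std::vector<vec> *customStarts = nullptr,
                              bool fast = false) {
  const int maxIter = fast ? 60 : 200;
  const double gtol = fast ? 1e-4 : 1e-6;
  vec yAll(d.N);
  // variance of y for scaling
  double vy;
  {
    // reconstruct y over all individuals
    vec parts(d.N, fill::zeros);
    parts.elem(d.singles) = d.ys;
    for (auto &b : d.blocks) parts.elem(b.idx) = b.y;
    vy = var(parts, 0);
  }
  if (!(vy > 0)) Rcpp::stop("response has zero variance");
  uvec active;
  if (fixQ) active = { 0, 2 }; else active = { 0, 1, 2 };
  std::vector<vec> starts;
  if (customStarts) {
    starts = *customStarts;
  } else if (fixQ) {
    starts.push_back(vec{ 0.5 * vy, 0.0, 0.5 * vy });
    starts.push_back(vec{ 0.05 * vy, 0.0, 0.95 * vy });
    starts.push_back(vec{ 0.9 * vy, 0.0, 0.1 * vy });
  } else {
    starts.push_back(vec{ vy / 3, vy / 3, vy / 3 });
    starts.push_back(vec{ 0.05 * vy, 0.05 * vy, 0.9 * vy });
    starts.push_back(vec{ 0.9 * vy, 0.05 * vy, 0.05 * vy });
    // boundary modes with the variance on the local component exist
    // (sigma_a and sigma_e both ~0); a Q-dominant start reaches them
    starts.push_back(vec{ 0.05 * vy, 0.9 * vy, 0.05 * vy });
  }
  double bestF = -datum::inf;
  vec bestTheta(3, fill::zeros);
  bool anyConv = false;
  int totIt = 0;
  const double phiFloorV = std::log(1e-10 * vy);
  for (auto &st : starts) {
    LogObj obj; obj.d = &d; obj.theta = st; obj.active = active;
    obj.phiFloor = phiFloorV;
    vec phi(active.n_elem);
    for (uword i = 0; i < active.n_elem; ++i)
      phi[i] = std::log(st[active[i]]);
    bool conv; int iters;
    double f = bfgsMax(obj, phi, maxIter, gtol, conv, iters);
    totIt += iters;
    if (f > bestF) {
      bestF = f;
      for (uword i = 0; i < active.n_elem; ++i)
        bestTheta[active[i]] = std::exp(phi[i]);
      if (fixQ) bestTheta[1] = 0.0;
      anyConv = conv;
    } else if (f == bestF && conv) {
      anyConv = true;
    }
  }
  // snap tiny variance components to exactly zero and re-polish
  const double floorV = 1e-8 * vy;
  uvec keep;
  std::vector<uword> kv;
  for (uword k = 0; k < 3; ++k) {
    bool isActive = any(active == k);
    if (!isActive) continue;
    if (k != 2 && bestTheta[k] < floorV) bestTheta[k] = 0.0;
    else kv.push_back(k);
  }
  keep = conv_to<uvec>::from(kv);
  if (keep.n_elem < active.n_elem && keep.n_elem > 0) {
    LogObj obj; obj.d = &d; obj.theta = bestTheta; obj.active = keep;
    obj.phiFloor = phiFloorV;
    vec phi(keep.n_elem);
    for (uword i = 0; i < keep.n_elem; ++i)
      phi[i] = std::log(std::max(bestTheta[keep[i]], 1e-12 * vy));
    bool conv; int iters;
    double f = bfgsMax(obj, phi, maxIter, gtol, conv, iters);
    totIt += iters;
    if (f >= bestF) {
      bestF = f;
      for (uword i = 0; i < keep.n_elem; ++i)
        bestTheta[keep[i]] = std::exp(phi[i]);
      anyConv = anyConv || conv;
    }
  }
  // final evaluation and GLS beta at the optimum
  bool ok;
  vec dummy;
  double ll = remlEval(d, bestTheta[0], bestTheta[1], bestTheta[2],
                       nullptr, &ok);
  // recover beta
  const double v1 = bestTheta[0] + bestTheta[1] + bestTheta[2];
  mat C = d.SXX / v1;
  vec Xty = d.SXy / v1;
  for (auto &b : d.blocks) {
    mat V = bestTheta[0] * b.Psi + bestTheta[1] * b.Phi;
    V.diag() += bestTheta[2];
    mat L;
    if (!chol(L, V, "lower")) { V.diag() += 1e-10 * v1; chol(L, V, "lower"); }
    mat Zx = solve(trimatl(L), b.X);
    vec zy = solve(trimatl(L), b.y);
    C += Zx.t() * Zx;
    Xty += Zx.t() * zy;
  }
  vec beta = solve(C, Xty);
  return Rcpp::List::create(
      Rcpp::_["sigmaA2"] = bestTheta[0], Rcpp::_["sigmaQ2"] = bestTheta[1],
      Rcpp::_["sigmaE2"] = bestTheta[2], Rcpp::_["loglik"] = ll,
      Rcpp::_["beta"] = beta, Rcpp::_["converged"] = anyConv && ok,
      Rcpp::_["iterations"] = totIt);
}

// [[Rcpp::export]]
Rcpp::List fit_reml_cpp(const Rcpp::List &prep, const arma::mat &X,
                        const arma::vec &y, bool fixQ) {
  RemlData d = buildData(prep, X, y);
  return fitInternal(d, fixQ);
}

// [[Rcpp::export]]
double reml_loglik_cpp(const Rcpp::List &prep, const arma::mat &X,
                       const arma::vec &y, double sa, double sq, double se) {
  RemlData d = buildData(prep, X, y);
  bool ok;
  double ll = remlEval(d, sa, sq, se, nullptr, &ok);
  if (!ok) Rcpp::stop("variance matrix not positive definite");
  return ll;
}

// [[Rcpp::export]]
arma::vec reml_grad_cpp(const Rcpp::List &prep, const arma::mat &X,
                        const arma::vec &y, double sa, double sq, double se) {
  RemlData d = buildData(prep, X, y);
  bool ok;
  vec g;
  remlEval(d, sa, sq, se, &g, &ok);
  if (!ok) Rcpp::stop("variance matrix not positive definite");
  return g;
}

// Alternative-hypothesis REML fits and the LOD-score statistic for a set
// of phenotype replicates sharing one (Psi, Phi) structure: returns one
// row per replicate (W, ll0, ll1, conv, sigmaA2, sigmaQ2, sigmaE2).
// Used by genome scans, where the null fit is shared across positions;
// theta0 (per-replicate null estimates of sigma_a2, sigma_e2) seeds the
// alternative fits: a boundary start at the null solution (the typical
// case in a null scan), a mid-level local-variance start from it, and
// the Q-dominant start that reaches local-variance boundary modes.
// [[Rcpp::export]]
arma::mat fit_w_multi_cpp(const Rcpp::List &prep, const arma::mat &X,
                          const arma::mat &Y, const arma::vec &ll0,
                          const arma::vec &conv0, const arma::mat &theta0) {
  const int R = Y.n_cols;
  mat out(R, 7);
  for (int r = 0; r < R; ++r) {
    RemlData d = buildData(prep, X, Y.col(r));
    double vy = var(Y.col(r), 0);
    double sa0 = std::max(theta0(r, 0), 1e-9 * vy);
    double se0 = std::max(theta0(r, 1), 1e-9 * vy);
    // score-adaptive starts: when the local-variance score at the null
    // solution is non-positive the boundary is a stationary maximum and
    // a single boundary start suffices; otherwise climb from the null
    // solution and from the Q-dominant corner (boundary modes)
    std::vector<vec> starts;
    bool okg;
    vec g0;
    remlEval(d, sa0, 1e-9 * vy, se0, &g0, &okg);
    if (okg && g0[1] <= 0) {
      starts.push_back(vec{ sa0, 1e-9 * vy, se0 });
    } else {
      starts.push_back(vec{ sa0, 0.2 * vy, se0 });
    }
    Rcpp::List f1 = fitInternal(d, false, &starts, true);
    double l1 = f1["loglik"];
    bool c1 = f1["converged"];
    double W = 2.0 * (l1 - ll0[r]);
    if (W < 0) W = 0;
    out(r, 0) = W;
    out(r, 1) = ll0[r];
    out(r, 2) = l1;
    out(r, 3) = (c1 && conv0[r] > 0.5) ? 1.0 : 0.0;
    out(r, 4) = Rcpp::as<double>(f1["sigmaA2"]);
    out(r, 5) = Rcpp::as<double>(f1["sigmaQ2"]);
    out(r, 6) = Rcpp::as<double>(f1["sigmaE2"]);
  }
  return out;
}
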