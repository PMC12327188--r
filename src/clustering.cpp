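#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Disjoint-set forest over haplotype indices.
struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// Refine group ids of haplotypes by agreement over markers [from, to]
// (inclusive, 0-based columns of H).  Starting groups are all-equal.
static std::vector<int> agreementGroups(const RawMatrix &H, int from, int to) {
  const int n = H.nrow();
  std::vector<int> g(n, 0);
  std::vector<long long> key(n);
  for (int j = from; j <= to; ++j) {
    std::unordered_map<long long, int> ids;
    ids.reserve(n * 2);
    int next = 0;
    for (int h = 0; h < n; ++h)
      key[h] = (static_cast<long long>(g[h]) << 9) |
               static_cast<long long>(H(h, j));
    for (int h = 0; h < n; ++h) {
      auto it = ids.find(key[h]);
      if (it == ids.end()) { ids.emplace(key[h], next); g[h] = next++; }
      else g[h] = it->second;
    }
  }
  return g;
}

// Maximal identical run of haplotypes a, b that contains [lo, hi];
// returns {l, r} marker indices, or l > r if a, b disagree inside [lo, hi].
static inline void maximalRun(const RawMatrix &H, int a, int b, int lo,
                              int hi, int M, int &l, int &r) {
  for (int j = lo; j <= hi; ++j)
    if (H(a, j) != H(b, j)) { l = 1; r = 0; return; }
  l = lo; r = hi;
  while (l > 0 && H(a, l - 1) == H(b, l - 1)) --l;
  while (r < M - 1 && H(a, r + 1) == H(b, r + 1)) ++r;
}

// Multi-individual IBD clustering at one focal marker.
// H: 2N x M haplotype alleles for one chromosome, cm: marker cM positions
// (non-decreasing), focal: 0-based focal marker index, L/T in cM.
// Two haplotypes are directly related when they share an identical allele
// sequence over a marker interval containing the focal marker, spanning at
// least L cM, and reaching at least T cM on each side of the focal marker
// (a side that reaches the chromosome end satisfies its T requirement).
// Clusters are the transitive closure; ids follow first-haplotype order.
// [[Rcpp::export]]
IntegerVector cluster_at_position_cpp(const RawMatrix &H,
                                      const NumericVector &cm, int focal,
                                      double L, double T) {
  const int n = H.nrow(), M = H.ncol();
  const double fcm = cm[focal];
  int rT = M - 1;
  for (int j = focal; j < M; ++j)
    if (cm[j] >= fcm + T) { rT = j; break; }
  int lT = 0;
  for (int j = focal; j >= 0; --j)
    if (cm[j] <= fcm - T) { lT = j; break; }

  std::vector<int> gr = agreementGroups(H, focal, rT);
  std::vector<int> gl = agreementGroups(H, lT, focal);

  // group haplotypes by the (left, right) agreement pair
  std::unordered_map<long long, std::vector<int>> cand;
  cand.reserve(n * 2);
  for (int h = 0; h < n; ++h) {
    long long key = (static_cast<long long>(gl[h]) << 32) |
                    static_cast<unsigned int>(gr[h]);
    cand[key].push_back(h);
  }

  UnionFind uf(n);
  const bool coreSuffices = (cm[rT] - cm[lT] >= L);
  for (auto &kv : cand) {
    std::vector<int> &mem = kv.second;
    const int s = mem.size();
    if (s < 2) continue;
    if (coreSuffices) {
      for (int i = 1; i < s; ++i) uf.unite(mem[0], mem[i]);
      continue;
    }
    for (int i = 0; i < s; ++i) {
      for (int j = i + 1; j < s; ++j) {
        if (uf.find(mem[i]) == uf.find(mem[j])) continue;
        int l, r;
        maximalRun(H, mem[i], mem[j], lT, rT, M, l, r);
        if (l <= r && cm[r] - cm[l] >= L) uf.unite(mem[i], mem[j]);
      }
    }
  }

  IntegerVector out(n);
  std::unordered_map<int, int> relabel;
  relabel.reserve(n);
  int next = 1;
  for (int h = 0; h < n; ++h) {
    int root = uf.find(h);
    auto it = relabel.find(root);
    if (it == relabel.end()) { relabel.emplace(root, next); out[h] = next++; }
    else out[h] = it->second;
  }
  return out;
}

// Pairwise IBD segment detection by windowed hashing plus run extension
// (seed-and-extend over the minor-allele-count-filtered marker set).
// keep: 0-based indices of filtered markers; windowCM: hash window length
// (half the minimum output length, so every qualifying run fully covers at
// least one window); minOutputCM / minMarkers: retention thresholds.
// Same-individual haplotype pairs are skipped.
// [[Rcpp::export]]
List detect_segments_cpp(const RawMatrix &H, const NumericVector &cm,
                         const IntegerVector &keep, double windowCM,
                         double minOutputCM, int minMarkers,
                         bool skipSameIndividual = true) {
  const int n = H.nrow();
  const int K = keep.size();
  std::vector<int> hap1, hap2;
  std::vector<int> segl, segr;   // filtered-marker index bounds
  if (K == 0)
    return List::create(_["hap1"] = IntegerVector(0),
                        _["hap2"] = IntegerVector(0),
                        _["lIdx"] = IntegerVector(0),
                        _["rIdx"] = IntegerVector(0));
  std::vector<double> cmf(K);
  for (int k = 0; k < K; ++k) cmf[k] = cm[keep[k]];
  const double base = cmf[0];
  const int nWin = static_cast<int>((cmf[K - 1] - base) / windowCM) + 1;
  // window -> filtered marker range
  std::vector<int> wstart(nWin + 1, K);
  for (int k = K - 1; k >= 0; --k) {
    int w = static_cast<int>((cmf[k] - base) / windowCM);
    if (w >= nWin) w = nWin - 1;
    wstart[w] = k;
  }
  for (int w = nWin - 1; w >= 0; --w)
    if (wstart[w] == K) wstart[w] = wstart[w + 1];
  wstart[nWin] = K;

  std::unordered_set<long long> seen; // (pair, run-start) dedupe
  std::vector<int> runl(1), runr(1);
  for (int w = 0; w < nWin; ++w) {
    const int a0 = wstart[w], a1 = wstart[w + 1] - 1;
    if (a1 < a0) continue;
    // group haplotypes by identity over filtered markers of this window
    std::vector<int> g(n, 0);
    std::vector<long long> key(n);
    for (int k = a0; k <= a1; ++k) {
      std::unordered_map<long long, int> ids;
      ids.reserve(n * 2);
      int next = 0;
      const int col = keep[k];
      for (int h = 0; h < n; ++h)
        key[h] = (static_cast<long long>(g[h]) << 9) |
                 static_cast<long long>(H(h, col));
      for (int h = 0; h < n; ++h) {
        auto it = ids.find(key[h]);
        if (it == ids.end()) { ids.emplace(key[h], next); g[h] = next++; }
        else g[h] = it->second;
      }
    }
    std::unordered_map<int, std::vector<int>> groups;
    for (int h = 0; h < n; ++h) groups[g[h]].push_back(h);
    for (auto &kv : groups) {
      std::vector<int> &mem = kv.second;
      const int s = mem.size();
      if (s < 2) continue;
      for (int i = 0; i < s; ++i) {
        for (int j = i + 1; j < s; ++j) {
          const int a = mem[i], b = mem[j];
          if (skipSameIndividual && a / 2 == b / 2) continue;
          // extend run over filtered markers from this window
          int l = a0, r = a1;
          const int ca = a, cb = b;
          while (l > 0 && H(ca, keep[l - 1]) == H(cb, keep[l - 1])) --l;
          while (r < K - 1 && H(ca, keep[r + 1]) == H(cb, keep[r + 1])) ++r;
          if (cmf[r] - cmf[l] < minOutputCM) continue;
          if (r - l + 1 < minMarkers) continue;
          long long pkey = (static_cast<long long>(a) * n + b) * (K + 1) + l;
          if (seen.insert(pkey).second) {
            hap1.push_back(a); hap2.push_back(b);
            segl.push_back(l); segr.push_back(r);
          }
        }
      }
    }
  }
  return List::create(_["hap1"] = wrap(hap1), _["hap2"] = wrap(hap2),
                      _["lIdx"] = wrap(segl), _["rIdx"] = wrap(segr));
}

// Partition of n nodes from an edge list, labels in first-node order.
// [[Rcpp::export]]
IntegerVector partition_from_edges(int n, const IntegerVector &a,
                                   const IntegerVector &b) {
  UnionFind uf(n);
  for (int k = 0; k < a.size(); ++k) uf.unite(a[k] - 1, b[k] - 1);
  IntegerVector out(n);
  std::unordered_map<int, int> relabel;
  int next = 1;
  for (int h = 0; h < n; ++h) {
    int root = uf.find(h);
    auto it = relabel.find(root);
    if (it == relabel.end()) { relabel.emplace(root, next); out[h] = next++; }
    else out[h] = it->second;
  }
  return out;
}

// Alternate-allele frequency per marker column.
// [[Rcpp::export]]
NumericVector alt_freq_cpp(const RawMatrix &H) {
  const int n = H.nrow(), M = H.ncol();
  NumericVector out(M);
  for (int j = 0; j < M; ++j) {
    int c = 0;
    for (int h = 0; h < n; ++h) if (H(h, j) != 0) ++c;
    out[j] = static_cast<double>(c) / n;
  }
  return out;
}

// Minor-allele dosage (0/1/2) per individual for selected marker columns.
// minorIsAlt[k]: whether the minor allele at cols[k] is the non-reference.
// [[Rcpp::export]]
IntegerMatrix minor_dosage_cpp(const RawMatrix &H, const IntegerVector &cols,
                               const LogicalVector &minorIsAlt) {
  const int n2 = H.nrow(), N = n2 / 2, K = cols.size();
  IntegerMatrix out(N, K);
  for (int k = 0; k < K; ++k) {
    const int j = cols[k];
    const bool alt = minorIsAlt[k];
    for (int i = 0; i < N; ++i) {
      int d = 0;
      for (int h = 0; h < 2; ++h) {
        bool isAlt = H(2 * i + h, j) != 0;
        if (isAlt == alt) ++d;
      }
      out(i, k) = d;
    }
  }
  return out;
}

// Parse the simulator bridge format: one line per site,
// "<pos>\t<allele string over haplotypes>", digits 0-9.
// [[Rcpp::export]]
List parse_hap_text_cpp(const std::string &path) {
  FILE *f = fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path);
  std::vector<double> pos;
  std::vector<unsigned char> data;
  int nhap = -1;
  std::string line;
  line.reserve(4096);
  int c;
  while (true) {
    line.clear();
    while ((c = fgetc(f)) != EOF && c != '\n') line.push_back((char)c);
    if (line.empty() && c == EOF) break;
    if (line.empty()) continue;
    size_t tab = line.find('\t');
    if (tab == std::string::npos) { fclose(f); stop("malformed line"); }
    double p = atof(line.substr(0, tab).c_str());
    int len = line.size() - tab - 1;
    if (nhap < 0) nhap = len;
    else if (len != nhap) { fclose(f); stop("ragged haplotype line"); }
    pos.push_back(p);
    for (int h = 0; h < nhap; ++h) {
      char ch = line[tab + 1 + h];
      if (ch < '0' || ch > '9') { fclose(f); stop("bad allele char"); }
      data.push_back(ch - '0');
    }
    if (c == EOF) break;
  }
  fclose(f);
  const int M = pos.size();
  RawMatrix H(nhap > 0 ? nhap : 0, M);
  for (int j = 0; j < M; ++j)
    for (int h = 0; h < nhap; ++h)
      H(h, j) = data[(size_t)j * nhap + h];
  return List::create(_["pos"] = wrap(pos), _["H"] = H);
}

// Monte-Carlo maxima of the modified OU process: nRep replicates of the
// squared positively-truncated AR(1) field over chromosomes with
// nPos[c] grid points and lag-one correlation r; uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector ou_max_sim_cpp(int nRep, double r, const IntegerVector &nPos) {
  NumericVector out(nRep);
  const double s = std::sqrt(1.0 - r * r);
  RNGScope scope;
  for (int rep = 0; rep < nRep; ++rep) {
    double best = 0.0;
    for (int c = 0; c < nPos.size(); ++c) {
      double z = R::norm_rand();
      if (z > 0 && z * z > best) best = z * z;
      for (int k = 1; k < nPos[c]; ++k) {
        z = r * z + s * R::norm_rand();
        if (z > 0 && z * z > best) best = z * z;
      }
    }
    out[rep] = best;
  }
  return out;
}

// Build the REML block structure for one cluster field: local IBD pairs
// from the cluster assignment (2N ids, sample-major), global IBD pairs
// from Psi triplets (0-based, upper or both triangles), connected
// components, and dense per-block Psi/Phi with unit diagonals.
// [[Rcpp::export]]
List scan_prepare_cpp(int N, const IntegerVector &ids,
                      const IntegerVector &psiI, const IntegerVector &psiJ,
                      const NumericVector &psiX) {
  // phi pair weights: for each cluster, individuals with 1 or 2 member
  // haplotypes contribute m_i * m_j / 2 per pair (capped at 1 later)
  std::unordered_map<int, std::vector<int>> clusters;
  for (int h = 0; h < 2 * N; ++h) clusters[ids[h]].push_back(h / 2);
  std::unordered_map<long long, double> phi;
  for (auto &kv : clusters) {
    std::vector<int> &mem = kv.second;
    if (mem.size() < 2) continue;
    std::sort(mem.begin(), mem.end());
    std::vector<std::pair<int, int>> ind;  // (individual, count)
    for (size_t i = 0; i < mem.size(); ) {
      size_t j = i;
      while (j < mem.size() && mem[j] == mem[i]) ++j;
      ind.push_back({ mem[i], (int)(j - i) });
      i = j;
    }
    for (size_t a = 0; a < ind.size(); ++a)
      for (size_t b = a + 1; b < ind.size(); ++b) {
        long long key = (long long)ind[a].first * N + ind[b].first;
        phi[key] += ind[a].second * ind[b].second / 2.0;
      }
  }
  UnionFind uf(N);
  for (auto &kv : phi)
    uf.unite((int)(kv.first / N), (int)(kv.first % N));
  for (int k = 0; k < psiI.size(); ++k)
    if (psiI[k] != psiJ[k]) uf.unite(psiI[k], psiJ[k]);
  // group individuals by component
  std::unordered_map<int, std::vector<int>> comp;
  for (int i = 0; i < N; ++i) comp[uf.find(i)].push_back(i);
  std::vector<int> singles;
  std::vector<std::vector<int>> blocks;
  for (auto &kv : comp) {
    if (kv.second.size() == 1) singles.push_back(kv.second[0] + 1);
    else blocks.push_back(kv.second);
  }
  std::sort(singles.begin(), singles.end());
  // dense block matrices
  std::unordered_map<int, std::pair<int, int>> where;  // ind -> (block, pos)
  for (size_t b = 0; b < blocks.size(); ++b) {
    std::sort(blocks[b].begin(), blocks[b].end());
    for (size_t p = 0; p < blocks[b].size(); ++p)
      where[blocks[b][p]] = { (int)b, (int)p };
  }
  List outBlocks(blocks.size());
  std::vector<NumericMatrix> Psis, Phis;
  for (size_t b = 0; b < blocks.size(); ++b) {
    int nb = blocks[b].size();
    NumericMatrix P(nb, nb), Q(nb, nb);
    for (int d = 0; d < nb; ++d) { P(d, d) = 1.0; Q(d, d) = 1.0; }
    Psis.push_back(P); Phis.push_back(Q);
  }
  for (int k = 0; k < psiI.size(); ++k) {
    if (psiI[k] == psiJ[k]) continue;
    auto a = where.find(psiI[k]);
    if (a == where.end()) continue;
    auto bpos = where[psiJ[k]];
    NumericMatrix &P = Psis[a->second.first];
    P(a->second.second, bpos.second) = psiX[k];
    P(bpos.second, a->second.second) = psiX[k];
  }
  for (auto &kv : phi) {
    int i = (int)(kv.first / N), j = (int)(kv.first % N);
    auto a = where[i], bpos = where[j];
    double v = std::min(kv.second, 1.0);
    NumericMatrix &Q = Phis[a.first];
    Q(a.second, bpos.second) = v;
    Q(bpos.second, a.second) = v;
  }
  for (size_t b = 0; b < blocks.size(); ++b) {
    IntegerVector idx(blocks[b].size());
    for (size_t p = 0; p < blocks[b].size(); ++p) idx[p] = blocks[b][p] + 1;
    outBlocks[b] = List::create(_["idx"] = idx, _["Psi"] = Psis[b],
                                _["Phi"] = Phis[b]);
  }
  return List::create(_["singles"] = wrap(singles),
                      _["blocks"] = outBlocks, _["N"] = N);
}
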