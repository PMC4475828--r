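// Stable Ecotype Model coalescent: event loop, complete-linkage binning
// and the simulation-likelihood inner loop. Uses R's RNG throughout so
// results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// backward-in-time simulation; fills D (n x n, mutation counts on tip
// pairs' paths). Returns false when the event cap is exceeded.
static bool simulate_once(double omega, double sigma, int npop, double drift,
                          int n, double maxDepth, int maxEvents,
                          std::vector<double> &m, std::vector<int> &lin,
                          std::vector<int> &eco, std::vector<double> &D) {
  const int np = std::min(npop, n);
  for (int i = 0; i < n; ++i) {
    lin[i] = i;
    eco[i] = i % np;
    m[i] = 0.0;
  }
  std::fill(D.begin(), D.end(), 0.0);
  double t = 0.0;
  int ev = 0;

  std::vector<int> ids, linEco, occ, kPerEco;
  std::vector<char> seen(n);

  auto join = [&](const std::vector<int> &lids) {
    for (size_t a = 0; a + 1 < lids.size(); ++a) {
      for (size_t b = a + 1; b < lids.size(); ++b) {
        for (int i = 0; i < n; ++i) {
          if (lin[i] != lids[a]) continue;
          for (int j = 0; j < n; ++j) {
            if (lin[j] != lids[b]) continue;
            D[i * n + j] = D[j * n + i] = m[i] + m[j];
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      for (size_t a = 1; a < lids.size(); ++a)
        if (lin[i] == lids[a]) lin[i] = lids[0];
    }
  };

  for (;;) {
    // active lineage ids
    std::fill(seen.begin(), seen.end(), 0);
    ids.clear();
    for (int i = 0; i < n; ++i) {
      if (!seen[lin[i]]) { seen[lin[i]] = 1; ids.push_back(lin[i]); }
    }
    const int nl = (int)ids.size();
    if (nl == 1) break;
    if (++ev > maxEvents) return false;

    // ecotype occupancy among active lineages
    linEco.assign(nl, 0);
    for (int a = 0; a < nl; ++a) {
      for (int i = 0; i < n; ++i)
        if (lin[i] == ids[a]) { linEco[a] = eco[i]; break; }
    }
    occ.clear(); kPerEco.clear();
    for (int a = 0; a < nl; ++a) {
      int pos = -1;
      for (size_t q = 0; q < occ.size(); ++q)
        if (occ[q] == linEco[a]) { pos = (int)q; break; }
      if (pos < 0) { occ.push_back(linEco[a]); kPerEco.push_back(1); }
      else kPerEco[pos]++;
    }
    const int nOcc = (int)occ.size();
    double rateForm = (nOcc > 1) ? omega * nl : 0.0;
    int nSwe = 0;
    double pairSum = 0.0;
    for (int q = 0; q < nOcc; ++q) {
      if (kPerEco[q] >= 2) ++nSwe;
      pairSum += kPerEco[q] * (kPerEco[q] - 1) / 2.0;
    }
    double rateSel = sigma * nSwe;
    double rateDrift = drift * pairSum;
    double R = rateForm + rateSel + rateDrift;

    double dt = (R > 0) ? R::rexp(1.0 / R) : R_PosInf;
    // maxDepth is the ecotype divergence depth: lineages still in
    // distinct ecotypes star-join there. A single ecotype coalesces on
    // its own clock (drift/sweeps), with a distant hard stop for safety.
    double cap = (nOcc > 1) ? maxDepth : 50.0 * maxDepth;
    bool fin = (t + dt >= cap);
    if (fin) dt = cap - t;
    t += dt;
    for (int a = 0; a < nl; ++a) {
      double mu = R::rpois(dt);
      for (int i = 0; i < n; ++i)
        if (lin[i] == ids[a]) m[i] += mu;
    }
    if (fin) { join(ids); break; }

    double u = unif_rand() * R;
    if (u < rateForm) {
      // backward ecotype formation: a random lineage's ecotype merges
      // into another occupied ecotype
      int li = (int)(unif_rand() * nl); if (li >= nl) li = nl - 1;
      int e = linEco[li];
      std::vector<int> others;
      for (int q = 0; q < nOcc; ++q) if (occ[q] != e) others.push_back(occ[q]);
      int e2 = others[(int)(unif_rand() * others.size()) % others.size()];
      for (int i = 0; i < n; ++i) if (eco[i] == e) eco[i] = e2;
    } else if (u < rateForm + rateSel) {
      // periodic selection: all lineages of one multi-lineage ecotype
      // coalesce
      std::vector<int> elig;
      for (int q = 0; q < nOcc; ++q) if (kPerEco[q] >= 2) elig.push_back(occ[q]);
      int e = elig[(int)(unif_rand() * elig.size()) % elig.size()];
      std::vector<int> lids;
      for (int a = 0; a < nl; ++a) if (linEco[a] == e) lids.push_back(ids[a]);
      join(lids);
    } else if (rateDrift > 0) {
      // drift: one within-ecotype pair coalesces; pick ecotype by pair
      // weight, then a uniform pair
      double r = unif_rand() * pairSum, acc = 0.0;
      int e = occ[nOcc - 1];
      for (int q = 0; q < nOcc; ++q) {
        acc += kPerEco[q] * (kPerEco[q] - 1) / 2.0;
        if (r <= acc) { e = occ[q]; break; }
      }
      std::vector<int> cand;
      for (int a = 0; a < nl; ++a) if (linEco[a] == e) cand.push_back(ids[a]);
      int i1 = (int)(unif_rand() * cand.size()) % cand.size();
      int i2 = (int)(unif_rand() * (cand.size() - 1)) % (cand.size() - 1);
      if (i2 >= i1) ++i2;
      std::vector<int> pick; pick.push_back(cand[i1]); pick.push_back(cand[i2]);
      join(pick);
    }
  }
  return true;
}

// sorted complete-linkage merge heights of an n x n distance matrix
static void clHeights(std::vector<double> cd, int n,
                      std::vector<double> &heights) {
  std::vector<char> alive(n, 1);
  heights.clear();
  for (int s = 0; s < n - 1; ++s) {
    double best = R_PosInf;
    int ba = -1, bb = -1;
    for (int a = 0; a < n; ++a) {
      if (!alive[a]) continue;
      for (int b = a + 1; b < n; ++b) {
        if (!alive[b]) continue;
        if (cd[a * n + b] < best) { best = cd[a * n + b]; ba = a; bb = b; }
      }
    }
    heights.push_back(best);
    for (int j = 0; j < n; ++j) {
      if (!alive[j] || j == ba) continue;
      double v = std::max(cd[ba * n + j], cd[bb * n + j]);
      cd[ba * n + j] = cd[j * n + ba] = v;
    }
    alive[bb] = 0;
  }
  std::sort(heights.begin(), heights.end());
}

static void binsFromMuts(const std::vector<double> &D, int n, double seqLen,
                         const NumericVector &thr, std::vector<int> &bins) {
  std::vector<double> djc(n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double p = std::min(D[i * n + j] / seqLen, 0.7499);
      djc[i * n + j] = -0.75 * std::log(1.0 - (4.0 / 3.0) * p);
    }
  }
  std::vector<double> heights;
  clHeights(djc, n, heights);
  bins.assign(thr.size(), 0);
  for (int k = 0; k < thr.size(); ++k) {
    int cnt = 0;
    for (size_t h = 0; h < heights.size(); ++h)
      if (heights[h] <= thr[k] + 1e-12) ++cnt;
    bins[k] = n - cnt;
  }
}

// [[Rcpp::export]]
NumericMatrix ses_simulate_cpp(double omega, double sigma, int npop,
                               double drift, int nLineages, double maxDepth,
                               int maxEvents) {
  int n = nLineages;
  std::vector<double> m(n), D(n * n);
  std::vector<int> lin(n), eco(n);
  if (!simulate_once(omega, sigma, npop, drift, n, maxDepth, maxEvents,
                     m, lin, eco, D))
    stop("cap exceeded");
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = D[i * n + j];
  return out;
}

// [[Rcpp::export]]
NumericVector ses_likelihood_cpp(NumericMatrix grid, int nLineages,
                                 double maxDepth, double seqLen,
                                 NumericVector thresholds,
                                 IntegerVector obsBins, int slack,
                                 int maxMiss, int nReps, int maxEvents) {
  const int n = nLineages, G = grid.nrow();
  std::vector<double> m(n), D(n * n);
  std::vector<int> lin(n), eco(n), bins;
  NumericVector lik(G);
  for (int g = 0; g < G; ++g) {
    int hits = 0;
    for (int r = 0; r < nReps; ++r) {
      if (!simulate_once(grid(g, 0), grid(g, 1), (int)grid(g, 2),
                         grid(g, 3), n, maxDepth, maxEvents, m, lin, eco, D))
        stop("cap exceeded");
      binsFromMuts(D, n, seqLen, thresholds, bins);
      int miss = 0;
      for (int k = 0; k < obsBins.size(); ++k)
        if (std::abs(bins[k] - obsBins[k]) > slack) ++miss;
      if (miss <= maxMiss) ++hits;
    }
    lik[g] = (double)hits / nReps;
  }
  return lik;
}
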