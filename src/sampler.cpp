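// Collapsed Gibbs sampler for the Dirichlet-process Gaussian mixture with a
// Potts-style MRF factor in the label conditional.
//
// Cluster parameters (mean, variance) are integrated against the
// normal-inverse-gamma base measure, so each cluster is carried as
// (n, sum, sumsq) and the single-site conditional is
//   p(S_i = k | ...) ~ n_k * exp(lambda * sum_{l in d(i)} w_il [S_l = k])
//                        * t_pred(x_i | stats_k)
//   p(new cluster)   ~ alpha * t_pred(x_i | empty)
// (a brand-new label matches no neighbor, so its MRF factor is 1).
// Empty clusters are deleted immediately and labels above them shift down,
// keeping labels contiguous. All randomness comes from R's RNG, so set.seed
// in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct NIG {
  double mu0, kappa0, a0, b0;
};

// log Student-t posterior predictive of the NIG model given (n, sum, sumsq)
static double logPredictive(double x, double n, double sum, double sumsq,
                            const NIG &g) {
  double kn = g.kappa0 + n;
  double mun = (g.kappa0 * g.mu0 + sum) / kn;
  double an = g.a0 + 0.5 * n;
  double bn = g.b0;
  if (n > 0) {
    double xbar = sum / n;
    double ss = sumsq - n * xbar * xbar;
    if (ss < 0) ss = 0;
    bn += 0.5 * ss +
          0.5 * g.kappa0 * n * (xbar - g.mu0) * (xbar - g.mu0) / kn;
  }
  double nu = 2.0 * an;
  double s2 = bn * (kn + 1.0) / (an * kn);
  double z2 = (x - mun) * (x - mun) / (nu * s2);
  return std::lgamma(0.5 * (nu + 1.0)) - std::lgamma(0.5 * nu) -
         0.5 * std::log(nu * M_PI * s2) - 0.5 * (nu + 1.0) * std::log1p(z2);
}

struct Clusters {
  std::vector<double> n, s, ss;
  int K() const { return (int)n.size(); }
  void removeCluster(int k, std::vector<int> &labels) {
    n.erase(n.begin() + k);
    s.erase(s.begin() + k);
    ss.erase(ss.begin() + k);
    for (size_t i = 0; i < labels.size(); ++i)
      if (labels[i] > k) labels[i]--;
  }
};

static Clusters statsFromLabels(const std::vector<int> &labels,
                                const NumericVector &x) {
  Clusters cl;
  int K = 0;
  for (size_t i = 0; i < labels.size(); ++i)
    if (labels[i] + 1 > K) K = labels[i] + 1;
  cl.n.assign(K, 0.0);
  cl.s.assign(K, 0.0);
  cl.ss.assign(K, 0.0);
  for (size_t i = 0; i < labels.size(); ++i) {
    int k = labels[i];
    cl.n[k] += 1.0;
    cl.s[k] += x[i];
    cl.ss[k] += x[i] * x[i];
  }
  return cl;
}

// Unnormalized log conditional over K existing clusters + a new one, for
// site i whose own point has already been removed from `cl`.
static void siteLogWeights(int i, const NumericVector &x,
                           const IntegerVector &offsets,
                           const IntegerVector &nbr, const NumericVector &wt,
                           const std::vector<int> &labels, const Clusters &cl,
                           double alpha, double lambda, const NIG &g,
                           std::vector<double> &logw) {
  int K = cl.K();
  logw.assign(K + 1, 0.0);
  std::vector<double> match(K, 0.0);
  if (lambda > 0) {
    for (int e = offsets[i]; e < offsets[i + 1]; ++e) {
      int l = labels[nbr[e]];
      if (l >= 0 && l < K) match[l] += wt[e];
    }
  }
  for (int k = 0; k < K; ++k)
    logw[k] = std::log(cl.n[k]) + lambda * match[k] +
              logPredictive(x[i], cl.n[k], cl.s[k], cl.ss[k], g);
  logw[K] = std::log(alpha) + logPredictive(x[i], 0.0, 0.0, 0.0, g);
}

static int sampleFromLogWeights(std::vector<double> &logw) {
  double mx = logw[0];
  for (size_t k = 1; k < logw.size(); ++k)
    if (logw[k] > mx) mx = logw[k];
  double tot = 0.0;
  for (size_t k = 0; k < logw.size(); ++k) {
    logw[k] = std::exp(logw[k] - mx);
    tot += logw[k];
  }
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (size_t k = 0; k < logw.size(); ++k) {
    acc += logw[k];
    if (u <= acc) return (int)k;
  }
  return (int)logw.size() - 1;
}

// One raster-order sweep; returns the number of sites whose cluster
// membership changed. A singleton that re-opens as a singleton counts as
// unchanged (the partition did not move).
static int sweep(const NumericVector &x, const IntegerVector &offsets,
                 const IntegerVector &nbr, const NumericVector &wt,
                 std::vector<int> &labels, Clusters &cl, double alpha,
                 double lambda, const NIG &g) {
  int m = x.size();
  int nChanged = 0;
  std::vector<double> logw;
  for (int i = 0; i < m; ++i) {
    int c = labels[i];
    cl.n[c] -= 1.0;
    cl.s[c] -= x[i];
    cl.ss[c] -= x[i] * x[i];
    bool deleted = false;
    if (cl.n[c] <= 0.5) {
      cl.removeCluster(c, labels);
      deleted = true;
    }
    labels[i] = -1;
    int K = cl.K();
    siteLogWeights(i, x, offsets, nbr, wt, labels, cl, alpha, lambda, g,
                   logw);
    int k = sampleFromLogWeights(logw);
    if (k == K) {
      cl.n.push_back(0.0);
      cl.s.push_back(0.0);
      cl.ss.push_back(0.0);
    }
    cl.n[k] += 1.0;
    cl.s[k] += x[i];
    cl.ss[k] += x[i] * x[i];
    labels[i] = k;
    bool changed = deleted ? (k != K) : (k != c);
    if (changed) nChanged++;
  }
  return nChanged;
}

// [[Rcpp::export]]
List cpp_gibbs_sweep(NumericVector x, IntegerVector offsets,
                     IntegerVector nbr, NumericVector wt,
                     IntegerVector labels, double alpha, double lambda,
                     double mu0, double kappa0, double a0, double b0) {
  NIG g{mu0, kappa0, a0, b0};
  std::vector<int> lab(labels.begin(), labels.end());
  Clusters cl = statsFromLabels(lab, x);
  int nChanged = sweep(x, offsets, nbr, wt, lab, cl, alpha, lambda, g);
  return List::create(
      _["labels"] = IntegerVector(lab.begin(), lab.end()),
      _["nChanged"] = nChanged,
      _["compN"] = NumericVector(cl.n.begin(), cl.n.end()),
      _["compSum"] = NumericVector(cl.s.begin(), cl.s.end()),
      _["compSumsq"] = NumericVector(cl.ss.begin(), cl.ss.end()));
}

// [[Rcpp::export]]
List cpp_run_sampler(NumericVector x, IntegerVector offsets,
                     IntegerVector nbr, NumericVector wt,
                     IntegerVector labels, double alpha, double lambda,
                     double mu0, double kappa0, double a0, double b0,
                     int maxIter, int window, double convFrac,
                     bool earlyStop) {
  NIG g{mu0, kappa0, a0, b0};
  std::vector<int> lab(labels.begin(), labels.end());
  Clusters cl = statsFromLabels(lab, x);
  int m = x.size();
  std::vector<int> traceK, traceChanged;
  double thresh = convFrac * m;
  for (int it = 0; it < maxIter; ++it) {
    int nChanged = sweep(x, offsets, nbr, wt, lab, cl, alpha, lambda, g);
    traceK.push_back(cl.K());
    traceChanged.push_back(nChanged);
    if (earlyStop && (int)traceChanged.size() >= window) {
      bool stable = true;
      for (int j = 0; j < window; ++j)
        if (traceChanged[traceChanged.size() - 1 - j] >= thresh) {
          stable = false;
          break;
        }
      if (stable) break;
    }
    if (it % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["labels"] = IntegerVector(lab.begin(), lab.end()),
      _["nClusters"] = IntegerVector(traceK.begin(), traceK.end()),
      _["nChanged"] =
          IntegerVector(traceChanged.begin(), traceChanged.end()),
      _["compN"] = NumericVector(cl.n.begin(), cl.n.end()),
      _["compSum"] = NumericVector(cl.s.begin(), cl.s.end()),
      _["compSumsq"] = NumericVector(cl.ss.begin(), cl.ss.end()));
}

// Normalized single-site conditional (site's point removed first, empty
// cluster deleted); used to cross-check the R-level implementation.
// [[Rcpp::export]]
NumericVector cpp_site_conditional(NumericVector x, IntegerVector offsets,
                                   IntegerVector nbr, NumericVector wt,
                                   IntegerVector labels, int site,
                                   double alpha, double lambda, double mu0,
                                   double kappa0, double a0, double b0) {
  NIG g{mu0, kappa0, a0, b0};
  std::vector<int> lab(labels.begin(), labels.end());
  Clusters cl = statsFromLabels(lab, x);
  int c = lab[site];
  cl.n[c] -= 1.0;
  cl.s[c] -= x[site];
  cl.ss[c] -= x[site] * x[site];
  if (cl.n[c] <= 0.5) cl.removeCluster(c, lab);
  lab[site] = -1;
  std::vector<double> logw;
  siteLogWeights(site, x, offsets, nbr, wt, lab, cl, alpha, lambda, g,
                 logw);
  double mx = *std::max_element(logw.begin(), logw.end());
  double tot = 0.0;
  NumericVector p(logw.size());
  for (size_t k = 0; k < logw.size(); ++k) {
    p[k] = std::exp(logw[k] - mx);
    tot += p[k];
  }
  for (size_t k = 0; k < logw.size(); ++k) p[k] /= tot;
  return p;
}

// Sequential CRP table assignments for n customers, canonical labels (new
// table = next integer), encoded base-n into one integer per draw.
// [[Rcpp::export]]
IntegerVector cpp_crp_codes(int nDraws, int n, double alpha) {
  if (n > 9) stop("n too large for integer encoding");
  IntegerVector out(nDraws);
  std::vector<double> sizes;
  for (int d = 0; d < nDraws; ++d) {
    sizes.clear();
    long code = 0;
    long mult = 1;
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (size_t k = 0; k < sizes.size(); ++k) tot += sizes[k];
      double u = unif_rand() * (tot + alpha);
      int pick = (int)sizes.size();
      double acc = 0.0;
      for (size_t k = 0; k < sizes.size(); ++k) {
        acc += sizes[k];
        if (u <= acc) {
          pick = (int)k;
          break;
        }
      }
      if (pick == (int)sizes.size())
        sizes.push_back(1.0);
      else
        sizes[pick] += 1.0;
      code += mult * pick;
      mult *= n;
    }
    out[d] = (int)code;
  }
  return out;
}
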