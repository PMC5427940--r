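// Birth-death pruning core: truncated transition matrices and the
// per-family Felsenstein recursion, vectorised across families.

#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
#include <cmath>

using namespace Rcpp;

// P[s][c] (row-major, states 0..S) for a linear birth-death process with
// per-copy gain lam and loss mu over duration t, via the survivor-sum
// closed form; terms are single-configuration probabilities (<= 1), so
// summing exponentials of log terms is overflow-safe.
static void bd_matrix(double lam, double mu, double t, int S,
                      std::vector<double> &M) {
  double alpha, beta;
  if (lam == 0.0 && mu == 0.0) {
    alpha = 0.0; beta = 0.0;
  } else if (std::fabs(lam - mu) * t < 1e-8) {
    alpha = lam * t / (1.0 + lam * t);
    beta = alpha;
  } else {
    double E = std::exp((lam - mu) * t);
    double denom = lam * E - mu;
    alpha = mu * (E - 1.0) / denom;
    beta = lam * (E - 1.0) / denom;
  }
  const int W = S + 1;
  // single-ancestor offspring law: extinct with prob alpha, else size
  // geometric with parameter (1 - beta)
  std::vector<double> r1(W);
  r1[0] = alpha;
  if (S >= 1) r1[1] = (1.0 - alpha) * (1.0 - beta);
  for (int c = 2; c <= S; ++c) r1[c] = r1[c - 1] * beta;
  // the s-ancestor row is the s-fold truncated convolution of r1 (copies
  // evolve independently); truncation is exact for c <= S because size
  // paths cannot re-enter from above
  std::fill(M.begin(), M.end(), 0.0);
  M[0] = 1.0;                                   // absorbing zero
  for (int s = 1; s <= S; ++s) {
    const double *prev = (s == 1) ? NULL : &M[(s - 1) * W];
    double *row = &M[s * W];
    if (s == 1) {
      std::copy(r1.begin(), r1.end(), row);
    } else {
      for (int c = 0; c <= S; ++c) {
        double acc = 0.0;
        for (int k = 0; k <= c; ++k) acc += prev[k] * r1[c - k];
        row[c] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".prune_core")]]
List prune_core(IntegerMatrix counts, IntegerMatrix edge,
                NumericVector elen, IntegerVector eclass,
                NumericVector lam, NumericVector mu, NumericVector eps,
                int S, NumericVector prior) {
  const int nf = counts.nrow();
  const int ntip = counts.ncol();
  const int nE = edge.nrow();
  const int W = S + 1;
  int nn = ntip;
  for (int k = 0; k < nE; ++k) {
    if (edge(k, 0) > nn) nn = edge(k, 0);
    if (edge(k, 1) > nn) nn = edge(k, 1);
  }

  // memoised transition matrices keyed by (class, branch length)
  std::map<std::pair<int, double>, std::vector<double> > cache;
  std::vector<const std::vector<double> *> mats(nE);
  for (int k = 0; k < nE; ++k) {
    std::pair<int, double> key(eclass[k], elen[k]);
    std::map<std::pair<int, double>,
             std::vector<double> >::iterator it = cache.find(key);
    if (it == cache.end()) {
      std::vector<double> M(W * W);
      bd_matrix(lam[eclass[k]], mu[eclass[k]], elen[k], S, M);
      it = cache.insert(std::make_pair(key, M)).first;
    }
    mats[k] = &(it->second);
  }

  // partial likelihoods per node (allocated lazily), scale per family
  std::vector<std::vector<double> > part(nn + 1);
  std::vector<bool> touched(nn + 1, false);
  std::vector<double> scale(nf, 0.0);
  std::vector<double> msg(static_cast<size_t>(nf) * W);
  std::vector<double> tipbuf(static_cast<size_t>(nf) * W);

  for (int k = 0; k < nE; ++k) {
    const int parent = edge(k, 0);
    const int child = edge(k, 1);
    const std::vector<double> &T = *mats[k];

    const double *Lc;
    if (child <= ntip) {
      const double e = eps[child - 1];
      for (int f = 0; f < nf; ++f) {
        const int obs = counts(f, child - 1);
        double *row = &tipbuf[static_cast<size_t>(f) * W];
        if (e == 0.0) {
          std::fill(row, row + W, 0.0);
          if (obs <= S) row[obs] = 1.0;
        } else {
          for (int st = 0; st <= S; ++st) {
            double v = 0.0;
            if (obs == st) v = 1.0 - e;
            else if (obs == st + 1 || obs + 1 == st) v = e / 2.0;
            if (st == 0 && obs == 0) v = 1.0 - e / 2.0;
            row[st] = v;
          }
        }
      }
      Lc = &tipbuf[0];
    } else {
      Lc = &part[child][0];
    }

    // msg[f][s] = sum_c Lc[f][c] * T[s][c]
    for (int f = 0; f < nf; ++f) {
      const double *L = Lc + static_cast<size_t>(f) * W;
      double *m = &msg[static_cast<size_t>(f) * W];
      for (int s = 0; s <= S; ++s) {
        const double *Trow = &T[static_cast<size_t>(s) * W];
        double acc = 0.0;
        for (int c = 0; c <= S; ++c) acc += L[c] * Trow[c];
        m[s] = acc;
      }
    }

    if (!touched[parent]) {
      part[parent].assign(msg.begin(),
                          msg.begin() + static_cast<size_t>(nf) * W);
      touched[parent] = true;
    } else {
      std::vector<double> &P = part[parent];
      for (int f = 0; f < nf; ++f) {
        double *p = &P[static_cast<size_t>(f) * W];
        const double *m = &msg[static_cast<size_t>(f) * W];
        double mx = 0.0;
        for (int s = 0; s <= S; ++s) {
          p[s] *= m[s];
          if (p[s] > mx) mx = p[s];
        }
        if (mx > 0.0) {
          for (int s = 0; s <= S; ++s) p[s] /= mx;
          scale[f] += std::log(mx);
        }
      }
    }
    if (child > ntip) {
      std::vector<double>().swap(part[child]);  // free
    }
  }

  const int root = ntip + 1;
  NumericVector loglik(nf);
  NumericMatrix root_partial(nf, W);
  const std::vector<double> &R = part[root];
  for (int f = 0; f < nf; ++f) {
    const double *p = &R[static_cast<size_t>(f) * W];
    double acc = 0.0;
    for (int s = 0; s <= S; ++s) {
      acc += p[s] * prior[s];
      root_partial(f, s) = p[s];
    }
    loglik[f] = std::log(acc) + scale[f];
  }
  return List::create(Named("loglik") = loglik,
                      Named("root_partial") = root_partial);
}
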