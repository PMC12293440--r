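// Hot paths of the pipeline: weighted graph metrics, surrogate ensembles
// (degree-preserving rewiring + weight permutation), and time-smoothed
// wavelet coherence aggregation. All randomness comes from R's RNG so that
// set.seed() on the R side makes results reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All-pairs shortest paths on edge lengths 1/w (Floyd-Warshall).
static arma::mat fw_distances(const arma::mat& W) {
  const arma::uword n = W.n_rows;
  arma::mat D(n, n);
  D.fill(arma::datum::inf);
  D.diag().zeros();
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0) D(i, j) = 1.0 / W(i, j);
  for (arma::uword k = 0; k < n; ++k)
    for (arma::uword i = 0; i < n; ++i) {
      const double dik = D(i, k);
      if (!std::isfinite(dik)) continue;
      for (arma::uword j = 0; j < n; ++j) {
        const double alt = dik + D(k, j);
        if (alt < D(i, j)) D(i, j) = alt;
      }
    }
  return D;
}

// Metric vector layout: [strength(1..C), clustering(1..C), energy,
// global_efficiency, transitivity, char_path_length, n_disconnected_pairs]
static arma::vec metric_vec(const arma::mat& W) {
  const arma::uword n = W.n_rows;
  arma::vec out(2 * n + 5, arma::fill::zeros);

  arma::vec s = arma::sum(W, 1);
  out.subvec(0, n - 1) = s;

  // Onnela clustering / transitivity on max-normalized weights
  const double wmax = W.max();
  arma::vec tri(n, arma::fill::zeros);
  arma::vec k(n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0) k(i) += 1.0;
  if (wmax > 0) {
    arma::mat A = arma::pow(W / wmax, 1.0 / 3.0);
    A.diag().zeros();
    arma::mat A2 = A * A;
    tri = arma::sum(A2 % A, 1);  // diag(A^3): weighted triangles x2
  }
  double denom_sum = 0.0, tri_sum = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double denom = k(i) * (k(i) - 1.0);
    if (denom > 0) out(n + i) = tri(i) / denom;
    denom_sum += denom;
    tri_sum += tri(i);
  }

  arma::vec ev;
  arma::eig_sym(ev, W);
  out(2 * n) = arma::sum(arma::abs(ev));  // graph energy

  arma::mat D = fw_distances(W);
  double eff = 0.0, plen = 0.0;
  arma::uword nfin = 0, ndisc = 0;
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j) {
      if (i == j) continue;
      if (std::isfinite(D(i, j))) {
        eff += 1.0 / D(i, j);
        plen += D(i, j);
        ++nfin;
      } else {
        ++ndisc;
      }
    }
  const double npairs = static_cast<double>(n) * (n - 1.0);
  out(2 * n + 1) = npairs > 0 ? eff / npairs : 0.0;
  out(2 * n + 2) = denom_sum > 0 ? tri_sum / denom_sum : 0.0;
  out(2 * n + 3) = nfin > 0 ? plen / nfin : NA_REAL;
  out(2 * n + 4) = static_cast<double>(ndisc);
  return out;
}

// [[Rcpp::export]]
arma::vec graph_metrics_cpp(const arma::mat& W) {
  return metric_vec(W);
}

// [[Rcpp::export]]
arma::mat floyd_distances_cpp(const arma::mat& W) {
  return fw_distances(W);
}

static inline int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int v = static_cast<int>(R::unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// Degree-preserving rewire of the edge list (Maslov-Sneppen double edge
// swaps), then random reassignment of the original weight multiset.
// Returns a list with the surrogate metric matrix (n_surr x (2C+5)) and the
// number of surrogates where no swap succeeded (rewiring fallback).
// [[Rcpp::export]]
List surrogate_metrics_cpp(const arma::mat& W, int n_surr, int swaps_per_edge) {
  const int n = W.n_rows;
  std::vector<int> ea, eb;
  std::vector<double> wts;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0) {
        ea.push_back(i);
        eb.push_back(j);
        wts.push_back(W(i, j));
      }
  const int E = static_cast<int>(ea.size());
  if (E < 2) stop("surrogate construction needs at least 2 edges");

  arma::mat out(n_surr, 2 * n + 5);
  int n_fallback = 0;
  arma::umat adj0(n, n, arma::fill::zeros);
  for (int e = 0; e < E; ++e) adj0(ea[e], eb[e]) = adj0(eb[e], ea[e]) = 1;

  for (int s = 0; s < n_surr; ++s) {
    std::vector<int> a(ea), b(eb);
    arma::umat adj(adj0);
    int ok = 0;
    const int attempts = swaps_per_edge * E;
    for (int it = 0; it < attempts; ++it) {
      const int e1 = runif_int(E);
      int e2 = runif_int(E);
      if (e1 == e2) continue;
      int p = a[e1], q = b[e1], r = a[e2], t = b[e2];
      if (R::unif_rand() < 0.5) std::swap(r, t);
      // propose (p,t) and (r,q)
      if (p == t || r == q || p == r || q == t) continue;
      if (adj(p, t) || adj(r, q)) continue;
      adj(p, q) = adj(q, p) = 0;
      adj(r, t) = adj(t, r) = 0;
      adj(p, t) = adj(t, p) = 1;
      adj(r, q) = adj(q, r) = 1;
      a[e1] = p; b[e1] = t;
      a[e2] = r; b[e2] = q;
      ++ok;
    }
    if (ok == 0) ++n_fallback;
    // Fisher-Yates permutation of the weight multiset
    std::vector<double> wp(wts);
    for (int i = E - 1; i > 0; --i) {
      const int j = runif_int(i + 1);
      std::swap(wp[i], wp[j]);
    }
    arma::mat Ws(n, n, arma::fill::zeros);
    for (int e = 0; e < E; ++e) {
      Ws(a[e], b[e]) = wp[e];
      Ws(b[e], a[e]) = wp[e];
    }
    out.row(s) = metric_vec(Ws).t();
  }
  return List::create(_["metrics"] = out, _["n_fallback"] = n_fallback);
}

// Window- and band-averaged wavelet coherence for all channel pairs.
// S: time x channel x scale complex CWT coefficients of one trial.
// windows: n_comp x 2 matrix of 0-based inclusive sample ranges.
// band_scales: list of 0-based scale index vectors per band.
// halfwidth: per-scale smoothing half-window in samples (delta = c/f).
// Returns coherence array (C x C x n_comp x n_band) and a zero-spectrum count.
// [[Rcpp::export]]
List coh_aggregate_cpp(const arma::cx_cube& S, const arma::imat& windows,
                       const List& band_scales, const arma::ivec& halfwidth) {
  const arma::uword n = S.n_rows, C = S.n_cols, nsc = S.n_slices;
  const int n_comp = windows.n_rows;
  const int n_band = band_scales.size();
  arma::field<arma::mat> acc(n_comp, n_band);
  std::vector<std::vector<double>> bandcount(n_comp,
                                             std::vector<double>(n_band, 0.0));
  for (int k = 0; k < n_comp; ++k)
    for (int b = 0; b < n_band; ++b) acc(k, b) = arma::mat(C, C, arma::fill::zeros);

  long zero_count = 0;
  // which bands use each scale
  std::vector<std::vector<int>> scale_bands(nsc);
  for (int b = 0; b < n_band; ++b) {
    IntegerVector idx = band_scales[b];
    for (int m = 0; m < idx.size(); ++m) scale_bands[idx[m]].push_back(b);
  }

  arma::mat coh_win(C, C);  // scratch: per-(scale,window) mean coherence
  for (arma::uword sc = 0; sc < nsc; ++sc) {
    if (scale_bands[sc].empty()) continue;
    const int h = halfwidth(sc);
    const arma::cx_mat Ssc = S.slice(sc);
    // cumulative sums of auto-spectra |S|^2 per channel
    arma::mat autocs(n + 1, C, arma::fill::zeros);
    for (arma::uword ch = 0; ch < C; ++ch) {
      double cs = 0.0;
      for (arma::uword t = 0; t < n; ++t) {
        cs += std::norm(Ssc(t, ch));
        autocs(t + 1, ch) = cs;
      }
    }
    arma::cx_vec crosscs(n + 1);
    for (arma::uword i = 0; i < C; ++i) {
      for (arma::uword j = i + 1; j < C; ++j) {
        std::complex<double> cs(0.0, 0.0);
        crosscs(0) = cs;
        for (arma::uword t = 0; t < n; ++t) {
          cs += Ssc(t, i) * std::conj(Ssc(t, j));
          crosscs(t + 1) = cs;
        }
        // coherence over time, then average within each component window
        for (int k = 0; k < n_comp; ++k) {
          const int w0 = windows(k, 0), w1 = windows(k, 1);
          double m = 0.0;
          for (int t = w0; t <= w1; ++t) {
            const int lo = std::max(0, t - h);
            const int hi = std::min(static_cast<int>(n) - 1, t + h);
            const double wxx = autocs(hi + 1, i) - autocs(lo, i);
            const double wyy = autocs(hi + 1, j) - autocs(lo, j);
            if (wxx <= 0.0 || wyy <= 0.0) {
              ++zero_count;
              continue;
            }
            const std::complex<double> wxy = crosscs(hi + 1) - crosscs(lo);
            double v = std::abs(wxy) / std::sqrt(wxx * wyy);
            if (v > 1.0) v = 1.0;
            m += v;
          }
          m /= (w1 - w0 + 1);
          for (int b : scale_bands[sc]) acc(k, b)(i, j) += m;
        }
      }
    }
    for (int k = 0; k < n_comp; ++k)
      for (int b : scale_bands[sc]) bandcount[k][b] += 1.0;
  }

  NumericVector out(C * C * n_comp * n_band);
  out.attr("dim") = IntegerVector::create(C, C, n_comp, n_band);
  for (int k = 0; k < n_comp; ++k)
    for (int b = 0; b < n_band; ++b) {
      arma::mat M = acc(k, b) / std::max(bandcount[k][b], 1.0);
      M = M + M.t();
      M.diag().ones();
      for (arma::uword j = 0; j < C; ++j)
        for (arma::uword i = 0; i < C; ++i)
          out[i + C * (j + C * (k + static_cast<arma::uword>(n_comp) * b))] =
              M(i, j);
    }
  return List::create(_["coh"] = out, _["zero_count"] = zero_count);
}
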