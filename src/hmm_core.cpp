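// Scaled forward recursion for an m-state Poisson HMM, evaluated in the
// unconstrained working parameterization, with analytic propagation of first
// and (optionally) second derivatives through every step of the recursion —
// including the linear solve for the stationary initial distribution.
//
// Working-parameter layout (0-based):
//   w[0 .. m-1]                 eta_i  = log(lambda_i)
//   w[m .. m + m(m-1) - 1]      tau_ij row-major, diagonal skipped
//   w[m + m(m-1) .. K-1]        nu_2..nu_m, initial-distribution logits
//                               (only when init_mode == 1)
// init_mode: 0 stationary, 1 freely estimated logits, 2 fixed vector.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct ParamDerivs {
  int m, K, ntau;
  vec lambda;                 // m
  mat Gamma;                  // m x m
  rowvec delta;               // 1 x m
  std::vector<mat> dG;        // K mats, m x m (zero except tau indices)
  std::vector<mat> d2G;       // K*K mats when order >= 2 (a*K+b), symmetric
  mat ddelta;                 // K x m
  std::vector<rowvec> d2delta; // K*K rowvecs when order >= 2
};

inline int tau_index(int m, int i, int j) {
  // position of tau_{ij} (i != j, 0-based) inside the tau block
  return i * (m - 1) + (j > i ? j - 1 : j);
}

// Fill Gamma row i and its tau-derivatives from the row's off-diagonal logits.
void build_tpm(ParamDerivs &pd, const vec &w, int order) {
  const int m = pd.m, K = pd.K;
  pd.Gamma.set_size(m, m);
  pd.dG.assign(K, mat(m, m, fill::zeros));
  if (order >= 2) pd.d2G.assign((size_t)K * K, mat());
  for (int i = 0; i < m; ++i) {
    // logits: diagonal entry is the reference category (logit 0)
    rowvec ex(m);
    double denom = 1.0;
    for (int j = 0; j < m; ++j) {
      if (j == i) { ex(j) = 1.0; continue; }
      ex(j) = std::exp(w(m + tau_index(m, i, j)));
      denom += ex(j);
    }
    rowvec s = ex / denom;            // row i of Gamma
    pd.Gamma.row(i) = s;
    for (int a = 0; a < m; ++a) {
      if (a == i) continue;
      int pa = m + tau_index(m, i, a);
      // ds_k/dt_a = s_k (1{k==a} - s_a)
      pd.dG[pa].row(i) = -s(a) * s;
      pd.dG[pa](i, a) += s(a);
      if (order >= 2) {
        for (int b = 0; b < m; ++b) {
          if (b == i) continue;
          int pb = m + tau_index(m, i, b);
          if (pb < pa) continue;      // fill upper triangle, mirror below
          mat h(m, m, fill::zeros);
          for (int k = 0; k < m; ++k) {
            double dka = (k == a) ? 1.0 : 0.0;
            double dkb = (k == b) ? 1.0 : 0.0;
            double dab = (a == b) ? 1.0 : 0.0;
            h(i, k) = s(k) * (dka * dkb - dka * s(b) - dkb * s(a)
                              + 2.0 * s(a) * s(b) - s(a) * dab);
          }
          pd.d2G[(size_t)pa * K + pb] = h;
          if (pa != pb) pd.d2G[(size_t)pb * K + pa] = h;
        }
      }
    }
  }
}

// Stationary distribution via the augmented linear system delta (I - G + U) = 1,
// U the all-ones matrix, with exact first/second derivatives in the taus.
void build_stationary(ParamDerivs &pd, int order) {
  const int m = pd.m, K = pd.K;
  mat M = eye(m, m) - pd.Gamma + ones(m, m);
  mat Minv;
  if (!inv(Minv, M)) Rcpp::stop("degenerate Markov chain: stationary distribution is not unique");
  pd.delta = ones<rowvec>(m) * Minv;
  pd.ddelta.zeros(K, m);
  for (int a = m; a < m + pd.ntau; ++a)
    pd.ddelta.row(a) = pd.delta * pd.dG[a] * Minv;
  if (order >= 2) {
    pd.d2delta.assign((size_t)K * K, rowvec(m, fill::zeros));
    for (int a = m; a < m + pd.ntau; ++a)
      for (int b = a; b < m + pd.ntau; ++b) {
        const mat &h = pd.d2G[(size_t)a * K + b];
        rowvec r(m, fill::zeros);
        if (h.n_elem) r = pd.delta * h * Minv;
        r += (pd.ddelta.row(a) * pd.dG[b] + pd.ddelta.row(b) * pd.dG[a]) * Minv;
        pd.d2delta[(size_t)a * K + b] = r;
        if (a != b) pd.d2delta[(size_t)b * K + a] = r;
      }
  }
}

// Freely estimated initial distribution: softmax of (0, nu_2, ..., nu_m).
void build_free_init(ParamDerivs &pd, const vec &w, int order) {
  const int m = pd.m, K = pd.K, off = m + pd.ntau;
  rowvec ex(m);
  double denom = 1.0;
  ex(0) = 1.0;
  for (int j = 1; j < m; ++j) { ex(j) = std::exp(w(off + j - 1)); denom += ex(j); }
  rowvec s = ex / denom;
  pd.delta = s;
  pd.ddelta.zeros(K, m);
  for (int a = 1; a < m; ++a) {
    int pa = off + a - 1;
    pd.ddelta.row(pa) = -s(a) * s;
    pd.ddelta(pa, a) += s(a);
  }
  if (order >= 2) {
    pd.d2delta.assign((size_t)K * K, rowvec(m, fill::zeros));
    for (int a = 1; a < m; ++a)
      for (int b = a; b < m; ++b) {
        int pa = off + a - 1, pb = off + b - 1;
        rowvec r(m);
        for (int k = 0; k < m; ++k) {
          double dka = (k == a) ? 1.0 : 0.0;
          double dkb = (k == b) ? 1.0 : 0.0;
          double dab = (a == b) ? 1.0 : 0.0;
          r(k) = s(k) * (dka * dkb - dka * s(b) - dkb * s(a)
                         + 2.0 * s(a) * s(b) - s(a) * dab);
        }
        pd.d2delta[(size_t)pa * K + pb] = r;
        if (pa != pb) pd.d2delta[(size_t)pb * K + pa] = r;
      }
  }
}

} // namespace

// Negative log-likelihood with analytic derivatives.
// order: 0 value, 1 + gradient, 2 + Hessian. x uses NA_INTEGER for missing.
// [[Rcpp::export(name = ".hmm_nll_cpp")]]
Rcpp::List hmm_nll_cpp(Rcpp::IntegerVector x, arma::vec w, int m,
                       int init_mode, arma::vec init_fixed, int order) {
  ParamDerivs pd;
  pd.m = m;
  pd.ntau = m * (m - 1);
  pd.K = (int)w.n_elem;
  const int K = pd.K, T = x.size();

  pd.lambda = exp(w.subvec(0, m - 1));
  const vec &lam = pd.lambda;
  vec loglam = w.subvec(0, m - 1);

  build_tpm(pd, w, order);
  if (init_mode == 0) {
    build_stationary(pd, order);
  } else if (init_mode == 1) {
    build_free_init(pd, w, order);
  } else {
    pd.delta = conv_to<rowvec>::from(init_fixed);
    pd.ddelta.zeros(K, m);
    if (order >= 2) pd.d2delta.assign((size_t)K * K, rowvec(m, fill::zeros));
  }

  double ll = 0.0;
  vec dll(K, fill::zeros);
  mat d2ll(K, K, fill::zeros);

  rowvec phi(m), u(m), v(m), p(m), dp(m), d2pd(m);
  mat dphi(K, m, fill::zeros), dv(K, m), du(K, m);
  std::vector<rowvec> d2phi, d2v;
  if (order >= 2) {
    d2phi.assign((size_t)K * K, rowvec(m, fill::zeros));
    d2v.assign((size_t)K * K, rowvec(m, fill::zeros));
  }
  vec dc(K);
  mat d2c(K, K);

  for (int t = 0; t < T; ++t) {
    const bool miss = (x[t] == NA_INTEGER);
    if (miss) {
      p.ones(); dp.zeros(); d2pd.zeros();
    } else {
      double xt = (double)x[t];
      double lgx = std::lgamma(xt + 1.0);
      for (int i = 0; i < m; ++i) {
        p(i) = std::exp(-lam(i) + xt * loglam(i) - lgx);
        dp(i) = p(i) * (xt - lam(i));                         // d/d eta_i
        d2pd(i) = p(i) * ((xt - lam(i)) * (xt - lam(i)) - lam(i));
      }
    }

    if (t == 0) {
      v = pd.delta % p;
      if (order >= 1) {
        for (int a = 0; a < K; ++a) {
          dv.row(a) = pd.ddelta.row(a) % p;
          if (a < m && !miss) dv(a, a) += pd.delta(a) * dp(a);
        }
      }
      if (order >= 2) {
        for (int a = 0; a < K; ++a)
          for (int b = a; b < K; ++b) {
            rowvec r = pd.d2delta[(size_t)a * K + b] % p;
            if (!miss) {
              if (b < m) r(b) += pd.ddelta(a, b) * dp(b);
              if (a < m) r(a) += pd.ddelta(b, a) * dp(a);
              if (a == b && a < m) r(a) += pd.delta(a) * d2pd(a);
            }
            d2v[(size_t)a * K + b] = r;
          }
      }
    } else {
      u = phi * pd.Gamma;
      v = u % p;
      if (order >= 1) {
        for (int a = 0; a < K; ++a) {
          du.row(a) = dphi.row(a) * pd.Gamma + phi * pd.dG[a];
          dv.row(a) = du.row(a) % p;
          if (a < m && !miss) dv(a, a) += u(a) * dp(a);
        }
      }
      if (order >= 2) {
        for (int a = 0; a < K; ++a)
          for (int b = a; b < K; ++b) {
            rowvec r = d2phi[(size_t)a * K + b] * pd.Gamma
                     + dphi.row(a) * pd.dG[b] + dphi.row(b) * pd.dG[a];
            const mat &h = pd.d2G[(size_t)a * K + b];
            if (h.n_elem) r += phi * h;
            r %= p;
            if (!miss) {
              if (b < m) r(b) += du(a, b) * dp(b);
              if (a < m) r(a) += du(b, a) * dp(a);
              if (a == b && a < m) r(a) += u(a) * d2pd(a);
            }
            d2v[(size_t)a * K + b] = r;
          }
      }
    }

    double c = accu(v);
    if (!(c > 0.0) || !std::isfinite(c)) {
      // numerically impossible observation under these parameters
      return Rcpp::List::create(Rcpp::Named("value") = R_PosInf,
                                Rcpp::Named("grad") = Rcpp::NumericVector(K),
                                Rcpp::Named("hess") = R_NilValue);
    }
    ll += std::log(c);
    if (order >= 1) {
      dc = dv * ones(m);
      dll += dc / c;
    }
    if (order >= 2) {
      for (int a = 0; a < K; ++a)
        for (int b = a; b < K; ++b) {
          double s2 = accu(d2v[(size_t)a * K + b]);
          d2c(a, b) = s2;
          double val = s2 / c - dc(a) * dc(b) / (c * c);
          d2ll(a, b) += val;
        }
    }

    phi = v / c;
    if (order >= 1)
      for (int a = 0; a < K; ++a)
        dphi.row(a) = (dv.row(a) - phi * dc(a)) / c;
    if (order >= 2)
      for (int a = 0; a < K; ++a)
        for (int b = a; b < K; ++b) {
          rowvec r = (d2v[(size_t)a * K + b] - phi * d2c(a, b)) / c
                   - (dphi.row(a) * dc(b) + dphi.row(b) * dc(a)) / c;
          d2phi[(size_t)a * K + b] = r;
        }
  }

  Rcpp::List out;
  out["value"] = -ll;
  if (order >= 1) out["grad"] = Rcpp::wrap(conv_to<std::vector<double>>::from(-dll));
  if (order >= 2) {
    mat H = -d2ll;
    H = symmatu(H);
    out["hess"] = H;
  }
  return out;
}
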