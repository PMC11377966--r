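// Likelihood core for the four-state continuous-time Markov model.
//
// The panel likelihood needs thousands of 4x4 matrix exponentials per
// evaluation (one per observation interval), so the hot path lives here.
// For each distinct covariate pattern we eigendecompose Q once and
// propagate P(dt) = V exp(D dt) V^{-1}; if the decomposition is unreliable
// (near-defective Q) we fall back to the Pade matrix exponential per pair.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NSTATE = 4;
static const int DEAD = 3; // 0-based index of the absorbing state

static mat build_Q_from(const vec& logq0, const mat& beta, const imat& tridx,
                        const rowvec& z) {
  mat Q(NSTATE, NSTATE, fill::zeros);
  const uword K = logq0.n_elem;
  for (uword k = 0; k < K; ++k) {
    double lp = logq0(k);
    for (uword j = 0; j < z.n_elem; ++j) lp += beta(k, j) * z(j);
    Q(tridx(k, 0) - 1, tridx(k, 1) - 1) = std::exp(lp);
  }
  for (int r = 0; r < NSTATE; ++r) {
    Q(r, r) = 0.0;
    Q(r, r) = -accu(Q.row(r));
  }
  return Q;
}

// [[Rcpp::export]]
arma::mat expm_mat(const arma::mat& A) { return expmat(A); }

static bool safe_expmat(const mat& A, mat& out) {
  try {
    out = expmat(A);
    return out.is_finite();
  } catch (...) {
    return false;
  }
}

// [[Rcpp::export]]
arma::mat build_Q_cpp(const arma::vec& logq0, const arma::mat& beta,
                      const arma::imat& tridx, const arma::rowvec& z) {
  return build_Q_from(logq0, beta, tridx, z);
}

// Log-likelihood and analytic gradient, summed over pairs.
//
// With Q = V D V^{-1}, the derivative of P(dt) along a perturbation dQ is
// V (F % Phi) V^{-1}, F = V^{-1} dQ V, Phi_ij = (e^{li dt} - e^{lj dt}) /
// (li - lj) (-> dt e^{li dt} as lj -> li). For the log-intensity of
// transition r->s, dQ = q_rs (E_rs - E_rr) is rank one, which reduces the
// directional derivative of a row of P to a handful of inner products; the
// covariate coefficients reuse the same quantities scaled by z.
// [[Rcpp::export]]
Rcpp::List panel_loglik_grad_cpp(const arma::vec& logq0, const arma::mat& beta,
                                 const arma::imat& tridx,
                                 const arma::mat& patterns,
                                 const arma::ivec& from, const arma::ivec& to,
                                 const arma::vec& dt, const arma::ivec& pat) {
  const uword npat = patterns.n_rows;
  const uword n = from.n_elem;
  const uword K = logq0.n_elem;
  const uword C = beta.n_cols;

  std::vector<mat> Qs(npat);
  std::vector<cx_mat> V(npat), Vinv(npat);
  std::vector<cx_vec> ev(npat);
  std::vector<bool> ok(npat, false), degenerate(npat, false);
  for (uword p = 0; p < npat; ++p) {
    Qs[p] = build_Q_from(logq0, beta, tridx, patterns.row(p));
    // a wildly scaled Q (optimizer overshoot) has zero likelihood anyway;
    // flag it instead of letting the matrix exponential blow up
    if (!Qs[p].is_finite() || abs(Qs[p]).max() > 1e6) {
      degenerate[p] = true;
      continue;
    }
    cx_vec d;
    cx_mat v;
    if (eig_gen(d, v, Qs[p])) {
      cx_mat vi;
      if (inv(vi, v)) {
        mat rec = real(v * diagmat(d) * vi);
        if (norm(rec - Qs[p], "fro") < 1e-10 * (1.0 + norm(Qs[p], "fro"))) {
          V[p] = v; Vinv[p] = vi; ev[p] = d; ok[p] = true;
        }
      }
    }
  }

  double total = 0.0;
  vec grad(K * (1 + C), fill::zeros);
  bool finite = true;

  // per-pattern precomputations for the rank-one derivative
  std::vector<cx_mat> W(npat); // K x 4: row k holds V.row(s_k) - V.row(r_k)
  for (uword p = 0; p < npat; ++p) {
    if (!ok[p]) continue;
    cx_mat w(K, NSTATE);
    for (uword k = 0; k < K; ++k)
      w.row(k) = V[p].row(tridx(k, 1) - 1) - V[p].row(tridx(k, 0) - 1);
    W[p] = w;
  }

  for (uword i = 0; i < n; ++i) {
    const int f = from(i) - 1;
    const int t = to(i) - 1;
    const uword p = (uword)(pat(i) - 1);
    const double h = dt(i);
    const rowvec z = patterns.row(p);
    vec dval(K, fill::zeros);
    double val;

    if (degenerate[p]) { finite = false; continue; }
    if (ok[p]) {
      cx_vec el = exp(ev[p] * h);
      cx_rowvec prow = (V[p].row(f) % el.st()) * Vinv[p];
      if (t != DEAD) {
        val = prow(t).real();
      } else {
        val = 0.0;
        for (int r = 0; r < DEAD; ++r) val += prow(r).real() * Qs[p](r, DEAD);
      }
      if (val <= 0.0) { finite = false; continue; }

      cx_mat Phi(NSTATE, NSTATE);
      for (int a = 0; a < NSTATE; ++a) {
        for (int b = 0; b < NSTATE; ++b) {
          cx_double dl = ev[p](a) - ev[p](b);
          Phi(a, b) = (std::abs(dl) > 1e-8) ? (el(a) - el(b)) / dl
                                            : h * el(a);
        }
      }
      // g_r = (V.row(f) % Vinv.col(r).t()) * Phi, for each live source r
      cx_mat G(DEAD, NSTATE);
      for (int r = 0; r < DEAD; ++r)
        G.row(r) = (V[p].row(f) % Vinv[p].col(r).st()) * Phi;

      for (uword k = 0; k < K; ++k) {
        const int rk = tridx(k, 0) - 1;
        const int sk = tridx(k, 1) - 1;
        const double c = Qs[p](rk, sk);
        cx_rowvec gw = G.row(rk) % W[p].row(k); // 1 x 4
        double dv;
        if (t != DEAD) {
          cx_double acc = 0;
          for (int j = 0; j < NSTATE; ++j) acc += gw(j) * Vinv[p](j, t);
          dv = c * acc.real();
        } else {
          dv = 0.0;
          for (int tt = 0; tt < DEAD; ++tt) {
            cx_double acc = 0;
            for (int j = 0; j < NSTATE; ++j) acc += gw(j) * Vinv[p](j, tt);
            dv += c * acc.real() * Qs[p](tt, DEAD);
          }
          if (sk == DEAD) dv += prow(rk).real() * c; // d q_{rk,dead} term
        }
        dval(k) = dv;
      }
    } else {
      // rare fallback (near-defective Q): Pade expm, central differences
      mat P;
      if (!safe_expmat(Qs[p] * h, P)) { finite = false; continue; }
      auto value_at = [&](const vec& lq, const mat& bt) {
        mat Qx = build_Q_from(lq, bt, tridx, z);
        mat Px;
        if (!safe_expmat(Qx * h, Px)) return 0.0;
        if (t != DEAD) return Px(f, t);
        double v2 = 0.0;
        for (int r = 0; r < DEAD; ++r) v2 += Px(f, r) * Qx(r, DEAD);
        return v2;
      };
      if (t != DEAD) {
        val = P(f, t);
      } else {
        val = 0.0;
        for (int r = 0; r < DEAD; ++r) val += P(f, r) * Qs[p](r, DEAD);
      }
      if (val <= 0.0) { finite = false; continue; }
      const double step = 1e-6;
      for (uword k = 0; k < K; ++k) {
        vec lqp = logq0, lqm = logq0;
        lqp(k) += step; lqm(k) -= step;
        dval(k) = (value_at(lqp, beta) - value_at(lqm, beta)) / (2 * step);
      }
    }

    total += std::log(val);
    for (uword k = 0; k < K; ++k) {
      const double gk = dval(k) / val;
      grad(k) += gk;
      for (uword j = 0; j < C; ++j) grad(K + j * K + k) += gk * z(j);
    }
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = finite ? total
                              : -std::numeric_limits<double>::infinity(),
                            Rcpp::Named("gradient") = grad);
}

// Per-pair log-likelihood contributions.
// from, to: 1-based states; to == 4 is an exactly observed death time and
// contributes the density sum_r P(dt)[from, r] * q_{r,dead}.
// pat: 1-based row index into `patterns` (unique covariate rows).
// [[Rcpp::export]]
arma::vec panel_loglik_pairs_cpp(const arma::vec& logq0, const arma::mat& beta,
                                 const arma::imat& tridx,
                                 const arma::mat& patterns,
                                 const arma::ivec& from, const arma::ivec& to,
                                 const arma::vec& dt, const arma::ivec& pat) {
  const uword npat = patterns.n_rows;
  const uword n = from.n_elem;

  std::vector<mat> Qs(npat);
  std::vector<cx_mat> V(npat), Vinv(npat);
  std::vector<cx_vec> ev(npat);
  std::vector<bool> ok(npat, false), degenerate(npat, false);

  for (uword p = 0; p < npat; ++p) {
    Qs[p] = build_Q_from(logq0, beta, tridx, patterns.row(p));
    if (!Qs[p].is_finite() || abs(Qs[p]).max() > 1e6) {
      degenerate[p] = true;
      continue;
    }
    cx_vec d;
    cx_mat v;
    if (eig_gen(d, v, Qs[p])) {
      cx_mat vi;
      if (inv(vi, v)) {
        // accept the decomposition only if it reconstructs Q accurately
        mat rec = real(v * diagmat(d) * vi);
        double err = norm(rec - Qs[p], "fro");
        if (err < 1e-10 * (1.0 + norm(Qs[p], "fro"))) {
          V[p] = v;
          Vinv[p] = vi;
          ev[p] = d;
          ok[p] = true;
        }
      }
    }
  }

  vec ll(n);
  for (uword i = 0; i < n; ++i) {
    const int f = from(i) - 1;
    const int t = to(i) - 1;
    const uword p = (uword)(pat(i) - 1);
    double val;
    if (degenerate[p]) {
      ll(i) = -std::numeric_limits<double>::infinity();
      continue;
    }
    if (ok[p]) {
      cx_rowvec row = (V[p].row(f) % exp(ev[p].t() * dt(i))) * Vinv[p];
      if (t != DEAD) {
        val = row(t).real();
      } else {
        val = 0.0;
        for (int r = 0; r < DEAD; ++r)
          val += row(r).real() * Qs[p](r, DEAD);
      }
    } else {
      mat P;
      if (!safe_expmat(Qs[p] * dt(i), P)) {
        ll(i) = -std::numeric_limits<double>::infinity();
        continue;
      }
      if (t != DEAD) {
        val = P(f, t);
      } else {
        val = 0.0;
        for (int r = 0; r < DEAD; ++r) val += P(f, r) * Qs[p](r, DEAD);
      }
    }
    ll(i) = (val > 0.0) ? std::log(val) : -std::numeric_limits<double>::infinity();
  }
  return ll;
}
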