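// Fast delayed-LNA window filter for the one-species TTFL model.
// Mirrors the R reference path (init_window + propagate_window +
// delayed_kalman_update) exactly; cross-checked against it in the tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double hill_nu(double u, double rmax, double kpc, double n) {
  return rmax / (1.0 + std::pow(u / kpc, n));
}

static inline double hill_dnu(double u, double rmax, double kpc, double n) {
  if (u <= 0.0) return (n == 1.0) ? -(rmax / kpc) : 0.0;
  double z = std::pow(u / kpc, n);
  return -(rmax * n / kpc) * std::pow(u / kpc, n - 1.0) /
         ((1.0 + z) * (1.0 + z));
}

// Kalman update of the window block [0, cur) with observation row fw placed
// at positions [b0, b0 + fw.n_elem); returns the innovation log-density.
static double window_update(arma::vec &rho, arma::mat &P, int cur, int b0,
                            const arma::vec &fw, double nv, double y,
                            double &mu_y, double &S_sig, bool &ok) {
  int Lb = fw.n_elem;
  arma::vec Pf(cur, arma::fill::zeros);
  for (int k = 0; k < Lb; ++k) {
    double w = fw(k);
    if (w == 0.0) continue;
    for (int i = 0; i < cur; ++i) Pf(i) += w * P(i, b0 + k);
  }
  mu_y = 0.0;
  S_sig = 0.0;
  for (int k = 0; k < Lb; ++k) {
    mu_y += fw(k) * rho(b0 + k);
    S_sig += fw(k) * Pf(b0 + k);
  }
  double S = S_sig + nv;
  if (!(S > 0.0) || !std::isfinite(S) || !std::isfinite(mu_y)) {
    ok = false;
    return R_NegInf;
  }
  double ll = R::dnorm(y, mu_y, std::sqrt(S), 1);
  double gain = (y - mu_y) / S;
  for (int i = 0; i < cur; ++i) rho(i) += Pf(i) * gain;
  // symmetric rank-1 downdate P -= Pf Pf' / S
  for (int j = 0; j < cur; ++j) {
    double c = Pf(j) / S;
    if (c == 0.0) continue;
    for (int i = 0; i < cur; ++i) P(i, j) -= Pf(i) * c;
  }
  return ll;
}

// [[Rcpp::export]]
List dlna_filter_cpp(NumericVector y_in, double exposure, double dt,
                     double tau_max, double rmax, double kpc, double hill_n,
                     double mu, NumericVector kern_w, double kappa,
                     double sigma_eps, double init_rate, double mu0,
                     double mean0, double var0, bool trapezoid) {
  arma::vec y(y_in.begin(), y_in.size());
  int n = y.n_elem;
  int L = (int)std::lround(exposure / dt);
  int M = (int)std::lround(tau_max / dt);
  int n_head = (int)std::lround(tau_max / exposure);
  if ((int)kern_w.size() != M + 1)
    stop("dlna_filter_cpp: kernel weight length mismatch");
  if (n <= n_head) stop("dlna_filter_cpp: series must span more than tau_max");

  // exposure-integral weights over a block of L+1 lattice points
  arma::vec fw(L + 1);
  if (trapezoid) {
    fw.fill(kappa * dt);
    fw(0) = fw(L) = 0.5 * kappa * dt;
  } else {
    fw.fill(kappa * dt);
    fw(0) = 0.0;
  }
  arma::vec kwrev(M + 1); // kwrev(pos) = K(lag of position), newest last
  for (int j = 0; j <= M; ++j) kwrev(j) = kern_w[M - j];

  double nv = sigma_eps * sigma_eps;
  arma::vec rho(M + 1, arma::fill::zeros);
  arma::mat P(M + 1, M + 1, arma::fill::zeros);
  arma::vec pred_mean(n), pred_vs(n), pred_vo(n), sm_mean(n), sm_var(n);
  pred_mean.fill(NA_REAL); pred_vs.fill(NA_REAL); pred_vo.fill(NA_REAL);
  sm_mean.fill(NA_REAL); sm_var.fill(NA_REAL);
  double ll = 0.0, mu_y, S_sig;
  bool ok = true;

  // ---- phase A: grow the window over [0, tau_max], plain birth-death ----
  rho(0) = mean0;
  P(0, 0) = var0;
  int cur = 1;
  double coef = 1.0 - mu0 * dt;
  for (int s = 1; s <= M && ok; ++s) {
    double x = rho(cur - 1);
    double noise = (init_rate + mu0 * std::max(x, 0.0)) * dt;
    rho(cur) = x + (init_rate - mu0 * x) * dt;
    for (int i = 0; i < cur; ++i) {
      double v = coef * P(i, cur - 1);
      P(i, cur) = v;
      P(cur, i) = v;
    }
    P(cur, cur) = coef * coef * P(cur - 1, cur - 1) + noise;
    ++cur;
    if (s % L == 0) {
      int k = s / L; // 1-based head observation index
      ll += window_update(rho, P, cur, cur - 1 - L, fw, nv, y(k - 1),
                          mu_y, S_sig, ok);
      pred_mean(k - 1) = mu_y;
      pred_vs(k - 1) = S_sig;
      pred_vo(k - 1) = S_sig + nv;
    }
  }

  // partial smoothing of bin 1 (leading block of the completed window)
  if (ok) {
    double sm = 0.0, sv = 0.0;
    for (int c = 0; c <= L; ++c) {
      sm += fw(c) * rho(c);
      double pf = 0.0;
      for (int c2 = 0; c2 <= L; ++c2) pf += fw(c2) * P(c, c2);
      sv += fw(c) * pf;
    }
    sm_mean(0) = sm;
    sm_var(0) = sv;
  }

  // ---- phase B: delayed dynamics on the full sliding window ----
  // The window lives in a ring buffer: logical lattice index i (0 = oldest)
  // sits at physical slot (off + i) mod N, so sliding the window is an
  // index rotation instead of an O(N^2) copy.
  int N = M + 1, off = 0;
  arma::vec a_phys(N), r_phys(N), Pf(N), kw_phys(N);
  for (int k = n_head + 1; k <= n && ok; ++k) {
    for (int s = 0; s < L; ++s) {
      for (int i = 0; i < N; ++i) kw_phys((off + i) % N) = kwrev(i);
      double u = arma::dot(kw_phys, rho);
      if (u < 0.0) u = 0.0;
      double nu = hill_nu(u, rmax, kpc, hill_n);
      double dnu = hill_dnu(u, rmax, kpc, hill_n);
      int cur = (off + M) % N;            // physical slot of newest state
      double x = rho(cur);
      double newmean = x + (nu - mu * x) * dt;
      double noise = (nu + mu * std::max(x, 0.0)) * dt;
      a_phys = (dt * dnu) * kw_phys;
      a_phys(cur) += 1.0 - mu * dt;
      r_phys = P * a_phys;
      double newvar = arma::dot(a_phys, r_phys) + noise;
      // the dropped (oldest) point's slot is recycled for the new state
      rho(off) = newmean;
      for (int q = 0; q < N; ++q) {
        P(q, off) = r_phys(q);
        P(off, q) = r_phys(q);
      }
      P(off, off) = newvar < 0.0 ? 0.0 : newvar;
      off = (off + 1) % N;
      if (!std::isfinite(newmean) || !std::isfinite(newvar)) {
        ok = false;
        break;
      }
    }
    if (!ok) break;
    // observation row acts on the trailing exposure block (logical M-L..M)
    Pf.zeros();
    double mu_y2 = 0.0;
    for (int c = 0; c <= L; ++c) {
      int pc = (off + M - L + c) % N;
      double w = fw(c);
      mu_y2 += w * rho(pc);
      if (w != 0.0) Pf += w * P.col(pc);
    }
    S_sig = 0.0;
    for (int c = 0; c <= L; ++c) S_sig += fw(c) * Pf((off + M - L + c) % N);
    double S = S_sig + nv;
    if (!(S > 0.0) || !std::isfinite(S) || !std::isfinite(mu_y2)) {
      ok = false;
      break;
    }
    ll += R::dnorm(y(k - 1), mu_y2, std::sqrt(S), 1);
    double gain = (y(k - 1) - mu_y2) / S;
    rho += gain * Pf;
    for (int j = 0; j < N; ++j) {
      double cj = Pf(j) / S;
      if (cj == 0.0) continue;
      for (int i = 0; i < N; ++i) P(i, j) -= Pf(i) * cj;
    }
    pred_mean(k - 1) = mu_y2;
    pred_vs(k - 1) = S_sig;
    pred_vo(k - 1) = S;
    // partial smoothing of the oldest complete exposure bin (about to exit)
    int b = k - n_head + 1;
    double sm = 0.0, sv = 0.0;
    for (int c = 0; c <= L; ++c) {
      int pc = (off + c) % N;
      sm += fw(c) * rho(pc);
      double pf = 0.0;
      for (int c2 = 0; c2 <= L; ++c2) pf += fw(c2) * P(pc, (off + c2) % N);
      sv += fw(c) * pf;
    }
    sm_mean(b - 1) = sm;
    sm_var(b - 1) = sv;
  }

  if (ok) { // bins still inside the final window: fully smoothed moments
    for (int b = n - n_head + 2; b <= n; ++b) {
      int o0 = M - (n - b + 1) * L;
      double sm = 0.0, sv = 0.0;
      for (int c = 0; c <= L; ++c) {
        int pc = (off + o0 + c) % N;
        sm += fw(c) * rho(pc);
        double pf = 0.0;
        for (int c2 = 0; c2 <= L; ++c2)
          pf += fw(c2) * P(pc, (off + o0 + c2) % N);
        sv += fw(c) * pf;
      }
      sm_mean(b - 1) = sm;
      sm_var(b - 1) = sv;
    }
  } else {
    ll = R_NegInf;
  }

  return List::create(
      _["loglik"] = ll, _["pred_mean"] = pred_mean,
      _["pred_var_signal"] = pred_vs, _["pred_var_obs"] = pred_vo,
      _["smooth_mean"] = sm_mean, _["smooth_var"] = sm_var);
}
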