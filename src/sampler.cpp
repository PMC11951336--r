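// Compiled engine for the adaptive Metropolis-within-Gibbs sampler.
//
// All randomness flows through R's RNG (GetRNGstate/PutRNGstate via Rcpp),
// so chains are reproducible from a single set.seed() and the engine shares
// one stream with R-level code. RNG consumption order per iteration:
// multinomial splits over non-zero cells in canonical cell order, gamma
// draws for lambda1 (i fastest, then h1), lambda2 (t, then h1, then h2),
// lambda3 (k, then h2), then one uniform + d normals + one uniform for the
// Metropolis coefficient update.
//
// Cell order: linear index c = i + N*(t + T*k), matching R array layout.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double ETA_CLAMP = 700.0;

struct Dims {
  int N, T, K, P, H1, H2, C, TK, HH;
};

// eta = X beta (clamped), W = offsets * exp(eta)
static void compute_W(const double* X, const double* offs, const double* beta,
                      const Dims& dm, double* W) {
  std::vector<double> eta(dm.C, 0.0);
  for (int p = 0; p < dm.P; ++p) {
    const double b = beta[p];
    const double* xp = X + (size_t)dm.C * p;
    for (int c = 0; c < dm.C; ++c) eta[c] += xp[c] * b;
  }
  for (int c = 0; c < dm.C; ++c) {
    double e = eta[c];
    if (e > ETA_CLAMP) e = ETA_CLAMP;
    if (e < -ETA_CLAMP) e = -ETA_CLAMP;
    W[c] = offs[c] * std::exp(e);
  }
}

// A[(t,k), h1] = sum_h2 l2[t,h1,h2] * l3[k,h2]
static void compute_A(const double* l2, const double* l3, const Dims& dm,
                      double* A) {
  const int T = dm.T, K = dm.K, H1 = dm.H1, H2 = dm.H2, TK = dm.TK;
  std::fill(A, A + (size_t)TK * H1, 0.0);
  for (int h1 = 0; h1 < H1; ++h1) {
    double* Ah = A + (size_t)TK * h1;
    for (int h2 = 0; h2 < H2; ++h2) {
      const double* l2c = l2 + T * (h1 + H1 * h2);
      const double* l3c = l3 + K * h2;
      for (int k = 0; k < K; ++k) {
        const double g = l3c[k];
        if (g == 0.0) continue;
        double* Atk = Ah + T * k;
        for (int t = 0; t < T; ++t) Atk[t] += l2c[t] * g;
      }
    }
  }
}

// lam[c] = sum_h1 l1[i,h1] * A[(t,k),h1]
static void compute_rate(const double* l1, const double* A, const Dims& dm,
                         double* lam) {
  const int N = dm.N, H1 = dm.H1, TK = dm.TK;
  std::fill(lam, lam + (size_t)dm.C, 0.0);
  for (int h1 = 0; h1 < H1; ++h1) {
    const double* l1c = l1 + (size_t)N * h1;
    const double* Ah = A + (size_t)TK * h1;
    for (int tk = 0; tk < TK; ++tk) {
      const double a = Ah[tk];
      double* lamc = lam + (size_t)N * tk;
      for (int i = 0; i < N; ++i) lamc[i] += l1c[i] * a;
    }
  }
}

// Poisson log-likelihood, log(Y!) excluded (added back as a constant by the
// caller); mu = W * lam cellwise.
static double loglik_core(const int* y, const double* W, const double* lam,
                          int C) {
  double ll = 0.0;
  for (int c = 0; c < C; ++c) {
    const double mu = W[c] * lam[c];
    if (y[c] > 0) {
      if (mu <= 0.0) return R_NegInf;
      ll += y[c] * std::log(mu) - mu;
    } else {
      ll -= mu;
    }
  }
  return ll;
}

// V[h1, tk] = sum_i l1[i,h1] * W[i + N*tk]
static void compute_V(const double* l1, const double* W, const Dims& dm,
                      double* V) {
  const int N = dm.N, H1 = dm.H1, TK = dm.TK;
  for (int tk = 0; tk < TK; ++tk) {
    const double* Wc = W + (size_t)N * tk;
    for (int h1 = 0; h1 < H1; ++h1) {
      const double* l1c = l1 + (size_t)N * h1;
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += l1c[i] * Wc[i];
      V[h1 + H1 * tk] = s;
    }
  }
}

// in-place lower Cholesky of S (d x d, column-major); returns false if the
// matrix is not (numerically) positive definite
static bool chol_lower(std::vector<double>& S, int d) {
  for (int j = 0; j < d; ++j) {
    double diag = S[j + d * j];
    for (int k = 0; k < j; ++k) diag -= S[j + d * k] * S[j + d * k];
    if (diag <= 0.0 || !R_finite(diag)) return false;
    diag = std::sqrt(diag);
    S[j + d * j] = diag;
    for (int i = j + 1; i < d; ++i) {
      double v = S[i + d * j];
      for (int k = 0; k < j; ++k) v -= S[i + d * k] * S[j + d * k];
      S[i + d * j] = v / diag;
    }
    for (int i = 0; i < j; ++i) S[i + d * j] = 0.0;
  }
  return true;
}

struct Engine {
  Dims dm;
  bool cp;
  const int* y;
  const double* offs;
  const double* X;
  std::vector<int> nz;
  // state
  std::vector<double> l1, l2, l3, beta;
  // adaptation
  std::vector<double> amean, aM2;
  long an;
  int n0;
  double p_fixed, sigma2;
  // priors
  double aa, ab, ga, gb, ea, eb;
  // workspaces
  std::vector<double> W, Wprop, A, lam, V, rate1, rate2, rate3, prob;
  std::vector<int> m1, m2, m3, split;
  double ll_const;  // -sum log(Y!)

  void init(const IntegerVector& counts, const NumericVector& offsets,
            const NumericMatrix& Xmat, int N, int T, int K, int H1, int H2,
            bool cp_mode) {
    dm.N = N; dm.T = T; dm.K = K; dm.P = Xmat.ncol();
    dm.H1 = H1; dm.H2 = H2; dm.C = N * T * K; dm.TK = T * K;
    dm.HH = H1 * H2;
    cp = cp_mode;
    y = counts.begin(); offs = offsets.begin(); X = Xmat.begin();
    nz.clear();
    ll_const = 0.0;
    for (int c = 0; c < dm.C; ++c) {
      if (y[c] > 0) nz.push_back(c);
      ll_const -= std::lgamma((double)y[c] + 1.0);
    }
    W.resize(dm.C); Wprop.resize(dm.C); lam.resize(dm.C);
    A.assign((size_t)dm.TK * H1, 0.0);
    V.assign((size_t)H1 * dm.TK, 0.0);
    rate1.assign((size_t)N * H1, 0.0);
    rate2.assign((size_t)T * dm.HH, 0.0);
    rate3.assign((size_t)K * H2, 0.0);
    prob.assign(dm.HH, 0.0);
    m1.assign((size_t)N * H1, 0);
    m2.assign((size_t)T * dm.HH, 0);
    m3.assign((size_t)K * H2, 0);
    split.assign(dm.HH, 0);
  }

  void thin() {
    const int N = dm.N, T = dm.T, H1 = dm.H1, H2 = dm.H2, HH = dm.HH;
    std::fill(m1.begin(), m1.end(), 0);
    std::fill(m2.begin(), m2.end(), 0);
    std::fill(m3.begin(), m3.end(), 0);
    for (size_t idx = 0; idx < nz.size(); ++idx) {
      const int c = nz[idx];
      const int i = c % N;
      const int tk = c / N;
      const int t = tk % T;
      const int k = tk / T;
      double tot = 0.0;
      for (int h2 = 0; h2 < H2; ++h2) {
        const double g3 = l3[k + dm.K * h2];
        for (int h1 = 0; h1 < H1; ++h1) {
          const double v =
              (l1[i + N * h1] * l2[t + T * (h1 + H1 * h2)]) * g3;
          prob[h1 + H1 * h2] = v;
          tot += v;
        }
      }
      if (!(tot > 0.0) || !R_finite(tot))
        stop("degenerate split probabilities at cell %d", c + 1);
      const int yc = y[c];
      if (yc <= 32) {
        // small counts: draw yc categorical labels by CDF walk (equivalent
        // to a multinomial split, much cheaper than successive binomials)
        std::fill(split.begin(), split.end(), 0);
        for (int r = 0; r < yc; ++r) {
          const double u = unif_rand() * tot;
          double acc = 0.0;
          int h = 0;
          for (; h < HH - 1; ++h) {
            acc += prob[h];
            if (u <= acc) break;
          }
          ++split[h];
        }
      } else {
        for (int h = 0; h < HH; ++h) prob[h] /= tot;
        rmultinom(yc, prob.data(), HH, split.data());
      }
      for (int h2 = 0; h2 < H2; ++h2) {
        for (int h1 = 0; h1 < H1; ++h1) {
          const int s = split[h1 + H1 * h2];
          if (s == 0) continue;
          m1[i + N * h1] += s;
          m2[t + T * (h1 + H1 * h2)] += s;
          m3[k + dm.K * h2] += s;
        }
      }
    }
  }

  void update_cores() {
    const int N = dm.N, T = dm.T, K = dm.K, H1 = dm.H1, H2 = dm.H2,
              TK = dm.TK;
    // lambda1 | lambda2, lambda3
    compute_A(l2.data(), l3.data(), dm, A.data());
    std::fill(rate1.begin(), rate1.end(), 0.0);
    for (int h1 = 0; h1 < H1; ++h1) {
      const double* Ah = A.data() + (size_t)TK * h1;
      double* r = rate1.data() + (size_t)N * h1;
      for (int tk = 0; tk < TK; ++tk) {
        const double a = Ah[tk];
        const double* Wc = W.data() + (size_t)N * tk;
        for (int i = 0; i < N; ++i) r[i] += Wc[i] * a;
      }
    }
    for (int h1 = 0; h1 < H1; ++h1)
      for (int i = 0; i < N; ++i) {
        const size_t q = i + (size_t)N * h1;
        l1[q] = R::rgamma(aa + m1[q], 1.0 / (ab + rate1[q]));
      }
    // lambda2 | new lambda1, lambda3
    compute_V(l1.data(), W.data(), dm, V.data());
    for (int h2 = 0; h2 < H2; ++h2)
      for (int h1 = 0; h1 < H1; ++h1) {
        if (cp && h1 != h2) continue;
        const double* l3c = l3.data() + (size_t)K * h2;
        for (int t = 0; t < T; ++t) {
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += V[h1 + H1 * (t + T * k)] * l3c[k];
          const size_t q = t + (size_t)T * (h1 + H1 * h2);
          l2[q] = R::rgamma(ga + m2[q], 1.0 / (gb + s));
        }
      }
    // lambda3 | new lambda1, new lambda2
    for (int h2 = 0; h2 < H2; ++h2)
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int t = 0; t < T; ++t)
          for (int h1 = 0; h1 < H1; ++h1)
            s += V[h1 + H1 * (t + T * k)] * l2[t + T * (h1 + H1 * h2)];
        const size_t q = k + (size_t)K * h2;
        l3[q] = R::rgamma(ea + m3[q], 1.0 / (eb + s));
      }
  }

  double beta_logprior(const std::vector<double>& b) const {
    double s = 0.0;
    for (int p = 0; p < dm.P; ++p) s += b[p] * b[p];
    return -0.5 * s / sigma2;
  }

  // returns log-likelihood (with constant) at the current state after the
  // MH step; updates beta/W in place
  double mh_beta(int& accepted) {
    const int d = dm.P;
    compute_A(l2.data(), l3.data(), dm, A.data());
    compute_rate(l1.data(), A.data(), dm, lam.data());
    const double ll0 = loglik_core(y, W.data(), lam.data(), dm.C);
    const double lp0 = ll0 + beta_logprior(beta);
    const double u_comp = unif_rand();
    bool use_fixed = (an <= n0) || (u_comp < p_fixed);
    std::vector<double> L;
    if (!use_fixed) {
      L.assign(aM2.begin(), aM2.end());
      const double sc = (2.38 * 2.38 / d) / (double)(an - 1);
      for (size_t q = 0; q < L.size(); ++q) L[q] *= sc;
      if (an < 2 || !chol_lower(L, d)) use_fixed = true;
    }
    if (use_fixed) {
      L.assign(sigma_fixed.begin(), sigma_fixed.end());
      const double sc = 0.1 * 0.1 / d;
      for (size_t q = 0; q < L.size(); ++q) L[q] *= sc;
      if (!chol_lower(L, d))
        stop("fixed proposal covariance is not positive definite");
    }
    std::vector<double> z(d), prop(d);
    for (int p = 0; p < d; ++p) z[p] = norm_rand();
    for (int p = 0; p < d; ++p) {
      double s = 0.0;
      for (int q = 0; q <= p; ++q) s += L[p + d * q] * z[q];
      prop[p] = beta[p] + s;
    }
    compute_W(X, offs, prop.data(), dm, Wprop.data());
    const double ll1 = loglik_core(y, Wprop.data(), lam.data(), dm.C);
    const double lp1 = ll1 + beta_logprior(prop);
    const double u_acc = unif_rand();
    double ll_now = ll0;
    accepted = 0;
    if (R_finite(lp1) && std::log(u_acc) < lp1 - lp0) {
      beta = prop;
      W.swap(Wprop);
      ll_now = ll1;
      accepted = 1;
    }
    return ll_now + ll_const;
  }

  void adapt_update() {
    const int d = dm.P;
    ++an;
    std::vector<double> delta(d);
    for (int p = 0; p < d; ++p) {
      delta[p] = beta[p] - amean[p];
      amean[p] += delta[p] / (double)an;
    }
    for (int q = 0; q < d; ++q)
      for (int p = 0; p < d; ++p)
        aM2[p + d * q] += delta[p] * (beta[q] - amean[q]);
  }

  std::vector<double> sigma_fixed;
};

static Engine make_engine(const IntegerVector& counts,
                          const NumericVector& offsets,
                          const NumericMatrix& X, int N, int T, int K,
                          int H1, int H2, bool cp,
                          const NumericMatrix& l1, const NumericVector& l2,
                          const NumericMatrix& l3, const NumericVector& beta,
                          const NumericMatrix& sigma_fixed,
                          const NumericVector& prior, double p_fixed,
                          int n0, const NumericVector& amean,
                          const NumericMatrix& aM2, long an) {
  Engine e;
  e.init(counts, offsets, X, N, T, K, H1, H2, cp);
  e.l1.assign(l1.begin(), l1.end());
  e.l2.assign(l2.begin(), l2.end());
  e.l3.assign(l3.begin(), l3.end());
  e.beta.assign(beta.begin(), beta.end());
  e.sigma_fixed.assign(sigma_fixed.begin(), sigma_fixed.end());
  e.aa = prior[0]; e.ab = prior[1]; e.ga = prior[2]; e.gb = prior[3];
  e.ea = prior[4]; e.eb = prior[5]; e.sigma2 = prior[6];
  e.p_fixed = p_fixed; e.n0 = n0;
  e.amean.assign(amean.begin(), amean.end());
  e.aM2.assign(aM2.begin(), aM2.end());
  e.an = an;
  compute_W(e.X, e.offs, e.beta.data(), e.dm, e.W.data());
  return e;
}

// [[Rcpp::export(name = ".cpp_run_chain")]]
List cpp_run_chain(IntegerVector counts, NumericVector offsets,
                   NumericMatrix X, int N, int T, int K, int H1, int H2,
                   bool cp, NumericMatrix l1, NumericVector l2,
                   NumericMatrix l3, NumericVector beta,
                   NumericMatrix sigma_fixed, NumericVector prior,
                   double p_fixed, int n0, int n_iter, int burn_in, int thin,
                   int core_mult) {
  Engine e = make_engine(counts, offsets, X, N, T, K, H1, H2, cp, l1, l2, l3,
                         beta, sigma_fixed, prior, p_fixed, n0,
                         NumericVector(X.ncol()),
                         NumericMatrix(X.ncol(), X.ncol()), 0);
  const int P = e.dm.P;
  const int S = (n_iter - burn_in) / thin;
  const int core_stride = thin * core_mult;
  const int Sc = (n_iter - burn_in + core_stride - 1) / core_stride;
  NumericMatrix beta_draws(S, P);
  NumericVector ll_trace(S);
  NumericMatrix l1_draws(Sc, e.l1.size());
  NumericMatrix l2_draws(Sc, e.l2.size());
  NumericMatrix l3_draws(Sc, e.l3.size());
  IntegerVector core_beta_row(Sc);
  std::vector<double> l1_sum(e.l1.size(), 0.0), l2_sum(e.l2.size(), 0.0),
      l3_sum(e.l3.size(), 0.0), beta_sum(P, 0.0);
  long n_keep = 0, n_acc = 0;
  int s = 0, sc = 0;

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    e.thin();
    e.update_cores();
    int acc = 0;
    const double ll = e.mh_beta(acc);
    e.adapt_update();
    n_acc += acc;
    if (it >= burn_in) {
      const int j = it - burn_in;
      ++n_keep;
      for (size_t q = 0; q < e.l1.size(); ++q) l1_sum[q] += e.l1[q];
      for (size_t q = 0; q < e.l2.size(); ++q) l2_sum[q] += e.l2[q];
      for (size_t q = 0; q < e.l3.size(); ++q) l3_sum[q] += e.l3[q];
      for (int p = 0; p < P; ++p) beta_sum[p] += e.beta[p];
      if (j % thin == 0 && s < S) {
        for (int p = 0; p < P; ++p) beta_draws(s, p) = e.beta[p];
        ll_trace[s] = ll;
        if (j % core_stride == 0 && sc < Sc) {
          for (size_t q = 0; q < e.l1.size(); ++q) l1_draws(sc, q) = e.l1[q];
          for (size_t q = 0; q < e.l2.size(); ++q) l2_draws(sc, q) = e.l2[q];
          for (size_t q = 0; q < e.l3.size(); ++q) l3_draws(sc, q) = e.l3[q];
          core_beta_row[sc] = s + 1;  // 1-based row in beta_draws
          ++sc;
        }
        ++s;
      }
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  for (int p = 0; p < P; ++p) beta_sum[p] /= (double)n_keep;
  for (size_t q = 0; q < e.l1.size(); ++q) l1_sum[q] /= (double)n_keep;
  for (size_t q = 0; q < e.l2.size(); ++q) l2_sum[q] /= (double)n_keep;
  for (size_t q = 0; q < e.l3.size(); ++q) l3_sum[q] /= (double)n_keep;

  return List::create(
      _["beta_draws"] = beta_draws, _["loglik_trace"] = ll_trace,
      _["accept_rate"] = (double)n_acc / (double)n_iter,
      _["l1_draws"] = l1_draws, _["l2_draws"] = l2_draws,
      _["l3_draws"] = l3_draws, _["core_beta_row"] = core_beta_row,
      _["beta_postmean"] = NumericVector(beta_sum.begin(), beta_sum.end()),
      _["l1_postmean"] = NumericVector(l1_sum.begin(), l1_sum.end()),
      _["l2_postmean"] = NumericVector(l2_sum.begin(), l2_sum.end()),
      _["l3_postmean"] = NumericVector(l3_sum.begin(), l3_sum.end()),
      _["final_l1"] = NumericVector(e.l1.begin(), e.l1.end()),
      _["final_l2"] = NumericVector(e.l2.begin(), e.l2.end()),
      _["final_l3"] = NumericVector(e.l3.begin(), e.l3.end()),
      _["final_beta"] = NumericVector(e.beta.begin(), e.beta.end()),
      _["adapt_mean"] = NumericVector(e.amean.begin(), e.amean.end()),
      _["adapt_M2"] = NumericVector(e.aM2.begin(), e.aM2.end()),
      _["adapt_n"] = (double)e.an);
}

// One transition-kernel sweep; used by the prior-preservation (joint
// distribution) test and kernel-level unit tests.
// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(IntegerVector counts, NumericVector offsets, NumericMatrix X,
               int N, int T, int K, int H1, int H2, bool cp,
               NumericMatrix l1, NumericVector l2, NumericMatrix l3,
               NumericVector beta, NumericMatrix sigma_fixed,
               NumericVector prior, double p_fixed, int n0,
               NumericVector amean, NumericMatrix aM2, double an) {
  Engine e = make_engine(counts, offsets, X, N, T, K, H1, H2, cp, l1, l2, l3,
                         beta, sigma_fixed, prior, p_fixed, n0, amean, aM2,
                         (long)an);
  GetRNGstate();
  e.thin();
  e.update_cores();
  int acc = 0;
  const double ll = e.mh_beta(acc);
  e.adapt_update();
  PutRNGstate();
  return List::create(
      _["l1"] = NumericVector(e.l1.begin(), e.l1.end()),
      _["l2"] = NumericVector(e.l2.begin(), e.l2.end()),
      _["l3"] = NumericVector(e.l3.begin(), e.l3.end()),
      _["beta"] = NumericVector(e.beta.begin(), e.beta.end()),
      _["accepted"] = acc, _["loglik"] = ll,
      _["m1"] = IntegerVector(e.m1.begin(), e.m1.end()),
      _["m2"] = IntegerVector(e.m2.begin(), e.m2.end()),
      _["m3"] = IntegerVector(e.m3.begin(), e.m3.end()),
      _["adapt_mean"] = NumericVector(e.amean.begin(), e.amean.end()),
      _["adapt_M2"] = NumericVector(e.aM2.begin(), e.aM2.end()),
      _["adapt_n"] = (double)e.an);
}

// Deterministic full-conditional rate terms at a given state (prior rate
// excluded); lets tests pin the compiled contractions against the plain-R
// reference implementations.
// [[Rcpp::export(name = ".cpp_fc_rates")]]
List cpp_fc_rates(NumericVector offsets, NumericMatrix X, int N, int T,
                  int K, int H1, int H2, NumericMatrix l1, NumericVector l2,
                  NumericMatrix l3, NumericVector beta) {
  Engine e;
  IntegerVector dummy(N * T * K);
  e.init(dummy, offsets, X, N, T, K, H1, H2, false);
  e.l1.assign(l1.begin(), l1.end());
  e.l2.assign(l2.begin(), l2.end());
  e.l3.assign(l3.begin(), l3.end());
  e.beta.assign(beta.begin(), beta.end());
  compute_W(e.X, e.offs, e.beta.data(), e.dm, e.W.data());

  const Dims& dm = e.dm;
  compute_A(e.l2.data(), e.l3.data(), dm, e.A.data());
  NumericMatrix rate1(N, H1);
  for (int h1 = 0; h1 < H1; ++h1) {
    const double* Ah = e.A.data() + (size_t)dm.TK * h1;
    for (int tk = 0; tk < dm.TK; ++tk) {
      const double a = Ah[tk];
      const double* Wc = e.W.data() + (size_t)N * tk;
      for (int i = 0; i < N; ++i) rate1(i, h1) += Wc[i] * a;
    }
  }
  compute_V(e.l1.data(), e.W.data(), dm, e.V.data());
  NumericVector rate2((size_t)T * H1 * H2);
  for (int h2 = 0; h2 < H2; ++h2)
    for (int h1 = 0; h1 < H1; ++h1)
      for (int t = 0; t < T; ++t) {
        double s = 0.0;
        for (int k = 0; k < K; ++k)
          s += e.V[h1 + H1 * (t + T * k)] * l3(k, h2);
        rate2[t + T * (h1 + H1 * h2)] = s;
      }
  NumericMatrix rate3(K, H2);
  for (int h2 = 0; h2 < H2; ++h2)
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int t = 0; t < T; ++t)
        for (int h1 = 0; h1 < H1; ++h1)
          s += e.V[h1 + H1 * (t + T * k)] * e.l2[t + T * (h1 + H1 * h2)];
      rate3(k, h2) = s;
    }
  rate2.attr("dim") = IntegerVector::create(T, H1, H2);
  return List::create(_["rate1"] = rate1, _["rate2"] = rate2,
                      _["rate3"] = rate3);
}
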