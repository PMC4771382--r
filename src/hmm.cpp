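#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Univariate Gaussian hidden Markov model over genome-ordered z-scores.
// Chromosomes are independent chains sharing one parameter set: the E-step
// runs forward-backward per chromosome and sufficient statistics accumulate
// across chromosomes. State identifiability is enforced by sorting states on
// their emission mean after every M-step.

namespace {

const int S = 3;

inline double dnorm_(double x, double mu, double sd) {
  double zr = (x - mu) / sd;
  return std::exp(-0.5 * zr * zr) / (sd * 2.5066282746310002);
}

struct SuffStats {
  double gamma_sum[S];
  double gamma_x[S];
  double gamma_xx[S];
  double xi[S][S];
  double init[S];
  double loglik;
  void reset() {
    loglik = 0.0;
    for (int i = 0; i < S; ++i) {
      gamma_sum[i] = gamma_x[i] = gamma_xx[i] = init[i] = 0.0;
      for (int j = 0; j < S; ++j) xi[i][j] = 0.0;
    }
  }
};

// scaled forward-backward on one sequence; accumulates into st, optionally
// writes posteriors into gamma_out (T x S, row offset 'off')
double forward_backward(const double* z, int T,
                        const double* mu, const double* sd,
                        const double (*A)[S], const double* pi,
                        SuffStats* st, NumericMatrix* gamma_out, int off) {
  std::vector<double> alpha(T * S), beta(T * S), c(T), em(T * S);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < S; ++i) {
      double e = dnorm_(z[t], mu[i], sd[i]);
      em[t * S + i] = e > 1e-300 ? e : 1e-300;
    }
  // forward
  double s0 = 0.0;
  for (int i = 0; i < S; ++i) { alpha[i] = pi[i] * em[i]; s0 += alpha[i]; }
  c[0] = s0;
  for (int i = 0; i < S; ++i) alpha[i] /= s0;
  for (int t = 1; t < T; ++t) {
    double sc = 0.0;
    for (int j = 0; j < S; ++j) {
      double a = 0.0;
      for (int i = 0; i < S; ++i) a += alpha[(t - 1) * S + i] * A[i][j];
      a *= em[t * S + j];
      alpha[t * S + j] = a;
      sc += a;
    }
    c[t] = sc;
    for (int j = 0; j < S; ++j) alpha[t * S + j] /= sc;
  }
  // backward
  for (int i = 0; i < S; ++i) beta[(T - 1) * S + i] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double b = 0.0;
      for (int j = 0; j < S; ++j)
        b += A[i][j] * em[(t + 1) * S + j] * beta[(t + 1) * S + j];
      beta[t * S + i] = b / c[t + 1];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  for (int t = 0; t < T; ++t) {
    double g[S], gs = 0.0;
    for (int i = 0; i < S; ++i) { g[i] = alpha[t * S + i] * beta[t * S + i]; gs += g[i]; }
    for (int i = 0; i < S; ++i) g[i] /= gs;
    if (gamma_out)
      for (int i = 0; i < S; ++i) (*gamma_out)(off + t, i) = g[i];
    if (st) {
      for (int i = 0; i < S; ++i) {
        st->gamma_sum[i] += g[i];
        st->gamma_x[i] += g[i] * z[t];
        st->gamma_xx[i] += g[i] * z[t] * z[t];
      }
      if (t == 0)
        for (int i = 0; i < S; ++i) st->init[i] += g[i];
      if (t < T - 1) {
        double xs = 0.0, x[S][S];
        for (int i = 0; i < S; ++i)
          for (int j = 0; j < S; ++j) {
            x[i][j] = alpha[t * S + i] * A[i][j] * em[(t + 1) * S + j] *
                      beta[(t + 1) * S + j];
            xs += x[i][j];
          }
        for (int i = 0; i < S; ++i)
          for (int j = 0; j < S; ++j) st->xi[i][j] += x[i][j] / xs;
      }
    }
  }
  return ll;
}

void order_states(double* mu, double* sd, double (*A)[S], double* pi) {
  int ord[S] = {0, 1, 2};
  std::sort(ord, ord + S, [&](int a, int b) { return mu[a] < mu[b]; });
  double mu2[S], sd2[S], pi2[S], A2[S][S];
  for (int i = 0; i < S; ++i) {
    mu2[i] = mu[ord[i]]; sd2[i] = sd[ord[i]]; pi2[i] = pi[ord[i]];
    for (int j = 0; j < S; ++j) A2[i][j] = A[ord[i]][ord[j]];
  }
  for (int i = 0; i < S; ++i) {
    mu[i] = mu2[i]; sd[i] = sd2[i]; pi[i] = pi2[i];
    for (int j = 0; j < S; ++j) A[i][j] = A2[i][j];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_hmm_em(NumericVector z, IntegerVector seq_len,
                NumericVector mu0, NumericVector sd0,
                NumericMatrix trans0, NumericVector init0,
                int max_iter, double tol, double sd_floor) {
  const int T = z.size();
  const int nseq = seq_len.size();
  double mu[S], sd[S], pi[S], A[S][S];
  for (int i = 0; i < S; ++i) {
    mu[i] = mu0[i]; sd[i] = sd0[i]; pi[i] = init0[i];
    for (int j = 0; j < S; ++j) A[i][j] = trans0(i, j);
  }
  order_states(mu, sd, A, pi);

  SuffStats st;
  double prev_ll = R_NegInf, ll = R_NegInf;
  int iter = 0;
  bool sd_floored = false;
  for (iter = 0; iter < max_iter; ++iter) {
    st.reset();
    ll = 0.0;
    int off = 0;
    for (int sq = 0; sq < nseq; ++sq) {
      ll += forward_backward(&z[off], seq_len[sq], mu, sd, A, pi, &st, nullptr, 0);
      off += seq_len[sq];
    }
    // M-step
    for (int i = 0; i < S; ++i) {
      double gs = st.gamma_sum[i];
      if (gs > 1e-12) {
        mu[i] = st.gamma_x[i] / gs;
        double var = st.gamma_xx[i] / gs - mu[i] * mu[i];
        sd[i] = std::sqrt(var > 0 ? var : 0.0);
      }
      if (sd[i] < sd_floor) { sd[i] = sd_floor; sd_floored = true; }
      double rs = 0.0;
      for (int j = 0; j < S; ++j) rs += st.xi[i][j];
      if (rs > 1e-12)
        for (int j = 0; j < S; ++j) A[i][j] = st.xi[i][j] / rs;
    }
    // initial distribution tied to the stationary distribution of the
    // transition matrix: with chromosomes as separate chains there are only
    // ~20 first positions, far too few to estimate a free initial law (a
    // free estimate can drift to putting all initial mass on an extreme
    // state, turning every chromosome's first SNP into a confident call)
    {
      double p0[S] = {1.0 / S, 1.0 / S, 1.0 / S}, p1[S];
      for (int it2 = 0; it2 < 200; ++it2) {
        for (int j = 0; j < S; ++j) {
          p1[j] = 0.0;
          for (int i2 = 0; i2 < S; ++i2) p1[j] += p0[i2] * A[i2][j];
        }
        double diff = 0.0;
        for (int j = 0; j < S; ++j) { diff += std::abs(p1[j] - p0[j]); p0[j] = p1[j]; }
        if (diff < 1e-12) break;
      }
      for (int j = 0; j < S; ++j) pi[j] = p0[j];
    }
    order_states(mu, sd, A, pi);
    if (iter > 0 && std::abs(ll - prev_ll) < tol) { ++iter; break; }
    prev_ll = ll;
  }

  NumericVector muo(S), sdo(S), pio(S);
  NumericMatrix Ao(S, S);
  for (int i = 0; i < S; ++i) {
    muo[i] = mu[i]; sdo[i] = sd[i]; pio[i] = pi[i];
    for (int j = 0; j < S; ++j) Ao(i, j) = A[i][j];
  }
  return List::create(_["mean"] = muo, _["sd"] = sdo, _["trans"] = Ao,
                      _["init"] = pio, _["loglik"] = ll, _["n_iter"] = iter,
                      _["sd_floored"] = sd_floored);
}

// [[Rcpp::export]]
List cpp_hmm_posterior(NumericVector z, IntegerVector seq_len,
                       NumericVector mu0, NumericVector sd0,
                       NumericMatrix trans0, NumericVector init0) {
  const int T = z.size();
  double mu[S], sd[S], pi[S], A[S][S];
  for (int i = 0; i < S; ++i) {
    mu[i] = mu0[i]; sd[i] = sd0[i]; pi[i] = init0[i];
    for (int j = 0; j < S; ++j) A[i][j] = trans0(i, j);
  }
  NumericMatrix gamma(T, S);
  double ll = 0.0;
  int off = 0;
  for (int sq = 0; sq < seq_len.size(); ++sq) {
    ll += forward_backward(&z[off], seq_len[sq], mu, sd, A, pi, nullptr, &gamma, off);
    off += seq_len[sq];
  }
  return List::create(_["posterior"] = gamma, _["loglik"] = ll);
}

// [[Rcpp::export]]
IntegerVector cpp_hmm_viterbi(NumericVector z, IntegerVector seq_len,
                              NumericVector mu0, NumericVector sd0,
                              NumericMatrix trans0, NumericVector init0) {
  const int T = z.size();
  IntegerVector path(T);
  double lA[S][S], lpi[S];
  for (int i = 0; i < S; ++i) {
    lpi[i] = std::log(init0[i] > 1e-300 ? init0[i] : 1e-300);
    for (int j = 0; j < S; ++j)
      lA[i][j] = std::log(trans0(i, j) > 1e-300 ? trans0(i, j) : 1e-300);
  }
  int off = 0;
  for (int sq = 0; sq < seq_len.size(); ++sq) {
    int Ts = seq_len[sq];
    std::vector<double> delta(Ts * S);
    std::vector<int> psi(Ts * S);
    for (int i = 0; i < S; ++i)
      delta[i] = lpi[i] + std::log(std::max(dnorm_(z[off], mu0[i], sd0[i]), 1e-300));
    for (int t = 1; t < Ts; ++t)
      for (int j = 0; j < S; ++j) {
        double best = R_NegInf; int arg = 0;
        for (int i = 0; i < S; ++i) {
          double v = delta[(t - 1) * S + i] + lA[i][j];
          if (v > best) { best = v; arg = i; }
        }
        delta[t * S + j] = best +
          std::log(std::max(dnorm_(z[off + t], mu0[j], sd0[j]), 1e-300));
        psi[t * S + j] = arg;
      }
    int arg = 0; double best = R_NegInf;
    for (int i = 0; i < S; ++i)
      if (delta[(Ts - 1) * S + i] > best) { best = delta[(Ts - 1) * S + i]; arg = i; }
    path[off + Ts - 1] = arg + 1;
    for (int t = Ts - 2; t >= 0; --t) {
      arg = psi[(t + 1) * S + arg];
      path[off + t] = arg + 1;
    }
    off += Ts;
  }
  return path;
}
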