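// Log-domain HMM inner loops: diagonal-covariance Gaussian-mixture emission
// densities, forward likelihood, forward-backward E-step accumulation, and
// Viterbi best-path search over a composite (sentence or network) HMM.
//
// Conventions shared with the R side:
//   * S composite emitting states; logpi (entry), logA (S x S), logeta (exit)
//     hold log probabilities with -Inf on disallowed arcs. Composite
//     transition matrices are sparse (left-to-right structures dominate), so
//     logA is scanned once into an arc list and all per-frame recursions
//     iterate arcs, not state pairs.
//   * Emission parameters are tied: state2tied maps composite state -> tied
//     state (0-based); per tied state, logw / mu / var give the mixture.
//   * Feature matrices are T x d (one frame per row).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double LOG_2PI = 1.8378770664093454836;

struct Arc { int from, to; double logp; };

static std::vector<Arc> scan_arcs(const NumericMatrix& logA) {
  std::vector<Arc> arcs;
  int S = logA.nrow();
  arcs.reserve(4 * S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < S; ++i)
      if (logA(i, j) != NEG_INF) arcs.push_back({i, j, logA(i, j)});
  return arcs;
}

// log N(x | mu, diag(var)) for one frame
static inline double diag_gauss_logpdf(const double* x, const double* mu,
                                       const double* var, int d) {
  double acc = 0.0;
  for (int k = 0; k < d; ++k) {
    double z = x[k] - mu[k];
    acc += std::log(var[k]) + z * z / var[k];
  }
  return -0.5 * (d * LOG_2PI + acc);
}

static inline double log_add(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  double diff = b - a;
  if (diff < -36.0) return a;  // below double precision of the sum
  return a + std::log1p(std::exp(diff));
}

// Per-mixture log densities for all tied states and frames.
// Fills comp[s] (M x T flattened, column t fastest) and logB (n_tied x T).
// Per-component log-normalizers and inverse variances are hoisted out of the
// frame loop, so the inner loop is pure multiply-add.
static void mixture_logdens(const NumericMatrix& X, const List& logw,
                            const List& mu, const List& var,
                            std::vector< std::vector<double> >& comp,
                            NumericMatrix& logB) {
  int T = X.nrow(), d = X.ncol(), n_tied = logw.size();
  std::vector<double> frame(d);
  for (int s = 0; s < n_tied; ++s) {
    NumericVector lw = logw[s];
    NumericMatrix m = mu[s], v = var[s];
    int M = lw.size();
    comp[s].assign((size_t)M * T, NEG_INF);
    std::vector<double> mus((size_t)M * d), ivars((size_t)M * d), cst(M);
    for (int j = 0; j < M; ++j) {
      double logdet = 0.0;
      for (int k = 0; k < d; ++k) {
        mus[(size_t)j * d + k] = m(j, k);
        ivars[(size_t)j * d + k] = 1.0 / v(j, k);
        logdet += std::log(v(j, k));
      }
      cst[j] = (lw[j] == NEG_INF)
                   ? NEG_INF
                   : lw[j] - 0.5 * (d * LOG_2PI + logdet);
    }
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < d; ++k) frame[k] = X(t, k);
      double tot = NEG_INF;
      for (int j = 0; j < M; ++j) {
        double lp = NEG_INF;
        if (cst[j] != NEG_INF) {
          double quad = 0.0;
          const double* mj = &mus[(size_t)j * d];
          const double* vj = &ivars[(size_t)j * d];
          for (int k = 0; k < d; ++k) {
            double z = frame[k] - mj[k];
            quad += z * z * vj[k];
          }
          lp = cst[j] - 0.5 * quad;
        }
        comp[s][(size_t)j * T + t] = lp;
        tot = log_add(tot, lp);
      }
      logB(s, t) = tot;
    }
  }
}

// [[Rcpp::export(name = ".cpp_tied_logB")]]
NumericMatrix cpp_tied_logB(NumericMatrix X, List logw, List mu, List var) {
  int n_tied = logw.size(), T = X.nrow();
  NumericMatrix logB(n_tied, T);
  std::vector< std::vector<double> > comp(n_tied);
  mixture_logdens(X, logw, mu, var, comp, logB);
  return logB;
}

// Forward log-likelihood. logB is S x T (already mapped to composite states).
// [[Rcpp::export(name = ".cpp_forward")]]
double cpp_forward(NumericVector logpi, NumericMatrix logA,
                   NumericVector logeta, NumericMatrix logB) {
  int S = logpi.size(), T = logB.ncol();
  std::vector<Arc> arcs = scan_arcs(logA);
  std::vector<double> alpha(S), nxt(S);
  for (int i = 0; i < S; ++i)
    alpha[i] = (logpi[i] == NEG_INF) ? NEG_INF : logpi[i] + logB(i, 0);
  for (int t = 1; t < T; ++t) {
    std::fill(nxt.begin(), nxt.end(), NEG_INF);
    for (const Arc& a : arcs) {
      if (alpha[a.from] == NEG_INF) continue;
      nxt[a.to] = log_add(nxt[a.to], alpha[a.from] + a.logp);
    }
    for (int j = 0; j < S; ++j)
      nxt[j] = (nxt[j] == NEG_INF) ? NEG_INF : nxt[j] + logB(j, t);
    alpha.swap(nxt);
  }
  double ll = NEG_INF;
  for (int i = 0; i < S; ++i)
    if (alpha[i] != NEG_INF && logeta[i] != NEG_INF)
      ll = log_add(ll, alpha[i] + logeta[i]);
  return ll;
}

// Viterbi best path; ties resolved toward the lowest state index.
// [[Rcpp::export(name = ".cpp_viterbi")]]
List cpp_viterbi(NumericVector logpi, NumericMatrix logA, NumericVector logeta,
                 NumericMatrix logB) {
  int S = logpi.size(), T = logB.ncol();
  std::vector<Arc> arcs = scan_arcs(logA);
  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);
  for (int i = 0; i < S; ++i)
    delta(i, 0) = (logpi[i] == NEG_INF) ? NEG_INF : logpi[i] + logB(i, 0);
  std::vector<double> best(S);
  std::vector<int> argb(S);
  for (int t = 1; t < T; ++t) {
    std::fill(best.begin(), best.end(), NEG_INF);
    std::fill(argb.begin(), argb.end(), -1);
    for (const Arc& a : arcs) {
      double prev = delta(a.from, t - 1);
      if (prev == NEG_INF) continue;
      double v = prev + a.logp;
      // strict > plus column-major arc order keeps the lowest source state
      if (v > best[a.to]) { best[a.to] = v; argb[a.to] = a.from; }
    }
    for (int j = 0; j < S; ++j) {
      delta(j, t) = (best[j] == NEG_INF) ? NEG_INF : best[j] + logB(j, t);
      psi(j, t) = argb[j];
    }
  }
  double fin = NEG_INF;
  int arg = -1;
  for (int i = 0; i < S; ++i) {
    if (delta(i, T - 1) == NEG_INF || logeta[i] == NEG_INF) continue;
    double v = delta(i, T - 1) + logeta[i];
    if (v > fin) { fin = v; arg = i; }
  }
  IntegerVector path(T);
  if (arg < 0)
    return List::create(_["path"] = IntegerVector(0), _["score"] = NEG_INF);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R
  return List::create(_["path"] = path, _["score"] = fin);
}

// Full E-step for one sentence, with classic per-frame scaling: the
// forward/backward recursions run in the linear domain on rescaled
// quantities (per-frame emission maxima factored out, alpha columns
// normalized to sum one), so the hot loops are pure multiply-add and the
// log-likelihood is recovered from the accumulated scale factors. Returns
// transition/entry/exit occupancies at the composite level and mixture
// occupancy statistics at the tied-state level.
// [[Rcpp::export(name = ".cpp_estep")]]
List cpp_estep(NumericVector logpi, NumericMatrix logA, NumericVector logeta,
               IntegerVector state2tied, List logw, List mu, List var,
               NumericMatrix X) {
  int S = logpi.size(), T = X.nrow(), d = X.ncol(), n_tied = logw.size();
  NumericMatrix logB_t(n_tied, T);
  std::vector< std::vector<double> > comp(n_tied);
  mixture_logdens(X, logw, mu, var, comp, logB_t);
  std::vector<Arc> arcs = scan_arcs(logA);
  std::vector<double> parc(arcs.size());
  for (size_t r = 0; r < arcs.size(); ++r) parc[r] = std::exp(arcs[r].logp);

  // rescaled emission matrix b(i,t) = exp(logB - bmax_t), composite states
  std::vector<double> b((size_t)S * T), bmax(T);
  for (int t = 0; t < T; ++t) {
    double mx = NEG_INF;
    for (int s = 0; s < n_tied; ++s)
      if (logB_t(s, t) > mx) mx = logB_t(s, t);
    bmax[t] = mx;
    if (mx == NEG_INF) return List::create(_["loglik"] = NEG_INF);
    for (int i = 0; i < S; ++i) {
      double lb = logB_t(state2tied[i], t);
      b[(size_t)t * S + i] = (lb == NEG_INF) ? 0.0 : std::exp(lb - mx);
    }
  }

  std::vector<double> alpha((size_t)S * T), beta((size_t)S * T), C(T);
  // forward
  {
    double* a0 = &alpha[0];
    double c = 0.0;
    for (int i = 0; i < S; ++i) {
      double v = (logpi[i] == NEG_INF) ? 0.0
                                       : std::exp(logpi[i]) * b[i];
      a0[i] = v;
      c += v;
    }
    if (c <= 0.0) return List::create(_["loglik"] = NEG_INF);
    for (int i = 0; i < S; ++i) a0[i] /= c;
    C[0] = c;
  }
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[(size_t)(t - 1) * S];
    double* an = &alpha[(size_t)t * S];
    std::fill(an, an + S, 0.0);
    for (size_t r = 0; r < arcs.size(); ++r)
      an[arcs[r].to] += ap[arcs[r].from] * parc[r];
    const double* bt = &b[(size_t)t * S];
    double c = 0.0;
    for (int i = 0; i < S; ++i) {
      an[i] *= bt[i];
      c += an[i];
    }
    if (c <= 0.0) return List::create(_["loglik"] = NEG_INF);
    for (int i = 0; i < S; ++i) an[i] /= c;
    C[t] = c;
  }
  double cfin = 0.0;
  {
    const double* aT = &alpha[(size_t)(T - 1) * S];
    for (int i = 0; i < S; ++i)
      if (logeta[i] != NEG_INF) cfin += aT[i] * std::exp(logeta[i]);
  }
  if (cfin <= 0.0) return List::create(_["loglik"] = NEG_INF);
  double ll = std::log(cfin);
  for (int t = 0; t < T; ++t) ll += std::log(C[t]) + bmax[t];

  // backward (scaled so gamma = alpha * beta elementwise)
  {
    double* bT = &beta[(size_t)(T - 1) * S];
    for (int i = 0; i < S; ++i)
      bT[i] = (logeta[i] == NEG_INF) ? 0.0 : std::exp(logeta[i]) / cfin;
  }
  for (int t = T - 2; t >= 0; --t) {
    const double* bn = &beta[(size_t)(t + 1) * S];
    double* bc = &beta[(size_t)t * S];
    const double* bt1 = &b[(size_t)(t + 1) * S];
    std::fill(bc, bc + S, 0.0);
    for (size_t r = 0; r < arcs.size(); ++r)
      bc[arcs[r].from] += parc[r] * bt1[arcs[r].to] * bn[arcs[r].to];
    double inv = 1.0 / C[t + 1];
    for (int i = 0; i < S; ++i) bc[i] *= inv;
  }

  NumericVector ent(S), ext(S);
  NumericMatrix trans(S, S);
  for (int i = 0; i < S; ++i) {
    ent[i] = alpha[i] * beta[i];  // t = 0 occupancy restricted to entries
    if (logpi[i] == NEG_INF) ent[i] = 0.0;
    if (logeta[i] != NEG_INF)
      ext[i] = alpha[(size_t)(T - 1) * S + i] * std::exp(logeta[i]) / cfin;
  }
  for (size_t r = 0; r < arcs.size(); ++r) {
    double acc = 0.0;
    int fi = arcs[r].from, ti = arcs[r].to;
    double p = parc[r];
    for (int t = 0; t < T - 1; ++t) {
      acc += alpha[(size_t)t * S + fi] * p * b[(size_t)(t + 1) * S + ti] *
             beta[(size_t)(t + 1) * S + ti] / C[t + 1];
    }
    trans(fi, ti) = acc;
  }

  // tied-level mixture statistics
  List occ(n_tied), sumx(n_tied), sumx2(n_tied);
  std::vector<NumericVector> occv(n_tied);
  std::vector<NumericMatrix> sx(n_tied), sx2(n_tied);
  std::vector<int> Ms(n_tied);
  for (int s = 0; s < n_tied; ++s) {
    Ms[s] = as<NumericVector>(logw[s]).size();
    occv[s] = NumericVector(Ms[s]);
    sx[s] = NumericMatrix(Ms[s], d);
    sx2[s] = NumericMatrix(Ms[s], d);
  }
  std::vector<double> frame(d), frame2(d);
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < d; ++k) {
      frame[k] = X(t, k);
      frame2[k] = frame[k] * frame[k];
    }
    const double* at = &alpha[(size_t)t * S];
    const double* bt = &beta[(size_t)t * S];
    for (int i = 0; i < S; ++i) {
      double g = at[i] * bt[i];
      if (g <= 1e-14) continue;
      int s = state2tied[i];
      double denom = logB_t(s, t);
      if (denom == NEG_INF) continue;
      double* ov = REAL(occv[s]);
      double* sxp = REAL(sx[s]);
      double* sx2p = REAL(sx2[s]);
      int M = Ms[s];
      for (int j = 0; j < M; ++j) {
        double lp = comp[s][(size_t)j * T + t] - denom;
        if (lp < -32.0) continue;
        double gm = g * std::exp(lp);
        ov[j] += gm;
        for (int k = 0; k < d; ++k) {
          sxp[j + M * k] += gm * frame[k];
          sx2p[j + M * k] += gm * frame2[k];
        }
      }
    }
  }
  for (int s = 0; s < n_tied; ++s) {
    occ[s] = occv[s];
    sumx[s] = sx[s];
    sumx2[s] = sx2[s];
  }
  return List::create(_["loglik"] = ll, _["ent"] = ent, _["trans"] = trans,
                      _["exit"] = ext, _["occ"] = occ, _["sumx"] = sumx,
                      _["sumx2"] = sumx2);
}
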