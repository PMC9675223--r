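// Hidden-Markov kernels for multipoint linkage analysis.
//
// Hidden chains run along ordered loci, one chain per individual:
//   kind "two"   : S = 2 states, transition parameter p (recombination
//                  fraction r for BC/DH, observed-line R for RIL/IRIL)
//   kind "kron4" : S = 4 states = ordered pair of two independent meioses
//                  (F2: maternal x paternal gamete; CP: transmitted homolog
//                  of each parent); transition = T2(r) (x) T2(r)
// Emission probabilities are precomputed in R and passed as an
// (S x n_ind x n_mark) array; a missing observation emits 1 in every state.
// All likelihoods here are natural logs; callers convert to log10/LOD.

#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

static const int MAXS = 4;

static int kind_S(const std::string &kind) {
  if (kind == "two") return 2;
  if (kind == "kron4") return 4;
  stop("unknown chain kind '%s'", kind.c_str());
  return 0;
}

static int kind_ncomp(const std::string &kind) { return kind == "kron4" ? 2 : 1; }

// number of meiosis components that switch between states s and t
static int n_changes(const std::string &kind, int s, int t) {
  if (kind == "two") return s != t;
  return ((s >> 1) != (t >> 1)) + ((s & 1) != (t & 1));
}

static void fill_trans(const std::string &kind, double p, double T[MAXS][MAXS]) {
  if (kind == "two") {
    T[0][0] = T[1][1] = 1.0 - p;
    T[0][1] = T[1][0] = p;
  } else {
    double t2[2][2] = {{1.0 - p, p}, {p, 1.0 - p}};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c)
          for (int d = 0; d < 2; ++d)
            T[a * 2 + c][b * 2 + d] = t2[a][b] * t2[c][d];
  }
}

// linear interpolation of p(d) from a monotone lookup table
static double interp_p(double d, const NumericVector &d_tab, const NumericVector &p_tab) {
  int n = d_tab.size();
  if (d <= d_tab[0]) return p_tab[0];
  if (d >= d_tab[n - 1]) return p_tab[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (d_tab[mid] <= d) lo = mid; else hi = mid;
  }
  double w = (d - d_tab[lo]) / (d_tab[hi] - d_tab[lo]);
  return p_tab[lo] * (1.0 - w) + p_tab[hi] * w;
}

struct Chain {
  int S, n, m;
  const double *E;  // (S, n, m)
  double em(int s, int i, int k) const { return E[s + S * (i + (size_t)n * k)]; }
};

static Chain make_chain(const NumericVector &emiss) {
  IntegerVector dm = emiss.attr("dim");
  if (dm.size() != 3) stop("emission array must be S x n x m");
  Chain c;
  c.S = dm[0]; c.n = dm[1]; c.m = dm[2];
  c.E = REAL(emiss);
  return c;
}

// forward pass with per-locus scaling; fills ahat (S,n,m) and la (n,m)
static void forward_pass(const Chain &c, const std::string &kind,
                         const NumericVector &p, double *ahat, double *la) {
  int S = c.S, n = c.n, m = c.m;
  double T[MAXS][MAXS];
  std::vector<double> cur(S), nxt(S);
  for (int i = 0; i < n; ++i) {
    double lsum = 0.0;
    for (int s = 0; s < S; ++s) cur[s] = (1.0 / S) * c.em(s, i, 0);
    double tot = 0; for (int s = 0; s < S; ++s) tot += cur[s];
    if (tot <= 0) stop("zero forward likelihood (individual %d, locus 1)", i + 1);
    for (int s = 0; s < S; ++s) { cur[s] /= tot; ahat[s + S * (i + (size_t)n * 0)] = cur[s]; }
    lsum += std::log(tot);
    la[i + (size_t)n * 0] = lsum;
    for (int k = 1; k < m; ++k) {
      fill_trans(kind, p[k - 1], T);
      for (int t = 0; t < S; ++t) {
        double v = 0;
        for (int s = 0; s < S; ++s) v += cur[s] * T[s][t];
        nxt[t] = v * c.em(t, i, k);
      }
      tot = 0; for (int s = 0; s < S; ++s) tot += nxt[s];
      if (tot <= 0) stop("zero forward likelihood (individual %d, locus %d)", i + 1, k + 1);
      for (int s = 0; s < S; ++s) { cur[s] = nxt[s] / tot; ahat[s + S * (i + (size_t)n * k)] = cur[s]; }
      lsum += std::log(tot);
      la[i + (size_t)n * k] = lsum;
    }
  }
}

// backward pass: b(j,s) = P(obs_{j+1..m} | S_j = s), scaled; fills bhat, lb
static void backward_pass(const Chain &c, const std::string &kind,
                          const NumericVector &p, double *bhat, double *lb) {
  int S = c.S, n = c.n, m = c.m;
  double T[MAXS][MAXS];
  std::vector<double> cur(S), prv(S);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < S; ++s) { cur[s] = 1.0 / S; bhat[s + S * (i + (size_t)n * (m - 1))] = cur[s]; }
    double lsum = std::log((double)S);  // so that bhat * exp(lb) = 1
    lb[i + (size_t)n * (m - 1)] = lsum;
    for (int j = m - 2; j >= 0; --j) {
      fill_trans(kind, p[j], T);
      for (int s = 0; s < S; ++s) {
        double v = 0;
        for (int t = 0; t < S; ++t) v += T[s][t] * c.em(t, i, j + 1) * cur[t];
        prv[s] = v;
      }
      double tot = 0; for (int s = 0; s < S; ++s) tot += prv[s];
      if (tot <= 0) stop("zero backward likelihood");
      for (int s = 0; s < S; ++s) { cur[s] = prv[s] / tot; bhat[s + S * (i + (size_t)n * j)] = cur[s]; }
      lsum += std::log(tot);
      lb[i + (size_t)n * j] = lsum;
    }
  }
}

// [[Rcpp::export]]
List cpp_loglik(NumericVector emiss, NumericVector p, std::string kind) {
  Chain c = make_chain(emiss);
  if ((int)p.size() != c.m - 1) stop("need m-1 interval parameters");
  std::vector<double> ahat((size_t)c.S * c.n * c.m), la((size_t)c.n * c.m);
  forward_pass(c, kind, p, ahat.data(), la.data());
  NumericVector per(c.n);
  double tot = 0;
  for (int i = 0; i < c.n; ++i) { per[i] = la[i + (size_t)c.n * (c.m - 1)]; tot += per[i]; }
  return List::create(_["loglik"] = tot, _["per_ind"] = per);
}

// [[Rcpp::export]]
List cpp_fb(NumericVector emiss, NumericVector p, std::string kind) {
  Chain c = make_chain(emiss);
  int S = c.S, n = c.n, m = c.m;
  if ((int)p.size() != m - 1) stop("need m-1 interval parameters");
  std::vector<double> ahat((size_t)S * n * m), la((size_t)n * m);
  std::vector<double> bhat((size_t)S * n * m), lb((size_t)n * m);
  forward_pass(c, kind, p, ahat.data(), la.data());
  backward_pass(c, kind, p, bhat.data(), lb.data());
  NumericVector gamma(Dimension(S, n, m));
  NumericVector rec(m - 1);
  double T[MAXS][MAXS];
  double ll = 0;
  for (int i = 0; i < n; ++i) ll += la[i + (size_t)n * (m - 1)];
  for (int k = 0; k < m; ++k) {
    for (int i = 0; i < n; ++i) {
      double u[MAXS], tot = 0;
      for (int s = 0; s < S; ++s) {
        u[s] = ahat[s + S * (i + (size_t)n * k)] * bhat[s + S * (i + (size_t)n * k)];
        tot += u[s];
      }
      for (int s = 0; s < S; ++s) gamma[s + S * (i + (size_t)n * k)] = u[s] / tot;
    }
  }
  for (int k = 0; k + 1 < m; ++k) {
    fill_trans(kind, p[k], T);
    double ex = 0;
    for (int i = 0; i < n; ++i) {
      double u[MAXS][MAXS], tot = 0;
      for (int s = 0; s < S; ++s)
        for (int t = 0; t < S; ++t) {
          u[s][t] = ahat[s + S * (i + (size_t)n * k)] * T[s][t] *
                    c.em(t, i, k + 1) * bhat[t + S * (i + (size_t)n * (k + 1))];
          tot += u[s][t];
        }
      for (int s = 0; s < S; ++s)
        for (int t = 0; t < S; ++t)
          ex += u[s][t] / tot * n_changes(kind, s, t);
    }
    rec[k] = ex;
  }
  return List::create(_["gamma"] = gamma, _["rec"] = rec, _["loglik"] = ll);
}

// Baum-Welch EM on interval parameters; log-likelihood is non-decreasing.
// [[Rcpp::export]]
List cpp_em(NumericVector emiss, NumericVector p0, std::string kind,
            int max_iter, double tol_log10, double pmin, double pmax) {
  Chain c = make_chain(emiss);
  int ncomp = kind_ncomp(kind);
  NumericVector p = clone(p0);
  std::vector<double> trace;
  double prev = R_NegInf;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    List fb = cpp_fb(emiss, p, kind);
    double ll = fb["loglik"];
    trace.push_back(ll / std::log(10.0));
    NumericVector rec = fb["rec"];
    for (int k = 0; k < (int)p.size(); ++k) {
      double ph = rec[k] / ((double)c.n * ncomp);
      p[k] = std::min(pmax, std::max(pmin, ph));
    }
    if (it > 0 && (ll - prev) / std::log(10.0) < tol_log10) { converged = true; break; }
    prev = ll;
  }
  List fin = cpp_loglik(emiss, p, kind);
  return List::create(_["p"] = p, _["loglik"] = (double)fin["loglik"],
                      _["trace"] = wrap(trace), _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Insertion scan: likelihood of placing one candidate marker into each slot
// (slot 0 = before the first locus, slot m = beyond the last, slot k = inside
// interval k).  Interior slots preserve the interval's total map distance and
// optimize the split; exterior slots optimize the attachment distance.
// ---------------------------------------------------------------------------

struct ScanCtx {
  Chain c;
  std::string kind;
  const double *ahat, *la, *bhat, *lb;
  const double *cand;   // (S, n, v)
  int nv;
  NumericVector d_tab, p_tab;
  std::vector<double> const_int;  // per slot k=1..m-1: sum_i la(k-1)+lb(k)
  std::vector<double> const_lo, const_hi;  // per-ind-summed la/lb constants
};

static double eval_slot(const ScanCtx &X, int slot, int v, double dl, double dr) {
  const Chain &c = X.c;
  int S = c.S, n = c.n, m = c.m;
  double Tl[MAXS][MAXS], Tr[MAXS][MAXS];
  const double *ec = X.cand + (size_t)S * n * v;
  double out = 0;
  if (slot == 0) {
    fill_trans(X.kind, interp_p(dr, X.d_tab, X.p_tab), Tr);
    for (int i = 0; i < n; ++i) {
      double s0 = 0;
      for (int u = 0; u < S; ++u) {
        double g = 0;
        for (int w = 0; w < S; ++w)
          g += Tr[u][w] * c.em(w, i, 0) * X.bhat[w + S * (i + (size_t)n * 0)];
        s0 += (1.0 / S) * ec[u + S * i] * g;
      }
      out += std::log(s0) + X.lb[i + (size_t)n * 0];
    }
  } else if (slot == m) {
    fill_trans(X.kind, interp_p(dl, X.d_tab, X.p_tab), Tl);
    for (int i = 0; i < n; ++i) {
      double s0 = 0;
      for (int s = 0; s < S; ++s) {
        double g = 0;
        for (int u = 0; u < S; ++u) g += Tl[s][u] * ec[u + S * i];
        s0 += X.ahat[s + S * (i + (size_t)n * (m - 1))] * g;
      }
      out += std::log(s0) + X.la[i + (size_t)n * (m - 1)];
    }
  } else {
    int kl = slot - 1, kr = slot;  // flanking marker indices
    fill_trans(X.kind, interp_p(dl, X.d_tab, X.p_tab), Tl);
    fill_trans(X.kind, interp_p(dr, X.d_tab, X.p_tab), Tr);
    for (int i = 0; i < n; ++i) {
      double g[MAXS];
      for (int u = 0; u < S; ++u) {
        double gv = 0;
        for (int w = 0; w < S; ++w)
          gv += Tr[u][w] * c.em(w, i, kr) * X.bhat[w + S * (i + (size_t)n * kr)];
        g[u] = gv * ec[u + S * i];
      }
      double s0 = 0;
      for (int s = 0; s < S; ++s) {
        double h = 0;
        for (int u = 0; u < S; ++u) h += Tl[s][u] * g[u];
        s0 += X.ahat[s + S * (i + (size_t)n * kl)] * h;
      }
      out += std::log(s0) + X.la[i + (size_t)n * kl] + X.lb[i + (size_t)n * kr];
    }
  }
  return out;
}

static double golden_max(std::function<double(double)> f, double a, double b,
                         int iters, double *xbest) {
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  for (int it = 0; it < iters; ++it) {
    if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = f(x2); }
    else { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = f(x1); }
  }
  if (f1 >= f2) { *xbest = x1; return f1; }
  *xbest = x2; return f2;
}

// [[Rcpp::export]]
List cpp_insert_scan(NumericVector emiss, NumericVector d, std::string kind,
                     NumericVector d_tab, NumericVector p_tab,
                     NumericVector cand, int refine_k, double d_ext_max) {
  Chain c = make_chain(emiss);
  int S = c.S, n = c.n, m = c.m;
  IntegerVector cdm = cand.attr("dim");
  int nv = (cdm.size() == 3) ? cdm[2] : 1;
  if ((int)d.size() != m - 1) stop("need m-1 interval distances");
  std::vector<double> ahat((size_t)S * n * m), la((size_t)n * m);
  std::vector<double> bhat((size_t)S * n * m), lb((size_t)n * m);
  NumericVector p(m - 1);
  for (int k = 0; k < m - 1; ++k) p[k] = interp_p(d[k], d_tab, p_tab);
  forward_pass(c, kind, p, ahat.data(), la.data());
  backward_pass(c, kind, p, bhat.data(), lb.data());

  ScanCtx X{c, kind, ahat.data(), la.data(), bhat.data(), lb.data(),
            REAL(cand), nv, d_tab, p_tab, {}, {}, {}};

  NumericMatrix slot_ll(m + 1, nv), slot_dl(m + 1, nv);
  double ll_chain = 0;
  for (int i = 0; i < n; ++i) ll_chain += la[i + (size_t)n * (m - 1)];

  for (int v = 0; v < nv; ++v) {
    // coarse pass
    std::vector<double> coarse(m + 1), cdl(m + 1);
    {
      // exterior: coarse over log-spaced distances
      double dg[6] = {0.5, 2, 5, 12, 25, 50};
      for (int side = 0; side < 2; ++side) {
        int slot = side == 0 ? 0 : m;
        double best = R_NegInf, bd = 1;
        for (double dd : dg) {
          if (dd > d_ext_max) break;
          double ll = side == 0 ? eval_slot(X, 0, v, 0, dd) : eval_slot(X, m, v, dd, 0);
          if (ll > best) { best = ll; bd = dd; }
        }
        coarse[slot] = best; cdl[slot] = bd;
      }
      for (int k = 1; k < m; ++k) {
        double dk = d[k - 1];
        coarse[k] = eval_slot(X, k, v, dk * 0.5, dk * 0.5);
        cdl[k] = dk * 0.5;
      }
    }
    // refine top slots by golden section
    std::vector<int> ord(m + 1);
    for (int k = 0; k <= m; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return coarse[a] > coarse[b]; });
    int nref = std::min(refine_k, m + 1);
    for (int j = 0; j < nref; ++j) {
      int k = ord[j];
      double xb, ll;
      if (k == 0) {
        ll = golden_max([&](double ld) { return eval_slot(X, 0, v, 0, std::exp(ld)); },
                        std::log(0.05), std::log(d_ext_max), 24, &xb);
        cdl[k] = std::exp(xb);
      } else if (k == m) {
        ll = golden_max([&](double ld) { return eval_slot(X, m, v, std::exp(ld), 0); },
                        std::log(0.05), std::log(d_ext_max), 24, &xb);
        cdl[k] = std::exp(xb);
      } else {
        double dk = d[k - 1];
        ll = golden_max([&](double f) { return eval_slot(X, k, v, f * dk, (1 - f) * dk); },
                        1e-4, 1 - 1e-4, 24, &xb);
        cdl[k] = xb * dk;
      }
      coarse[k] = std::max(coarse[k], ll);
    }
    for (int k = 0; k <= m; ++k) { slot_ll(k, v) = coarse[k]; slot_dl(k, v) = cdl[k]; }
  }
  return List::create(_["slot_ll"] = slot_ll, _["slot_dl"] = slot_dl,
                      _["loglik_chain"] = ll_chain);
}

// ---------------------------------------------------------------------------
// All-pairs 2-point EM on observed-class counts.
// obs: m x n integer matrix, 0 = missing, else class index 1..K_m.
// compat: per marker, a list of K x S 0/1 matrices (one per phase variant;
//         non-CP markers have a single variant).
// Joint prior over hidden pair: P(s,t) = (1/S) T(p)[s,t].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_two_point_all(IntegerMatrix obs, List compat, std::string kind,
                       int max_iter, double tol, double p_init,
                       IntegerVector pairs_i, IntegerVector pairs_j) {
  int m = obs.nrow(), n = obs.ncol();
  int S = kind_S(kind), ncomp = kind_ncomp(kind);
  bool all_pairs = pairs_i.size() == 0;
  int npairs = all_pairs ? m * (m - 1) / 2 : pairs_i.size();

  NumericMatrix R(m, m), LOD(m, m), NCOT(m, m);
  IntegerMatrix PH(m, m);
  std::fill(R.begin(), R.end(), NA_REAL);
  std::fill(LOD.begin(), LOD.end(), NA_REAL);
  std::fill(PH.begin(), PH.end(), NA_INTEGER);

  // pre-extract compat pointers
  std::vector<std::vector<const double *>> cm(m);
  std::vector<int> K(m);
  for (int i = 0; i < m; ++i) {
    List vi = compat[i];
    K[i] = NumericMatrix(as<NumericMatrix>(vi[0])).nrow();
    for (int v = 0; v < vi.size(); ++v)
      cm[i].push_back(REAL(as<NumericMatrix>(vi[v])));
  }

  int chg[MAXS][MAXS];
  for (int s = 0; s < S; ++s) for (int t = 0; t < S; ++t) chg[s][t] = n_changes(kind, s, t);

  double T[MAXS][MAXS];

  for (int idx = 0, a = 0, b = 1; idx < npairs; ++idx) {
    int i, j;
    if (all_pairs) {
      i = a; j = b;
      if (++b >= m) { ++a; b = a + 1; }
    } else { i = pairs_i[idx] - 1; j = pairs_j[idx] - 1; }

    int Ki = K[i], Kj = K[j];
    std::vector<double> N(Ki * Kj, 0.0);
    double Ntot = 0;
    for (int q = 0; q < n; ++q) {
      int oi = obs(i, q), oj = obs(j, q);
      if (oi == 0 || oj == 0) continue;
      N[(oi - 1) + Ki * (oj - 1)] += 1.0;
      Ntot += 1.0;
    }
    NCOT(i, j) = NCOT(j, i) = Ntot;
    if (Ntot == 0) { LOD(i, j) = LOD(j, i) = 0.0; continue; }

    double best_ll = R_NegInf, best_p = NA_REAL, best_ll0 = 0;
    int best_v = 0;
    const double *Ci = cm[i][0];  // fix marker i at variant 1
    for (size_t v = 0; v < cm[j].size(); ++v) {
      const double *Cj = cm[j][v];
      double p = p_init, ll = R_NegInf;
      for (int it = 0; it < max_iter; ++it) {
        fill_trans(kind, p, T);
        double E = 0, llnew = 0;
        for (int aK = 0; aK < Ki; ++aK)
          for (int bK = 0; bK < Kj; ++bK) {
            double cnt = N[aK + Ki * bK];
            if (cnt == 0) continue;
            double tot = 0, ex = 0;
            for (int s = 0; s < S; ++s) {
              if (Ci[aK + Ki * s] == 0) continue;
              for (int t = 0; t < S; ++t) {
                if (Cj[bK + Kj * t] == 0) continue;
                double w = (1.0 / S) * T[s][t];
                tot += w;
                ex += w * chg[s][t];
              }
            }
            llnew += cnt * std::log(tot);
            E += cnt * (ex / tot);
          }
        double pnew = std::min(0.5, std::max(1e-7, E / (Ntot * ncomp)));
        bool done = (it > 0 && llnew - ll < tol * (std::fabs(ll) + 1.0));
        ll = llnew; p = pnew;
        if (done) break;
      }
      // final likelihood at converged p, and null at p = 0.5
      double ll_hat = 0, ll0 = 0;
      fill_trans(kind, p, T);
      double T0[MAXS][MAXS];
      fill_trans(kind, 0.5, T0);
      for (int aK = 0; aK < Ki; ++aK)
        for (int bK = 0; bK < Kj; ++bK) {
          double cnt = N[aK + Ki * bK];
          if (cnt == 0) continue;
          double tot = 0, tot0 = 0;
          for (int s = 0; s < S; ++s) {
            if (Ci[aK + Ki * s] == 0) continue;
            for (int t = 0; t < S; ++t) {
              if (Cj[bK + Kj * t] == 0) continue;
              tot += (1.0 / S) * T[s][t];
              tot0 += (1.0 / S) * T0[s][t];
            }
          }
          ll_hat += cnt * std::log(tot);
          ll0 += cnt * std::log(tot0);
        }
      if (ll_hat > best_ll) { best_ll = ll_hat; best_p = p; best_v = v + 1; best_ll0 = ll0; }
    }
    double lod = (best_ll - best_ll0) / std::log(10.0);
    if (lod < 0) lod = 0;
    R(i, j) = R(j, i) = best_p;
    LOD(i, j) = LOD(j, i) = lod;
    PH(i, j) = PH(j, i) = best_v;
  }
  return List::create(_["p"] = R, _["lod"] = LOD, _["phase"] = PH, _["n"] = NCOT);
}
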