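#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pruning-algorithm likelihood core for state-dependent speciation-extinction
// models.  Two rate maps share one integrator:
//   model 1: anagenetic k-state ("MuSSE-like": BiSSE k=2, HiSSE k=3/4/8)
//   model 2: GeoSSE (states A=0, B=1, AB=2) with cladogenetic node merges
// Along every branch the coupled (E, D) system is integrated with an
// embedded Dormand-Prince 5(4) pair and per-branch renormalization of D
// (log of the normalizer accumulated) so long trees never underflow.

#define MAXK 8

struct SseModel {
  int type;     // 1 = anagenetic k-state, 2 = geosse
  int k;        // number of states
  double lambda[MAXK];
  double mu[MAXK];
  double Q[MAXK][MAXK]; // off-diagonal transition rates, Q[i][j] = rate i -> j
  double qrow[MAXK];    // row sums of Q
  double g[7];          // geosse: sA sB sAB xA xB dA dB
};

static void sse_deriv(const SseModel &m, const double *y, double *dy) {
  const double *E = y;
  const double *D = y + m.k;
  double *dE = dy;
  double *dD = dy + m.k;
  if (m.type == 1) {
    for (int i = 0; i < m.k; ++i) {
      double tot = m.lambda[i] + m.mu[i] + m.qrow[i];
      double se = m.mu[i] - tot * E[i] + m.lambda[i] * E[i] * E[i];
      double sd = -tot * D[i] + 2.0 * m.lambda[i] * E[i] * D[i];
      for (int j = 0; j < m.k; ++j) {
        if (j == i) continue;
        se += m.Q[i][j] * E[j];
        sd += m.Q[i][j] * D[j];
      }
      dE[i] = se;
      dD[i] = sd;
    }
  } else {
    const double sA = m.g[0], sB = m.g[1], sAB = m.g[2];
    const double xA = m.g[3], xB = m.g[4], dA = m.g[5], dB = m.g[6];
    const double EA = E[0], EB = E[1], EAB = E[2];
    const double DA = D[0], DB = D[1], DAB = D[2];
    dE[0] = xA - (sA + dA + xA) * EA + sA * EA * EA + dA * EAB;
    dE[1] = xB - (sB + dB + xB) * EB + sB * EB * EB + dB * EAB;
    dE[2] = -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA +
            sA * EA * EAB + sB * EB * EAB + sAB * EA * EB;
    dD[0] = -(sA + dA + xA) * DA + dA * DAB + 2.0 * sA * EA * DA;
    dD[1] = -(sB + dB + xB) * DB + dB * DAB + 2.0 * sB * EB * DB;
    dD[2] = -(sA + sB + sAB + xA + xB) * DAB + xA * DB + xB * DA +
            sA * (EA * DAB + EAB * DA) + sB * (EB * DAB + EAB * DB) +
            sAB * (EA * DB + EB * DA);
  }
}

// Dormand-Prince 5(4) with standard step-size control.  Returns false on
// failure (step underflow / non-finite state).
static bool integrate_branch(const SseModel &m, double *y, double len,
                             double rtol, double atol) {
  if (len <= 0.0) return true;
  const int n = 2 * m.k;
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
  (void)c2; (void)c3; (void)c4; (void)c5;

  double k1[2 * MAXK], k2[2 * MAXK], k3[2 * MAXK], k4[2 * MAXK],
      k5[2 * MAXK], k6[2 * MAXK], k7[2 * MAXK], yt[2 * MAXK],
      ynew[2 * MAXK];
  double t = 0.0, h = len;
  int nstep = 0;
  sse_deriv(m, y, k1);
  while (t < len) {
    if (++nstep > 20000) return false; // pathological stiffness: give up, caller reports -Inf
    if (t + h > len) h = len - t;
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    sse_deriv(m, yt, k2);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sse_deriv(m, yt, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sse_deriv(m, yt, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    sse_deriv(m, yt, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    sse_deriv(m, yt, k6);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    sse_deriv(m, ynew, k7);
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) return false;
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i]; // FSAL
      }
    }
    double fac = (errnorm > 0.0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14 * len) return false;
  }
  return true;
}

static void merge_node(const SseModel &m, const double *DL, const double *DR,
                       double *Dout) {
  if (m.type == 1) {
    for (int i = 0; i < m.k; ++i) Dout[i] = m.lambda[i] * DL[i] * DR[i];
  } else {
    const double sA = m.g[0], sB = m.g[1], sAB = m.g[2];
    Dout[0] = sA * DL[0] * DR[0];
    Dout[1] = sB * DL[1] * DR[1];
    Dout[2] = 0.5 * (sA * (DL[0] * DR[2] + DL[2] * DR[0]) +
                     sB * (DL[1] * DR[2] + DL[2] * DR[1]) +
                     sAB * (DL[0] * DR[1] + DL[1] * DR[0]));
  }
}

// [[Rcpp::export]]
List sse_pruning_cpp(IntegerMatrix edge, NumericVector edge_len, int n_tip,
                     int root, NumericMatrix tipD, NumericVector E0,
                     int model_type, NumericVector lambda, NumericVector mu,
                     NumericMatrix Q, NumericVector gpars, double rtol,
                     double atol, int constrain_node, int constrain_state) {
  SseModel m;
  m.type = model_type;
  m.k = (model_type == 2) ? 3 : lambda.size();
  if (m.k > MAXK) stop("state space too large for engine");
  if (model_type == 1) {
    for (int i = 0; i < m.k; ++i) {
      m.lambda[i] = lambda[i];
      m.mu[i] = mu[i];
      double rs = 0.0;
      for (int j = 0; j < m.k; ++j) {
        m.Q[i][j] = (i == j) ? 0.0 : Q(i, j);
        if (i != j) rs += Q(i, j);
      }
      m.qrow[i] = rs;
    }
  } else {
    for (int i = 0; i < 7; ++i) m.g[i] = gpars[i];
  }

  const int n_edge = edge.nrow();
  const int n_all = n_tip + n_edge + 1 - n_tip; // tips + internals
  const int N = std::max(n_all, root) + 1;
  std::vector<double> Dn(N * m.k, 0.0), En(N * m.k, 0.0);
  std::vector<int> nchild(N, 0);
  double logcomp = 0.0;
  bool ok = true;

  // node indices are ape 1-based; use them directly (slot 0 unused)
  for (int i = 0; i < n_tip; ++i) {
    for (int s = 0; s < m.k; ++s) {
      double d = tipD(i, s);
      if (constrain_node == i + 1 && s != constrain_state - 1) d = 0.0;
      Dn[(i + 1) * m.k + s] = d;
      En[(i + 1) * m.k + s] = E0[s];
    }
  }

  double ybuf[2 * MAXK];
  for (int eidx = 0; eidx < n_edge && ok; ++eidx) {
    int par = edge(eidx, 0), ch = edge(eidx, 1);
    for (int s = 0; s < m.k; ++s) {
      ybuf[s] = En[ch * m.k + s];
      ybuf[m.k + s] = Dn[ch * m.k + s];
    }
    if (!integrate_branch(m, ybuf, edge_len[eidx], rtol, atol)) {
      ok = false;
      break;
    }
    double dsum = 0.0;
    for (int s = 0; s < m.k; ++s) dsum += ybuf[m.k + s];
    if (!(dsum > 0.0) || !std::isfinite(dsum)) {
      ok = false;
      break;
    }
    logcomp += std::log(dsum);
    for (int s = 0; s < m.k; ++s) ybuf[m.k + s] /= dsum;

    if (nchild[par] == 0) {
      for (int s = 0; s < m.k; ++s) {
        En[par * m.k + s] = ybuf[s];
        Dn[par * m.k + s] = ybuf[m.k + s];
      }
      nchild[par] = 1;
    } else {
      double Dl[MAXK], Dr[MAXK], Dm[MAXK];
      for (int s = 0; s < m.k; ++s) {
        Dl[s] = Dn[par * m.k + s];
        Dr[s] = ybuf[m.k + s];
      }
      merge_node(m, Dl, Dr, Dm);
      for (int s = 0; s < m.k; ++s) Dn[par * m.k + s] = Dm[s];
      nchild[par] = 2;
      if (constrain_node == par) {
        for (int s = 0; s < m.k; ++s)
          if (s != constrain_state - 1) Dn[par * m.k + s] = 0.0;
      }
    }
  }

  NumericVector rootD(m.k), rootE(m.k);
  if (ok) {
    for (int s = 0; s < m.k; ++s) {
      rootD[s] = Dn[root * m.k + s];
      rootE[s] = En[root * m.k + s];
    }
  }
  return List::create(_["rootD"] = rootD, _["rootE"] = rootE,
                      _["logcomp"] = logcomp, _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// Truncated-normal Gibbs sweep over tip liabilities for the threshold model.
// Uses R's RNG so set.seed() governs reproducibility.

static double rtnorm_pos(double mu, double sd) {
  // sample z ~ N(mu, sd^2) conditioned on z > 0
  double alpha = -mu / sd; // lower bound on the standard scale
  if (alpha < 0.35) {
    double z;
    do {
      z = norm_rand();
    } while (z <= alpha);
    return mu + sd * z;
  } else if (alpha < 6.0) {
    double plo = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double u = plo + unif_rand() * (1.0 - plo);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return mu + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
  } else {
    // Robert (1995) exponential rejection for the deep tail
    for (;;) {
      double z = alpha + exp_rand() / alpha;
      double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
      if (unif_rand() <= rho) return mu + sd * z;
    }
  }
}

// [[Rcpp::export]]
List liability_sweep_cpp(NumericVector l, NumericMatrix W, NumericVector a,
                         NumericVector b, double ml, IntegerVector state,
                         double R11s, double R12s) {
  int n = l.size();
  NumericVector lo = clone(l), ao = clone(a);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double wii = W(i, i);
    double prec = R11s * wii;
    double sd = 1.0 / std::sqrt(prec);
    double off = R11s * (ao[i] - wii * (lo[i] - ml)) + R12s * b[i];
    double mu = ml - off / prec;
    double lnew;
    if (state[i] == 1) {
      lnew = rtnorm_pos(mu, sd);
    } else {
      lnew = -rtnorm_pos(-mu, sd);
    }
    double delta = lnew - lo[i];
    if (delta != 0.0) {
      for (int j = 0; j < n; ++j) ao[j] += W(j, i) * delta;
      lo[i] = lnew;
    }
  }
  return List::create(_["l"] = lo, _["a"] = ao);
}
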