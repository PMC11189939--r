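#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Double-hierarchical Gaussian model, adaptive Metropolis-within-Gibbs.
//
//   y_k ~ N(mu_k, sigma_k)
//   mu_k        = Xm_k . betam + a[id_k] + b[id_k] * t_k
//   log sigma_k = Xr_k . betar + w[id_k]
//
// Non-centred random effects: (a,b,w)_i = diag(sd) * L * z_i with
// L = chol(R) (lower) built from the three pairwise correlations
// (r_ab, r_aw, r_bw).  Priors: all fixed effects N(0,1); sd_j half-N(0,1)
// sampled on the log scale with Jacobian; R uniform over positive-definite
// correlation matrices (LKJ with shape 1); z ~ N(0,1).
//
// Rows must arrive sorted by individual; the R wrapper guarantees this and
// drives the RNG (R's own stream), so runs are reproducible via set.seed().

static inline double ldnorm(double y, double mu, double logsig) {
  const double z = (y - mu) / std::exp(logsig);
  return -0.9189385332046727 - logsig - 0.5 * z * z;
}

// lower Cholesky of the 3x3 correlation matrix; false if not PD
static bool chol3(double r12, double r13, double r23, double L[3][3]) {
  if (std::fabs(r12) >= 1.0 || std::fabs(r13) >= 1.0 ||
      std::fabs(r23) >= 1.0)
    return false;
  const double l22sq = 1.0 - r12 * r12;
  if (l22sq <= 1e-12) return false;
  const double l22 = std::sqrt(l22sq);
  const double l32 = (r23 - r12 * r13) / l22;
  const double l33sq = 1.0 - r13 * r13 - l32 * l32;
  if (l33sq <= 1e-12) return false;
  L[0][0] = 1.0;  L[0][1] = 0.0; L[0][2] = 0.0;
  L[1][0] = r12;  L[1][1] = l22; L[1][2] = 0.0;
  L[2][0] = r13;  L[2][1] = l32; L[2][2] = std::sqrt(l33sq);
  return true;
}

// in-place Cholesky (lower) of a small SPD matrix stored row-major
static bool small_chol(std::vector<double>& A, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= A[j * p + k] * A[j * p + k];
    if (d <= 0.0) return false;
    A[j * p + j] = std::sqrt(d);
    for (int i = j + 1; i < p; ++i) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= A[i * p + k] * A[j * p + k];
      A[i * p + j] = s / A[j * p + j];
    }
  }
  return true;
}

struct Model {
  const NumericVector y, tcov;
  const NumericMatrix Xm, Xr;
  const IntegerVector id;       // 0-based, sorted
  int N, n, pm, pr;
  bool prior_only;
  std::vector<int> start, stop; // row range per individual

  // state
  std::vector<double> betam, betar, ls, rho;  // ls = log sd (3), rho (3)
  std::vector<double> z;                      // n x 3, row-major
  double L[3][3];
  // caches
  std::vector<double> mfix, rfix;             // fixed-effect parts per row
  std::vector<double> a, b, w;                // realized effects per ind
  std::vector<double> lli;                    // log-lik per individual
  double ll;

  Model(NumericVector y_, NumericMatrix Xm_, NumericMatrix Xr_,
        IntegerVector id_, NumericVector t_, int n_, bool prior_only_)
      : y(y_), tcov(t_), Xm(Xm_), Xr(Xr_), id(id_),
        N(y_.size()), n(n_), pm(Xm_.ncol()), pr(Xr_.ncol()),
        prior_only(prior_only_),
        start(n_, 0), stop(n_, 0),
        betam(pm, 0.0), betar(pr, 0.0), ls(3, 0.0), rho(3, 0.0),
        z(3 * n_, 0.0),
        mfix(N, 0.0), rfix(N, 0.0),
        a(n_, 0.0), b(n_, 0.0), w(n_, 0.0), lli(n_, 0.0), ll(0.0) {
    std::vector<int> seen(n, 0);
    for (int k = 0; k < N; ++k) seen[id[k]]++;
    int acc = 0;
    for (int i = 0; i < n; ++i) { start[i] = acc; acc += seen[i]; stop[i] = acc; }
  }

  void refresh_fixed() {
    for (int k = 0; k < N; ++k) {
      double sm = 0.0, sr = 0.0;
      for (int j = 0; j < pm; ++j) sm += Xm(k, j) * betam[j];
      for (int j = 0; j < pr; ++j) sr += Xr(k, j) * betar[j];
      mfix[k] = sm; rfix[k] = sr;
    }
  }

  void refresh_re() {
    const double s0 = std::exp(ls[0]), s1 = std::exp(ls[1]),
                 s2 = std::exp(ls[2]);
    for (int i = 0; i < n; ++i) {
      const double z0 = z[3 * i], z1 = z[3 * i + 1], z2 = z[3 * i + 2];
      a[i] = s0 * z0;
      b[i] = s1 * (L[1][0] * z0 + L[1][1] * z1);
      w[i] = s2 * (L[2][0] * z0 + L[2][1] * z1 + L[2][2] * z2);
    }
  }

  double llik_ind(int i, double ai, double bi, double wi) const {
    if (prior_only) return 0.0;
    double s = 0.0;
    for (int k = start[i]; k < stop[i]; ++k)
      s += ldnorm(y[k], mfix[k] + ai + bi * tcov[k], rfix[k] + wi);
    return s;
  }

  void refresh_llik() {
    ll = 0.0;
    for (int i = 0; i < n; ++i) { lli[i] = llik_ind(i, a[i], b[i], w[i]); ll += lli[i]; }
  }
};

// [[Rcpp::export]]
List dhmm_mcmc(NumericVector y, NumericMatrix Xm, NumericMatrix Xr,
               IntegerVector id, NumericVector tcov, int n_ind,
               int iter, int warmup, int thin, bool prior_only,
               int time_col) {
  Model m(y, Xm, Xr, id, tcov, n_ind, prior_only);
  const int pm = m.pm, pr = m.pr, n = m.n;
  const int P = pm + pr + 3 + 3 + 3 * n + 3 + 3 + 3;

  // dispersed initial values (R RNG)
  for (int j = 0; j < pm; ++j) m.betam[j] = 0.2 * norm_rand();
  for (int j = 0; j < pr; ++j) m.betar[j] = 0.2 * norm_rand();
  for (int j = 0; j < 3; ++j) m.ls[j] = std::log(0.5) + 0.2 * norm_rand();
  for (int j = 0; j < 3; ++j) m.rho[j] = 0.1 * norm_rand();
  if (!chol3(m.rho[0], m.rho[1], m.rho[2], m.L))
    { m.rho[0] = m.rho[1] = m.rho[2] = 0.0; chol3(0, 0, 0, m.L); }
  for (int j = 0; j < 3 * n; ++j) m.z[j] = 0.5 * norm_rand();
  m.refresh_fixed();
  m.refresh_re();
  m.refresh_llik();

  std::vector<double> lstep(P, std::log(0.3));  // log proposal SDs
  std::vector<int> acc(P, 0);
  const int batch = 50;
  int batch_no = 0;

  int kept_count = 0;
  for (int it = warmup; it < iter; ++it)
    if ((it - warmup) % thin == 0) ++kept_count;
  NumericMatrix draws(kept_count, pm + pr + 6);
  NumericMatrix redraws(kept_count, 3 * n);

  std::vector<double> tmp_lli(n);

  int row = 0;
  for (int it = 0; it < iter; ++it) {
    int p = 0;

    // mean-model fixed effects: exact Gibbs draw from the conjugate
    // conditional (heteroscedastic normal regression with N(0,1) prior)
    {
      p += pm;  // keep the adaptation bookkeeping aligned
      std::vector<double> A(pm * pm, 0.0), v(pm, 0.0);
      for (int j = 0; j < pm; ++j) A[j * pm + j] = 1.0;
      if (!m.prior_only) {
        for (int k = 0; k < m.N; ++k) {
          const int i = m.id[k];
          const double lg = m.rfix[k] + m.w[i];
          const double wk = std::exp(-2.0 * lg);
          const double rk = y[k] - m.a[i] - m.b[i] * m.tcov[k];
          for (int u = 0; u < pm; ++u) {
            const double xu = Xm(k, u);
            v[u] += wk * xu * rk;
            for (int q = 0; q <= u; ++q) A[u * pm + q] += wk * xu * Xm(k, q);
          }
        }
        for (int u = 0; u < pm; ++u)
          for (int q = u + 1; q < pm; ++q) A[u * pm + q] = A[q * pm + u];
      }
      if (small_chol(A, pm)) {
        // solve L t = v, then L' mean = t; draw = mean + L'^{-1} z
        std::vector<double> t(pm), mn(pm), zv(pm);
        for (int u = 0; u < pm; ++u) {
          double s = v[u];
          for (int q = 0; q < u; ++q) s -= A[u * pm + q] * t[q];
          t[u] = s / A[u * pm + u];
        }
        for (int u = pm - 1; u >= 0; --u) {
          double s = t[u];
          for (int q = u + 1; q < pm; ++q) s -= A[q * pm + u] * mn[q];
          mn[u] = s / A[u * pm + u];
        }
        for (int u = 0; u < pm; ++u) zv[u] = norm_rand();
        for (int u = pm - 1; u >= 0; --u) {
          double s = zv[u];
          for (int q = u + 1; q < pm; ++q) s -= A[q * pm + u] * zv[q];
          zv[u] = s / A[u * pm + u];
        }
        for (int u = 0; u < pm; ++u) m.betam[u] = mn[u] + zv[u];
        if (!m.prior_only) {
          for (int k = 0; k < m.N; ++k) {
            double sm = 0.0;
            for (int j = 0; j < pm; ++j) sm += Xm(k, j) * m.betam[j];
            m.mfix[k] = sm;
          }
          m.refresh_llik();
        }
      }
    }

    // residual-model fixed effects
    for (int j = 0; j < pr; ++j, ++p) {
      const double cur = m.betar[j];
      const double prop = cur + std::exp(lstep[p]) * norm_rand();
      double newll = 0.0;
      if (!m.prior_only) {
        for (int k = 0; k < m.N; ++k) m.rfix[k] += Xr(k, j) * (prop - cur);
        for (int i = 0; i < n; ++i) { tmp_lli[i] = m.llik_ind(i, m.a[i], m.b[i], m.w[i]); newll += tmp_lli[i]; }
      }
      const double dlp = (newll - m.ll) - 0.5 * (prop * prop - cur * cur);
      if (std::isfinite(dlp) && std::log(unif_rand()) < dlp) {
        m.betar[j] = prop;
        if (!m.prior_only) { m.ll = newll; m.lli = tmp_lli; }
        ++acc[p];
      } else if (!m.prior_only) {
        for (int k = 0; k < m.N; ++k) m.rfix[k] -= Xr(k, j) * (prop - cur);
      }
    }

    // random-effect SDs, sampled as log sd; prior half-N(0,1) with Jacobian
    for (int j = 0; j < 3; ++j, ++p) {
      const double cur = m.ls[j];
      const double prop = cur + std::exp(lstep[p]) * norm_rand();
      if (prop > 12.0 || prop < -12.0) continue;   // guard overflow
      const double sd_cur = std::exp(cur), sd_prop = std::exp(prop);
      m.ls[j] = prop;
      m.refresh_re();
      double newll = 0.0;
      for (int i = 0; i < n; ++i) { tmp_lli[i] = m.llik_ind(i, m.a[i], m.b[i], m.w[i]); newll += tmp_lli[i]; }
      const double dlp = (newll - m.ll)
        - 0.5 * (sd_prop * sd_prop - sd_cur * sd_cur) + (prop - cur);
      if (std::isfinite(dlp) && std::log(unif_rand()) < dlp) {
        m.ll = newll; m.lli = tmp_lli; ++acc[p];
      } else {
        m.ls[j] = cur;
        m.refresh_re();
      }
    }

    // random-effect correlations; uniform prior over the PD elliptope
    for (int j = 0; j < 3; ++j, ++p) {
      const double cur = m.rho[j];
      const double prop = cur + std::exp(lstep[p]) * norm_rand();
      double Lnew[3][3];
      double r[3] = { m.rho[0], m.rho[1], m.rho[2] };
      r[j] = prop;
      if (!chol3(r[0], r[1], r[2], Lnew)) continue;
      double Lold[3][3];
      for (int u = 0; u < 3; ++u) for (int v = 0; v < 3; ++v) Lold[u][v] = m.L[u][v];
      m.rho[j] = prop;
      for (int u = 0; u < 3; ++u) for (int v = 0; v < 3; ++v) m.L[u][v] = Lnew[u][v];
      m.refresh_re();
      double newll = 0.0;
      for (int i = 0; i < n; ++i) { tmp_lli[i] = m.llik_ind(i, m.a[i], m.b[i], m.w[i]); newll += tmp_lli[i]; }
      const double dlp = newll - m.ll;
      if (std::isfinite(dlp) && std::log(unif_rand()) < dlp) {
        m.ll = newll; m.lli = tmp_lli; ++acc[p];
      } else {
        m.rho[j] = cur;
        for (int u = 0; u < 3; ++u) for (int v = 0; v < 3; ++v) m.L[u][v] = Lold[u][v];
        m.refresh_re();
      }
    }

    // latent standard normals, one scalar at a time; only the owning
    // individual's likelihood rows are touched
    const double s0 = std::exp(m.ls[0]), s1 = std::exp(m.ls[1]),
                 s2 = std::exp(m.ls[2]);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 3; ++c, ++p) {
        const double cur = m.z[3 * i + c];
        const double prop = cur + std::exp(lstep[p]) * norm_rand();
        m.z[3 * i + c] = prop;
        const double z0 = m.z[3 * i], z1 = m.z[3 * i + 1], z2 = m.z[3 * i + 2];
        const double ai = s0 * z0;
        const double bi = s1 * (m.L[1][0] * z0 + m.L[1][1] * z1);
        const double wi = s2 * (m.L[2][0] * z0 + m.L[2][1] * z1 + m.L[2][2] * z2);
        const double newlli = m.llik_ind(i, ai, bi, wi);
        const double dlp = (newlli - m.lli[i]) - 0.5 * (prop * prop - cur * cur);
        if (std::isfinite(dlp) && std::log(unif_rand()) < dlp) {
          m.ll += newlli - m.lli[i];
          m.lli[i] = newlli;
          m.a[i] = ai; m.b[i] = bi; m.w[i] = wi;
          ++acc[p];
        } else {
          m.z[3 * i + c] = cur;
        }
      }
    }

    // likelihood-invariant translation sweeps: move mass between an
    // intercept-like fixed effect and its random-effect column (delta added
    // to the fixed effect, subtracted from every individual's effect);
    // only the N(0,1) priors on the fixed effect and the latent z change
    for (int c = 0; c < 3; ++c, ++p) {
      if (c == 1 && time_col < 0) continue;
      double* fe = (c == 0) ? &m.betam[0]
                 : (c == 1) ? &m.betam[time_col] : &m.betar[0];
      const double sdc = std::exp(m.ls[c]);
      if (sdc < 1e-8) continue;
      const double delta = std::exp(lstep[p]) * norm_rand();
      // solve L dz = -delta/sd * e_c (same dz for every individual)
      double rhs[3] = { 0.0, 0.0, 0.0 };
      rhs[c] = -delta / sdc;
      double dz[3];
      dz[0] = rhs[0];
      dz[1] = (rhs[1] - m.L[1][0] * dz[0]) / m.L[1][1];
      dz[2] = (rhs[2] - m.L[2][0] * dz[0] - m.L[2][1] * dz[1]) / m.L[2][2];
      double dpr = -0.5 * ((*fe + delta) * (*fe + delta) - (*fe) * (*fe));
      for (int i = 0; i < n; ++i)
        for (int cc = 0; cc < 3; ++cc) {
          const double zc = m.z[3 * i + cc];
          dpr -= 0.5 * ((zc + dz[cc]) * (zc + dz[cc]) - zc * zc);
        }
      if (std::isfinite(dpr) && std::log(unif_rand()) < dpr) {
        *fe += delta;
        for (int i = 0; i < n; ++i) {
          for (int cc = 0; cc < 3; ++cc) m.z[3 * i + cc] += dz[cc];
          if (c == 0) m.a[i] -= delta;
          else if (c == 1) m.b[i] -= delta;
          else m.w[i] -= delta;
        }
        if (!m.prior_only) {
          if (c == 0) for (int k = 0; k < m.N; ++k) m.mfix[k] += delta;
          else if (c == 1)
            for (int k = 0; k < m.N; ++k) m.mfix[k] += delta * m.tcov[k];
          else for (int k = 0; k < m.N; ++k) m.rfix[k] += delta;
        }
        ++acc[p];
      }
    }

    // likelihood-invariant scale sweeps: rescale one random-effect SD while
    // transforming the latents so every realized (a, b, w) stays fixed
    // (the ancillary counterpart of sampling the SD conditional on z);
    // Jacobian of the latent map is exp(-n * delta)
    for (int c = 0; c < 3; ++c, ++p) {
      const double delta = std::exp(lstep[p]) * norm_rand();
      const double lsp = m.ls[c] + delta;
      if (lsp > 12.0 || lsp < -12.0) continue;
      const double sd_cur = std::exp(m.ls[c]), sd_prop = std::exp(lsp);
      const double shrink = std::exp(-delta);
      double dpr = -0.5 * (sd_prop * sd_prop - sd_cur * sd_cur)
                 + (lsp - m.ls[c]) - n * delta;
      std::vector<double> znew(3 * n);
      for (int i = 0; i < n; ++i) {
        const double z0 = m.z[3 * i], z1 = m.z[3 * i + 1],
                     z2 = m.z[3 * i + 2];
        double v0 = z0;
        double v1 = m.L[1][0] * z0 + m.L[1][1] * z1;
        double v2 = m.L[2][0] * z0 + m.L[2][1] * z1 + m.L[2][2] * z2;
        if (c == 0) v0 *= shrink; else if (c == 1) v1 *= shrink;
        else v2 *= shrink;
        const double n0 = v0;
        const double n1 = (v1 - m.L[1][0] * n0) / m.L[1][1];
        const double n2 = (v2 - m.L[2][0] * n0 - m.L[2][1] * n1) / m.L[2][2];
        znew[3 * i] = n0; znew[3 * i + 1] = n1; znew[3 * i + 2] = n2;
        dpr -= 0.5 * (n0 * n0 + n1 * n1 + n2 * n2
                      - z0 * z0 - z1 * z1 - z2 * z2);
      }
      if (std::isfinite(dpr) && std::log(unif_rand()) < dpr) {
        m.ls[c] = lsp;
        m.z = znew;
        ++acc[p];
      }
    }

    // likelihood-invariant correlation sweeps: re-draw one pairwise
    // correlation while transforming the latents so the realized effects
    // stay fixed; Jacobian is (det L / det L')^n on the latent block
    for (int j = 0; j < 3; ++j, ++p) {
      const double cur = m.rho[j];
      const double prop = cur + std::exp(lstep[p]) * norm_rand();
      double r[3] = { m.rho[0], m.rho[1], m.rho[2] };
      r[j] = prop;
      double Lnew[3][3];
      if (!chol3(r[0], r[1], r[2], Lnew)) continue;
      const double ldet_ratio =
        std::log(m.L[1][1] * m.L[2][2]) - std::log(Lnew[1][1] * Lnew[2][2]);
      double dpr = n * ldet_ratio;
      std::vector<double> znew(3 * n);
      for (int i = 0; i < n; ++i) {
        const double z0 = m.z[3 * i], z1 = m.z[3 * i + 1],
                     z2 = m.z[3 * i + 2];
        const double v0 = z0;
        const double v1 = m.L[1][0] * z0 + m.L[1][1] * z1;
        const double v2 = m.L[2][0] * z0 + m.L[2][1] * z1 + m.L[2][2] * z2;
        const double n0 = v0;
        const double n1 = (v1 - Lnew[1][0] * n0) / Lnew[1][1];
        const double n2 = (v2 - Lnew[2][0] * n0 - Lnew[2][1] * n1)
                          / Lnew[2][2];
        znew[3 * i] = n0; znew[3 * i + 1] = n1; znew[3 * i + 2] = n2;
        dpr -= 0.5 * (n0 * n0 + n1 * n1 + n2 * n2
                      - z0 * z0 - z1 * z1 - z2 * z2);
      }
      if (std::isfinite(dpr) && std::log(unif_rand()) < dpr) {
        m.rho[j] = prop;
        for (int u = 0; u < 3; ++u)
          for (int v = 0; v < 3; ++v) m.L[u][v] = Lnew[u][v];
        m.z = znew;
        ++acc[p];
      }
    }

    // Robbins-Monro step-size adaptation during warmup, batches of 50
    if (it < warmup && (it + 1) % batch == 0) {
      ++batch_no;
      const double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
      for (int q = 0; q < P; ++q) {
        const double rate = (double)acc[q] / batch;
        lstep[q] += (rate > 0.44) ? delta : -delta;
        acc[q] = 0;
      }
    }
    if (it == warmup - 1) std::fill(acc.begin(), acc.end(), 0);

    if (it >= warmup && (it - warmup) % thin == 0) {
      int cidx = 0;
      for (int j = 0; j < pm; ++j) draws(row, cidx++) = m.betam[j];
      for (int j = 0; j < pr; ++j) draws(row, cidx++) = m.betar[j];
      for (int j = 0; j < 3; ++j) draws(row, cidx++) = std::exp(m.ls[j]);
      for (int j = 0; j < 3; ++j) draws(row, cidx++) = m.rho[j];
      for (int i = 0; i < n; ++i) {
        redraws(row, 3 * i) = m.a[i];
        redraws(row, 3 * i + 1) = m.b[i];
        redraws(row, 3 * i + 2) = m.w[i];
      }
      ++row;
    }
  }

  return List::create(_["draws"] = draws, _["re"] = redraws,
                      _["final_ll"] = m.ll);
}

// direct evaluation of the model log-likelihood for a given parameter set;
// used as an internal consistency check against the R-level evaluator
// [[Rcpp::export]]
double dhmm_loglik_cpp(NumericVector y, NumericMatrix Xm, NumericMatrix Xr,
                       IntegerVector id, NumericVector tcov,
                       NumericVector betam, NumericVector betar,
                       NumericVector a, NumericVector b, NumericVector w) {
  const int N = y.size();
  double s = 0.0;
  for (int k = 0; k < N; ++k) {
    double mu = a[id[k]] + b[id[k]] * tcov[k];
    double lg = w[id[k]];
    for (int j = 0; j < Xm.ncol(); ++j) mu += Xm(k, j) * betam[j];
    for (int j = 0; j < Xr.ncol(); ++j) lg += Xr(k, j) * betar[j];
    s += ldnorm(y[k], mu, lg);
  }
  return s;
}
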