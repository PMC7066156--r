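// Weighted linear quantile regression by a primal-dual interior-point
// method on the bounded-variable LP dual (Frisch-Newton scheme with a
// Mehrotra predictor-corrector), specialized to the intercept+slope design.
//
// Primal:  min_{b0,b1}  sum_i w_i * rho_tau(y_i - b0 - b1 x_i)
// Row-scaling the design and response by w reduces the weighted problem to
// the unweighted one (rho_tau is positively homogeneous), so the solver
// works on pre-scaled columns c1 = w, c2 = w*x, y = w*y throughout.
//
// Dual:    max_a  y'a   s.t.  C'a = (1 - tau) C'1,  0 <= a <= 1
// KKT: y - C beta + z - w = 0 with z, w >= 0 (so z = (C beta - y)^+,
// w = (y - C beta)^+), complementarity a.z = 0, (1 - a).w = 0.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int    IPM_MAXIT = 100;
static const double IPM_STEP  = 0.99995;  // fraction-to-boundary damping

struct Work {  // preallocated scratch, reused across fits
  vec a, s, z, w, d, r, r2c, ia, is, iz, iw, g1, g2, da, dz, dw;
  void resize(uword n) {
    if (a.n_elem == n) return;
    a.set_size(n); s.set_size(n); z.set_size(n); w.set_size(n);
    d.set_size(n); r.set_size(n); r2c.set_size(n);
    ia.set_size(n); is.set_size(n); iz.set_size(n); iw.set_size(n);
    g1.set_size(n); g2.set_size(n);
    da.set_size(n); dz.set_size(n); dw.set_size(n);
  }
};

// Solve the 2x2 system M beta = rhs; returns false if singular.
static inline bool solve2(double m11, double m12, double m22,
                          double rhs1, double rhs2,
                          double& b1, double& b2) {
  double det = m11 * m22 - m12 * m12;
  if (!(std::abs(det) > 1e-300)) return false;
  b1 = ( m22 * rhs1 - m12 * rhs2) / det;
  b2 = (-m12 * rhs1 + m11 * rhs2) / det;
  return true;
}

// One fit at level tau on weight-scaled columns. beta0/beta1 out.
static bool qr_ipm_fit(const double* __restrict__ c1,
                       const double* __restrict__ c2,
                       const double* __restrict__ y,
                       uword n, double tau, double& beta0, double& beta1,
                       double tol, Work& Wk) {
  Wk.resize(n);
  double *__restrict__ a = Wk.a.memptr(), *__restrict__ s = Wk.s.memptr(), *__restrict__ z = Wk.z.memptr(),
         *__restrict__ w = Wk.w.memptr(), *__restrict__ d = Wk.d.memptr(),
         *__restrict__ r = Wk.r.memptr(), *__restrict__ r2c = Wk.r2c.memptr(),
         *__restrict__ ia = Wk.ia.memptr(), *__restrict__ is = Wk.is.memptr(),
         *__restrict__ iz = Wk.iz.memptr(), *__restrict__ iw = Wk.iw.memptr(),
         *__restrict__ g1 = Wk.g1.memptr(), *__restrict__ g2 = Wk.g2.memptr(),
         *__restrict__ da = Wk.da.memptr(), *__restrict__ dz = Wk.dz.memptr(),
         *__restrict__ dw = Wk.dw.memptr();

  // equality rhs b_eq = (1 - tau) * C'1
  double be1 = 0.0, be2 = 0.0;
  for (uword i = 0; i < n; ++i) { be1 += c1[i]; be2 += c2[i]; }
  be1 *= (1.0 - tau); be2 *= (1.0 - tau);

  // initial beta: least squares on the scaled design
  {
    double m11 = 0, m12 = 0, m22 = 0, q1 = 0, q2 = 0;
    for (uword i = 0; i < n; ++i) {
      m11 += c1[i] * c1[i]; m12 += c1[i] * c2[i]; m22 += c2[i] * c2[i];
      q1 += c1[i] * y[i];   q2 += c2[i] * y[i];
    }
    if (!solve2(m11, m12, m22, q1, q2, beta0, beta1)) return false;
  }

  double yscale = 1.0, rabs = 0.0;
  for (uword i = 0; i < n; ++i) {
    r[i] = y[i] - beta0 * c1[i] - beta1 * c2[i];
    rabs += std::abs(r[i]);
    yscale += std::abs(y[i]);
  }
  double delta = 0.1 * rabs / n + 1e-4;
  for (uword i = 0; i < n; ++i) {
    a[i] = 1.0 - tau; s[i] = tau;
    z[i] = (r[i] < 0 ? -r[i] : 0.0) + delta;
    w[i] = (r[i] > 0 ?  r[i] : 0.0) + delta;
  }

  for (int it = 0; it < IPM_MAXIT; ++it) {
    double gap = 0.0, r11 = be1, r12 = be2;
    for (uword i = 0; i < n; ++i) {
      gap += a[i] * z[i] + s[i] * w[i];
      r11 -= c1[i] * a[i];
      r12 -= c2[i] * a[i];
      ia[i] = 1.0 / a[i]; is[i] = 1.0 / s[i];
      iz[i] = 1.0 / z[i]; iw[i] = 1.0 / w[i];
      d[i] = 1.0 / (z[i] * ia[i] + w[i] * is[i]);
      r2c[i] = -r[i] - z[i] + w[i];   // -(y - C beta + z - w)
    }
    if (gap < tol * yscale) break;

    // predictor (affine, mu = 0):
    // da = d .* (-C dbeta - r2c - z + w); C' da = r1  =>
    // (C'DC) dbeta = C'[d(-r2c - z + w)] - r1
    double m11 = 0, m12 = 0, m22 = 0, q1 = 0, q2 = 0;
    for (uword i = 0; i < n; ++i) {
      double di = d[i], e = di * (-r2c[i] - z[i] + w[i]);
      m11 += di * c1[i] * c1[i];
      m12 += di * c1[i] * c2[i];
      m22 += di * c2[i] * c2[i];
      q1 += c1[i] * e; q2 += c2[i] * e;
    }
    double db0, db1;
    if (!solve2(m11, m12, m22, q1 - r11, q2 - r12, db0, db1)) return false;

    // affine step lengths via max ratios (multiplications only)
    double mp = 0.0, md = 0.0;
    for (uword i = 0; i < n; ++i) {
      double dai = d[i] * (-(db0 * c1[i] + db1 * c2[i]) - r2c[i] - z[i] + w[i]);
      double dzi = -z[i] - (z[i] * ia[i]) * dai;
      double dwi = -w[i] + (w[i] * is[i]) * dai;
      da[i] = dai; dz[i] = dzi; dw[i] = dwi;
      double t = -dai * ia[i]; if (t > mp) mp = t;   //  a + ap*da >= 0
      t =  dai * is[i];        if (t > mp) mp = t;   //  s - ap*da >= 0
      t = -dzi * iz[i];        if (t > md) md = t;
      t = -dwi * iw[i];        if (t > md) md = t;
    }
    double ap = mp > 1.0 ? 1.0 / mp : 1.0;
    double ad = md > 1.0 ? 1.0 / md : 1.0;

    double gap_aff = 0.0;
    for (uword i = 0; i < n; ++i) {
      gap_aff += (a[i] + ap * da[i]) * (z[i] + ad * dz[i])
               + (s[i] - ap * da[i]) * (w[i] + ad * dw[i]);
    }
    if (gap_aff < 0) gap_aff = 0;
    double sigma = gap_aff / gap;
    sigma = sigma * sigma * sigma;
    double mu = sigma * gap / (2.0 * n);

    // corrector with second-order complementarity terms
    m11 = 0; m12 = 0; m22 = 0; q1 = 0; q2 = 0;
    for (uword i = 0; i < n; ++i) {
      g1[i] = (mu - da[i] * dz[i]) * ia[i];
      g2[i] = (mu + da[i] * dw[i]) * is[i];
      double di = d[i], e = di * (-r2c[i] + g1[i] - z[i] - g2[i] + w[i]);
      m11 += di * c1[i] * c1[i];
      m12 += di * c1[i] * c2[i];
      m22 += di * c2[i] * c2[i];
      q1 += c1[i] * e; q2 += c2[i] * e;
    }
    if (!solve2(m11, m12, m22, q1 - r11, q2 - r12, db0, db1)) return false;

    mp = 0.0; md = 0.0;
    for (uword i = 0; i < n; ++i) {
      double dai = d[i] * (-(db0 * c1[i] + db1 * c2[i])
                           - r2c[i] + g1[i] - z[i] - g2[i] + w[i]);
      double dzi = g1[i] - z[i] - (z[i] * ia[i]) * dai;
      double dwi = g2[i] - w[i] + (w[i] * is[i]) * dai;
      da[i] = dai; dz[i] = dzi; dw[i] = dwi;
      double t = -dai * ia[i]; if (t > mp) mp = t;
      t =  dai * is[i];        if (t > mp) mp = t;
      t = -dzi * iz[i];        if (t > md) md = t;
      t = -dwi * iw[i];        if (t > md) md = t;
    }
    ap = IPM_STEP / std::max(mp, IPM_STEP);   // min(1, IPM_STEP/mp)
    ad = IPM_STEP / std::max(md, IPM_STEP);

    beta0 += ad * db0; beta1 += ad * db1;
    for (uword i = 0; i < n; ++i) {
      a[i] += ap * da[i];
      s[i] = 1.0 - a[i];
      z[i] += ad * dz[i];
      w[i] += ad * dw[i];
      r[i] -= ad * (db0 * c1[i] + db1 * c2[i]);
    }
  }
  return std::isfinite(beta0) && std::isfinite(beta1);
}


// ---------------------------------------------------------------------------
// Exact simplex solver for the same problem: the optimum of the check-loss
// LP with an intercept and one covariate lies on a line through two data
// points; starting from the weighted tau-quantile intercept, alternately
// rotate the line about its two basis points to the optimal slope along
// that edge (a weighted-quantile selection over pairwise slopes) until no
// rotation improves. Each rotation is the minimization of a convex
// piecewise-linear function of the slope, so the walk is a monotone
// vertex-to-vertex simplex path and terminates at the global optimum.

// first index (in implicit sorted order of v) where cumulative weight >= need;
// operates destructively on v/m/id within [0, n), returning the id of the
// attained kink. Expected O(n) quickselect.
static uword weighted_kink(double* v, double* m, uword* id, uword n,
                           double need) {
  uword lo = 0, hi = n;          // active window [lo, hi)
  while (hi - lo > 32) {
    double p = v[lo + (hi - lo) / 2];
    double p2 = v[lo], p3 = v[hi - 1];
    // median of three
    if ((p2 > p) != (p2 > p3)) p = p2;
    else if ((p3 > p) != (p3 > p2)) p = p3;
    uword i = lo, j = hi;
    double wl = 0.0;
    while (i < j) {
      if (v[i] <= p) { wl += m[i]; ++i; }
      else {
        --j;
        std::swap(v[i], v[j]); std::swap(m[i], m[j]); std::swap(id[i], id[j]);
      }
    }
    if (i == lo || i == hi) break;   // all equal; bail to scan
    if (need <= wl) hi = i; else { need -= wl; lo = i; }
  }
  // insertion sort the remaining window, then scan
  for (uword i = lo + 1; i < hi; ++i) {
    double vv = v[i], mm = m[i]; uword ii = id[i]; uword j = i;
    while (j > lo && v[j - 1] > vv) {
      v[j] = v[j - 1]; m[j] = m[j - 1]; id[j] = id[j - 1]; --j;
    }
    v[j] = vv; m[j] = mm; id[j] = ii;
  }
  double cum = 0.0;
  for (uword i = lo; i < hi; ++i) {
    cum += m[i];
    if (cum >= need - 1e-12 * (1.0 + need)) return i;
  }
  return hi - 1;
}

static double qr_objective(const double* x, const double* y, const double* w,
                           uword n, double tau, double a, double b) {
  double obj = 0.0;
  for (uword i = 0; i < n; ++i) {
    double u = y[i] - a - b * x[i];
    obj += w[i] * u * (tau - (u < 0 ? 1.0 : 0.0));
  }
  return obj;
}

// Optimal rotation of the line about data point c: returns new slope (and
// partner index) minimizing the check loss along that edge. sv/sm/sidx are
// caller-owned scratch of length n.
static bool rotate_about(const double* x, const double* y, const double* w,
                         uword n, double tau, uword c,
                         double* sv, double* sm, uword* sidx,
                         double& b_out, uword& partner) {
  const double xc = x[c], yc = y[c];
  uword m = 0;
  double Upos = 0.0, Uneg = 0.0;
  for (uword i = 0; i < n; ++i) {
    double u = x[i] - xc;
    if (u == 0.0) continue;
    double wm = w[i] * std::abs(u);
    if (u > 0) Upos += wm; else Uneg += wm;
    sv[m] = (y[i] - yc) / u;
    sm[m] = wm;
    sidx[m] = i;
    ++m;
  }
  if (m == 0) return false;
  double need = tau * Upos + (1.0 - tau) * Uneg;
  uword k = weighted_kink(sv, sm, sidx, m, need);
  b_out = sv[k];
  partner = sidx[k];
  return true;
}

// Exact fit; returns false if it fails to converge (caller falls back to
// the interior-point solver, which also resolves exact-tie plateaus).
// sv/sm/sidx are caller-owned scratch of length n. Each rotation jumps to
// the check-loss optimum along the line through the current center, so the
// objective is non-increasing by construction; a vertex whose two basis
// edges both admit no better slope is the global optimum. `hint` warm-starts
// from a previous solution (slope + basis point), e.g. the adjacent tau.
static bool qr_simplex_fit(const double* x, const double* y, const double* w,
                           uword n, double tau,
                           double* sv, double* sm, uword* sidx,
                           double& a_out, double& b_out, uword& basis_out,
                           bool warm = false, double b_init = 0.0,
                           uword center_init = 0) {
  double b;
  uword center;
  if (warm && std::isfinite(b_init)) {
    b = b_init;
    center = center_init;
  } else {
    // initial slope: weighted least squares
    double sw = 0, sx = 0, sy = 0, sxx = 0, sxy = 0;
    for (uword i = 0; i < n; ++i) {
      sw += w[i]; sx += w[i] * x[i]; sy += w[i] * y[i];
      sxx += w[i] * x[i] * x[i]; sxy += w[i] * x[i] * y[i];
    }
    double det = sw * sxx - sx * sx;
    if (!(std::abs(det) > 0)) return false;
    b = (sw * sxy - sx * sy) / det;
    // intercept = weighted tau-quantile of y - b x; pivot = attaining point
    for (uword i = 0; i < n; ++i) {
      sv[i] = y[i] - b * x[i]; sm[i] = w[i]; sidx[i] = i;
    }
    center = sidx[weighted_kink(sv, sm, sidx, n, tau * sw)];
  }
  uword basis0 = center, basis1 = n;

  int stale = 0;
  for (int it = 0; it < 200; ++it) {
    double b_new; uword partner;
    if (!rotate_about(x, y, w, n, tau, center, sv, sm, sidx,
                      b_new, partner)) return false;
    if (b_new != b) {            // strict improvement along this edge
      b = b_new;
      basis0 = center; basis1 = partner;
      center = partner;          // rotate about the new point next
      stale = 0;
    } else {
      basis1 = partner;          // current b attained by edge (center, partner)
      ++stale;
      if (stale >= 2) break;
      center = (center == basis0) ? basis1 : basis0;   // try the other edge
    }
  }
  if (stale < 2) return false;   // hit rotation cap: possible tie plateau
  a_out = y[basis0] - b * x[basis0];
  b_out = b;
  basis_out = basis0;
  return true;
}


// [[Rcpp::export]]
arma::mat qr_process_cpp(const arma::vec& x, const arma::vec& y,
                         const arma::vec& w, const arma::vec& taus,
                         double tol = 1e-10) {
  const uword n = x.n_elem;
  vec c1 = w, c2 = w % x, yw = w % y;
  vec sv(n), sm(n);
  std::vector<uword> sidx(n);
  mat coef(taus.n_elem, 2, fill::value(datum::nan));
  Work Wk;
  double b0, b1;
  double b_prev = datum::nan;
  uword basis = 0, basis_prev = 0;
  bool have_prev = false;
  for (uword k = 0; k < taus.n_elem; ++k) {
    if (qr_simplex_fit(x.memptr(), y.memptr(), w.memptr(), n, taus(k),
                       sv.memptr(), sm.memptr(), sidx.data(), b0, b1, basis,
                       have_prev, b_prev, basis_prev)) {
      coef(k, 0) = b0; coef(k, 1) = b1;
      b_prev = b1; basis_prev = basis; have_prev = true;
    } else if (qr_ipm_fit(c1.memptr(), c2.memptr(), yw.memptr(), n,
                          taus(k), b0, b1, tol, Wk)) {
      coef(k, 0) = b0; coef(k, 1) = b1;
      have_prev = false;
    }
  }
  return coef;
}

// Bootstrap refits: idx is an n x B matrix of 0-based resampling indices.
// Returns a B x ntau matrix of slope coefficients.
// [[Rcpp::export]]
arma::mat qr_boot_cpp(const arma::vec& x, const arma::vec& y,
                      const arma::vec& w, const arma::vec& taus,
                      const arma::umat& idx, double tol = 1e-8) {
  const uword n = idx.n_rows, B = idx.n_cols, ntau = taus.n_elem;
  mat slopes(B, ntau, fill::value(datum::nan));
  vec c1(n), c2(n), yb(n), xb(n), wb(n), yr(n), sv(n), sm(n);
  std::vector<uword> sidx(n);
  Work Wk;
  double b0, b1;
  for (uword rep = 0; rep < B; ++rep) {
    for (uword i = 0; i < n; ++i) {
      uword j = idx(i, rep);
      double wi = w(j);
      xb(i) = x(j); wb(i) = wi; yr(i) = y(j);
      c1(i) = wi; c2(i) = wi * x(j); yb(i) = wi * y(j);
    }
    double b_prev = datum::nan;
    uword basis = 0, basis_prev = 0;
    bool have_prev = false;
    for (uword k = 0; k < ntau; ++k) {
      if (qr_simplex_fit(xb.memptr(), yr.memptr(), wb.memptr(), n, taus(k),
                         sv.memptr(), sm.memptr(), sidx.data(), b0, b1, basis,
                         have_prev, b_prev, basis_prev)) {
        slopes(rep, k) = b1;
        b_prev = b1; basis_prev = basis; have_prev = true;
      } else if (qr_ipm_fit(c1.memptr(), c2.memptr(), yb.memptr(), n,
                            taus(k), b0, b1, tol, Wk)) {
        slopes(rep, k) = b1;
        have_prev = false;
      }
    }
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return slopes;
}
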