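// Discretized propagation of the Extended ITB accumulator.
//
// Computes, per trial, the exact choice probability by propagating a
// probability mass vector over LPO bins between -B and +B with two
// absorbing bound masses. Validated fast paths (see the methods vignette):
//  - trials whose LPO distribution provably stays clear of the bound on
//    every frame use the analytic Gaussian recursion instead of the grid;
//  - the per-frame LLO offset is applied afterwards as a linearly
//    interpolated shift, so one contraction+blur transition operator
//    serves all trials and frames, applied to all grid trials at once
//    as a BLAS matrix product.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Standard normal CDF lookup table (linear interpolation), range +/-8.5.
struct PhiTable {
  std::vector<double> tab;
  double lo, step, inv_step;
  PhiTable() : lo(-8.5), step(0.004) {
    inv_step = 1.0 / step;
    int K = (int)std::ceil(17.0 / step) + 2;
    tab.resize(K);
    for (int i = 0; i < K; i++) tab[i] = R::pnorm(lo + i * step, 0.0, 1.0, 1, 0);
  }
  inline double operator()(double x) const {
    if (x <= lo) return 0.0;
    double u = (x - lo) * inv_step;
    int i = (int)u;
    if (i >= (int)tab.size() - 1) return 1.0;
    double f = u - i;
    return tab[i] + f * (tab[i + 1] - tab[i]);
  }
};

// E[crule(clamp(u, -B, B))] for u ~ N(m, v): bound tails exactly, the
// interior integral of the sigmoid by trapezoid quadrature with spacing
// fine relative to both the temperature and the sd.
static double expect_crule_clamped(double m, double v, double B, double lapse,
                                   double T, double crule_lo, double crule_hi) {
  double sd = std::sqrt(v);
  if (sd <= 0.0) {
    double u = m > B ? B : (m < -B ? -B : m);
    return lapse + (1.0 - 2.0 * lapse) * sigmoid(u / T);
  }
  double p_lo = R::pnorm((-B - m) / sd, 0.0, 1.0, 1, 0);
  double p_hi = R::pnorm((B - m) / sd, 0.0, 1.0, 0, 0);
  double lo = std::max(-B, m - 9.0 * sd);
  double hi = std::min(B, m + 9.0 * sd);
  double I = 0.0;
  if (hi > lo) {
    double dx = T / 4.0;
    if (sd / 16.0 < dx) dx = sd / 16.0;
    int K = (int)std::ceil((hi - lo) / dx);
    if (K < 16) K = 16;
    if (K > 20000) K = 20000;
    dx = (hi - lo) / K;
    for (int k = 0; k <= K; k++) {
      double u = lo + k * dx;
      double w = (k == 0 || k == K) ? 0.5 : 1.0;
      I += w * sigmoid(u / T) * R::dnorm(u, m, sd, 0);
    }
    I *= dx;
  }
  return crule_lo * p_lo + crule_hi * p_hi +
         lapse * (1.0 - p_lo - p_hi) + (1.0 - 2.0 * lapse) * I;
}

// E[sigmoid(u/T)] for u ~ N(m, v): step part P(u > 0) plus the smooth
// correction integrated on a grid fine relative to both T and sd.
static double expect_sigmoid_gauss(double m, double v, double T) {
  if (v <= 0.0) return sigmoid(m / T);
  double sd = std::sqrt(v);
  double base = R::pnorm(m / sd, 0.0, 1.0, 1, 0);
  double lo = -20.0 * T, hi = 20.0 * T;
  if (lo < m - 9.0 * sd) lo = m - 9.0 * sd;
  if (hi > m + 9.0 * sd) hi = m + 9.0 * sd;
  double corr = 0.0;
  if (hi > lo) {
    double dx = T / 4.0;
    if (sd / 16.0 < dx) dx = sd / 16.0;
    int K = (int)std::ceil((hi - lo) / dx);
    if (K < 8) K = 8;
    if (K > 4000) K = 4000;
    dx = (hi - lo) / K;
    for (int k = 0; k <= K; k++) {
      double u = lo + k * dx;
      double w = (k == 0 || k == K) ? 0.5 : 1.0;
      double stp = (u > 0.0) ? 1.0 : (u == 0.0 ? 0.5 : 0.0);
      corr += w * (sigmoid(u / T) - stp) * R::dnorm(u, m, sd, 0);
    }
    corr *= dx;
  }
  double p = base + corr;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
NumericVector itb_choice_prob_cpp(NumericMatrix llo, double lpo0, double lapse,
                                  double temp, double noise, double bound,
                                  double leak, double clip, double bin_width) {
  const int n = llo.nrow(), F = llo.ncol();
  NumericVector out(n);
  const double B = std::min(bound, clip);
  if (B <= 0.0) stop("bound/clip must be positive");

  int nb = (int)std::ceil(2.0 * B / bin_width);
  if (nb < 8) nb = 8;
  if (nb > 200000) stop("LPO grid too large; increase bin_width or reduce clip");
  const double h = 2.0 * B / nb;
  const double om = 1.0 - leak;
  const double noise2 = noise * noise;

  auto crule = [&](double u) {
    return lapse + (1.0 - 2.0 * lapse) * sigmoid(u / temp);
  };
  const double crule_hi = crule(B), crule_lo = crule(-B);
  auto center = [&](double j) { return -B + (j + 0.5) * h; };

  PhiTable Phi;

  // ---- phase 1: analytic Gaussian recursion per trial ------------------
  // While the cumulative (union-bound) absorption probability of the
  // unbounded Gaussian recursion stays below 1e-5, the grid is provably
  // unnecessary; the first frame exceeding the budget records the last
  // safe state (m,v) and switches the trial to the grid from there.
  std::vector<int> gtrial, gf0;
  std::vector<double> gm, gv;
  for (int t = 0; t < n; t++) {
    double m = lpo0, v = 0.0;
    if (std::fabs(lpo0) >= B) {
      out[t] = lpo0 > 0 ? crule_hi : crule_lo;
      continue;
    }
    int f0 = -1;
    double tail_sum = 0.0;
    for (int f = 0; f < F; f++) {
      double m2 = om * m + llo(t, f);
      double v2 = om * om * v + noise2;
      double sd2 = std::sqrt(v2);
      double tail;
      if (sd2 <= 0.0) {
        tail = std::fabs(m2) >= B ? 1.0 : 0.0;
      } else {
        double zf = (B - std::fabs(m2)) / sd2;
        double zn = (B + std::fabs(m2)) / sd2;
        tail = (zf < 8.0 ? R::pnorm(-zf, 0.0, 1.0, 1, 0) : 0.0) +
               (zn < 8.0 ? R::pnorm(-zn, 0.0, 1.0, 1, 0) : 0.0);
      }
      tail_sum += tail;
      if (tail_sum > 1e-5) { f0 = f; break; }
      m = m2; v = v2;
    }
    if (f0 < 0) {
      out[t] = lapse + (1.0 - 2.0 * lapse) * expect_sigmoid_gauss(m, v, temp);
    } else if (f0 == F - 1) {
      // only the final frame can touch the bound: finish by quadrature on
      // the clamped Gaussian instead of the grid
      double m2 = om * m + llo(t, f0);
      double v2 = om * om * v + noise2;
      out[t] = expect_crule_clamped(m2, v2, B, lapse, temp,
                                    crule_lo, crule_hi);
    } else {
      gtrial.push_back(t); gf0.push_back(f0);
      gm.push_back(m); gv.push_back(v);
    }
  }
  const int ng = (int)gtrial.size();
  if (ng == 0) return out;

  // ---- shared transition operator --------------------------------------
  // A[r, j]: mass of bin j landing (before the per-trial integer LLO
  // shift) in virtual destination row r. Rows are restricted to those
  // that can reach the grid under some occurring shift; kernel mass
  // outside always absorbs and is folded into per-column tail scalars.
  long dmax = 0;
  for (int k = 0; k < ng; k++)
    for (int f = gf0[k]; f < F; f++) {
      long d = std::labs(std::lround(llo(gtrial[k], f) / h)) + 1;
      if (d > dmax) dmax = d;
    }
  double spread = noise > 0 ? 4.0 * noise : h;
  long kmin = (long)std::floor((om * center(0) - spread + B) / h) - 1;
  long kmax = (long)std::floor((om * center(nb - 1) + spread + B) / h) + 1;
  long R0 = std::max(kmin, -dmax - 1);
  long R1 = std::min(kmax + 1, (long)nb + dmax + 1);
  if (R1 <= R0) { R0 = 0; R1 = 1; }
  const int RR = (int)(R1 - R0);
  if ((double)nb * ng > 8e7 || (double)RR * ng > 8e7)
    stop("ITB transition operator too large");

  // banded kernel: column j holds the destination band of bin j under the
  // contraction+blur map (no shift); the ~3e-5 mass outside +/-4 sd absorbs
  std::vector<long> kstart(nb);
  std::vector<int> klen(nb);
  std::vector<double> kval, kcum;
  std::vector<double> ktot(nb), tail_lo(nb, 0.0), tail_hi(nb, 0.0);
  std::vector<size_t> koff(nb + 1, 0);
  int band = 0;
  if (noise > 0.0) {
    const double inv_noise = 1.0 / noise;
    for (int j = 0; j < nb; j++) {
      double c = om * center(j);
      kstart[j] = (long)std::floor((c - spread + B) / h);
      long ihi = (long)std::floor((c + spread + B) / h) + 1;
      klen[j] = (int)(ihi - kstart[j] + 1);
      if (klen[j] > band) band = klen[j];
      koff[j + 1] = koff[j] + klen[j];
    }
    kval.resize(koff[nb]);
    kcum.resize(koff[nb]);
    for (int j = 0; j < nb; j++) {
      double c = om * center(j);
      double prev = Phi(((-B + kstart[j] * h) - c) * inv_noise);
      tail_lo[j] = prev;
      double acc = 0.0;
      for (int k = 0; k < klen[j]; k++) {
        double cur = Phi(((-B + (kstart[j] + k + 1) * h) - c) * inv_noise);
        double val = cur - prev;
        prev = cur;
        kval[koff[j] + k] = val;
        acc += val;
        kcum[koff[j] + k] = acc;
      }
      ktot[j] = acc;
      tail_hi[j] = 1.0 - prev;
    }
  }
  // dense operator pays off only when the kernel band fills most rows
  const bool use_gemm = noise > 0.0 && RR < 6 * band &&
    (double)RR * nb <= 8e7;
  std::vector<double> A;
  std::vector<double> tlo(nb, 0.0), thi(nb, 0.0);
  if (use_gemm) {
    A.assign((size_t)RR * nb, 0.0);
    for (int j = 0; j < nb; j++) {
      tlo[j] = tail_lo[j];
      thi[j] = tail_hi[j];
      for (int k = 0; k < klen[j]; k++) {
        long r = kstart[j] + k;
        double val = kval[koff[j] + k];
        if (r < R0) tlo[j] += val;
        else if (r >= R1) thi[j] += val;
        else A[(size_t)(r - R0) + (size_t)j * RR] += val;
      }
    }
  }
  std::vector<double> crule_centers(nb);
  for (int i = 0; i < nb; i++) crule_centers[i] = crule(center(i));

  // ---- phase 2: frame-major batched propagation ------------------------
  std::vector<double> G((size_t)nb * ng, 0.0);    // column per grid trial
  std::vector<double> TMP((size_t)RR * ng);
  std::vector<double> ap(ng, 0.0), am(ng, 0.0);
  std::vector<char> active(ng, 0), started(ng, 0);

  int fmin = F;
  for (int k = 0; k < ng; k++) if (gf0[k] < fmin) fmin = gf0[k];

  for (int f = fmin; f < F; f++) {
    // activate trials whose first unsafe frame is f
    for (int k = 0; k < ng; k++) {
      if (gf0[k] != f) continue;
      started[k] = 1; active[k] = 1;
      double *g = &G[(size_t)nb * k];
      double m = gm[k], v = gv[k];
      if (v <= 0.0) {
        double fi = (m + B) / h - 0.5;
        long i0 = (long)std::floor(fi);
        double w = fi - i0;
        long i1 = i0 + 1;
        if (i0 >= 0 && i0 < nb) g[i0] += 1.0 - w;
        else if (i0 < 0) am[k] += 1.0 - w; else ap[k] += 1.0 - w;
        if (i1 >= 0 && i1 < nb) g[i1] += w;
        else if (i1 < 0) am[k] += w; else ap[k] += w;
      } else {
        double sd = std::sqrt(v), prev = Phi((-B - m) / sd);
        am[k] += prev;
        for (int i = 0; i < nb; i++) {
          double cur = Phi(((-B + (i + 1) * h) - m) / sd);
          g[i] = cur - prev;
          prev = cur;
        }
        ap[k] += 1.0 - prev;
      }
    }
    // collect active columns contiguously for the matrix product
    std::vector<int> cols;
    cols.reserve(ng);
    for (int k = 0; k < ng; k++) if (active[k]) cols.push_back(k);
    int m = (int)cols.size();
    if (m == 0) {
      bool pending = false;
      for (int k = 0; k < ng; k++) if (gf0[k] > f) { pending = true; break; }
      if (!pending) break;
      continue;
    }
    if (noise <= 0.0) {
      // deterministic dynamics: contraction and LLO shift combined into a
      // single exact linear-interpolation deposit per trial (no blur)
      for (int c = 0; c < m; c++) {
        int k = cols[c];
        double *g = &G[(size_t)nb * k];
        double llo_f = llo(gtrial[k], f);
        std::vector<double> gn(nb, 0.0);
        for (int j = 0; j < nb; j++) {
          double gj = g[j];
          if (gj <= 0.0) continue;
          double mu = om * center(j) + llo_f;
          if (mu >= B) { ap[k] += gj; continue; }
          if (mu <= -B) { am[k] += gj; continue; }
          double fi = (mu + B) / h - 0.5;
          long i0 = (long)std::floor(fi);
          double w = fi - i0;
          if (i0 >= 0) gn[i0] += gj * (1.0 - w); else am[k] += gj * (1.0 - w);
          if (i0 + 1 < nb) gn[i0 + 1] += gj * w; else ap[k] += gj * w;
        }
        std::copy(gn.begin(), gn.end(), g);
        if (ap[k] + am[k] > 1.0 - 1e-9) active[k] = 0;
      }
      continue;
    }
    if (use_gemm) {
      std::vector<double> Gc((size_t)nb * m);
      for (int c = 0; c < m; c++)
        std::copy(&G[(size_t)nb * cols[c]], &G[(size_t)nb * (cols[c] + 1)],
                  &Gc[(size_t)nb * c]);
      {
        const double one = 1.0, zero = 0.0;
        F77_CALL(dgemm)("N", "N", &RR, &m, &nb, &one, A.data(), &RR,
                        Gc.data(), &nb, &zero, TMP.data(), &RR FCONE FCONE);
      }
      for (int c = 0; c < m; c++) {
        int k = cols[c];
        const double *g = &Gc[(size_t)nb * c];
        // shift-independent kernel tails
        double alo = 0.0, ahi = 0.0;
        for (int j = 0; j < nb; j++) {
          double gj = g[j];
          if (gj > 0.0) { alo += gj * tlo[j]; ahi += gj * thi[j]; }
        }
        // fractional shift by the true LLO: destination bin i receives
        // (1-w) * TMP[i - d] + w * TMP[i - d - 1]   (linear interpolation)
        double dr = llo(gtrial[k], f) / h;
        long d = (long)std::floor(dr);
        double w = dr - d;
        const double *tc = &TMP[(size_t)RR * c];
        double *gout = &G[(size_t)nb * k];
        std::fill(gout, gout + nb, 0.0);
        for (int pass = 0; pass < 2; pass++) {
          double wt = pass == 0 ? 1.0 - w : w;
          long dd = d + pass;
          if (wt <= 0.0) continue;
          long r_lo = std::max(R0, -dd);
          long r_hi = std::min(R1, (long)nb - dd);
          for (long r = R0; r < std::min(r_lo, R1); r++) alo += wt * tc[r - R0];
          for (long r = std::max(r_hi, R0); r < R1; r++) ahi += wt * tc[r - R0];
          for (long r = r_lo; r < r_hi; r++) gout[r + dd] += wt * tc[r - R0];
        }
        am[k] += alo; ap[k] += ahi;
        if (ap[k] + am[k] > 1.0 - 1e-9) active[k] = 0;  // residual <= 1e-9
      }
    } else {
      // narrow kernel: per-trial banded application with the fractional
      // shift folded into the deposit; out-of-grid tails via prefix sums
      std::vector<double> gn(nb);
      for (int c = 0; c < m; c++) {
        int k = cols[c];
        double *g = &G[(size_t)nb * k];
        double dr = llo(gtrial[k], f) / h;
        long d = (long)std::floor(dr);
        double w = dr - d;
        std::fill(gn.begin(), gn.end(), 0.0);
        double alo = 0.0, ahi = 0.0;
        for (int j = 0; j < nb; j++) {
          double gj = g[j];
          if (gj < 1e-13) continue;
          alo += gj * tail_lo[j];
          ahi += gj * tail_hi[j];
          const double *kv = &kval[koff[j]];
          const double *kc = &kcum[koff[j]];
          int L = klen[j];
          for (int pass = 0; pass < 2; pass++) {
            double wt = (pass == 0 ? 1.0 - w : w) * gj;
            if (wt <= 0.0) continue;
            long sjd = kstart[j] + d + pass;
            long lo_in = std::max(0L, -sjd);
            long hi_in = std::min((long)L, (long)nb - sjd);
            if (lo_in > 0) {
              long kk = std::min(lo_in, (long)L) - 1;
              alo += wt * kc[kk];
            }
            if (hi_in < L) {
              long kk = std::max(hi_in, 0L) - 1;
              ahi += wt * (ktot[j] - (kk >= 0 ? kc[kk] : 0.0));
            }
            if (hi_in > lo_in) {
              double *dst = &gn[sjd + lo_in];
              for (long kk = lo_in; kk < hi_in; kk++)
                dst[kk - lo_in] += wt * kv[kk];
            }
          }
        }
        std::copy(gn.begin(), gn.end(), g);
        am[k] += alo; ap[k] += ahi;
        if (ap[k] + am[k] > 1.0 - 1e-9) active[k] = 0;
      }
    }
  }

  for (int k = 0; k < ng; k++) {
    double p = ap[k] * crule_hi + am[k] * crule_lo;
    const double *g = &G[(size_t)nb * k];
    if (started[k])
      for (int i = 0; i < nb; i++)
        if (g[i] > 0.0) p += g[i] * crule_centers[i];
    out[gtrial[k]] = p;
  }
  return out;
}
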