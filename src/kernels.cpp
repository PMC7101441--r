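// Numerical kernels: per-voxel fourth-order tensor assembly and contraction,
// mask-aware finite-difference gradients, the local weak-form accumulation of
// the stiffness inversion, and the matrix-free wave-operator application used
// by the frequency-domain simulator.
//
// Conventions (fixed repo-wide):
//  * voxel linear index p = i + n1*(j + n2*k), 0-based, first axis fastest;
//  * 3x3 tensors stored column-major in 9 columns: col = i + 3*j for T_ij;
//  * (grad v)_ij = d v_i / d x_j;
//  * fourth-order tensors stored in 81 columns: col = i + 3*k + 9*m + 27*l
//    for H_ikml, contracting as (H:A)_ik = H_ikml A_ml.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void inv3(const double *a, double *ai) {
  // a, ai column-major 3x3
  double d = a[0] * (a[4] * a[8] - a[7] * a[5]) -
             a[3] * (a[1] * a[8] - a[7] * a[2]) +
             a[6] * (a[1] * a[5] - a[4] * a[2]);
  double id = 1.0 / d;
  ai[0] = (a[4] * a[8] - a[7] * a[5]) * id;
  ai[1] = -(a[1] * a[8] - a[7] * a[2]) * id;
  ai[2] = (a[1] * a[5] - a[4] * a[2]) * id;
  ai[3] = -(a[3] * a[8] - a[6] * a[5]) * id;
  ai[4] = (a[0] * a[8] - a[6] * a[2]) * id;
  ai[5] = -(a[0] * a[5] - a[3] * a[2]) * id;
  ai[6] = (a[3] * a[7] - a[6] * a[4]) * id;
  ai[7] = -(a[0] * a[7] - a[6] * a[1]) * id;
  ai[8] = (a[0] * a[4] - a[3] * a[1]) * id;
}

static inline double det3(const double *a) {
  return a[0] * (a[4] * a[8] - a[7] * a[5]) -
         a[3] * (a[1] * a[8] - a[7] * a[2]) +
         a[6] * (a[1] * a[5] - a[4] * a[2]);
}

// H'(F) per voxel. F: N x 9. Returns N x 81.
// [[Rcpp::export]]
NumericMatrix cpp_hprime_volume(NumericMatrix F) {
  const int N = F.nrow();
  NumericMatrix H(N, 81);
  // reference tensor at F = I: H_ikml = dik*dml*(-2/3) + dim*dkl + dkm*dil
  double H0[81];
  for (int l = 0; l < 3; ++l)
    for (int m = 0; m < 3; ++m)
      for (int k = 0; k < 3; ++k)
        for (int i = 0; i < 3; ++i)
          H0[i + 3 * k + 9 * m + 27 * l] =
              -(2.0 / 3.0) * (i == k) * (m == l) + (i == m) * (k == l) +
              (k == m) * (i == l);
  for (int v = 0; v < N; ++v) {
    double Fv[9];
    bool isI = true;
    for (int c = 0; c < 9; ++c) {
      Fv[c] = F(v, c);
      if (Fv[c] != ((c % 4 == 0) ? 1.0 : 0.0)) isI = false;
    }
    if (isI) {
      for (int c = 0; c < 81; ++c) H(v, c) = H0[c];
      continue;
    }
    double J = det3(Fv);
    double Fi[9], C[9], Ci[9];
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int q = 0; q < 3; ++q) s += Fv[q + 3 * i] * Fv[q + 3 * j];
        C[i + 3 * j] = s;
      }
    inv3(Fv, Fi);
    inv3(C, Ci);
    double IC = C[0] + C[4] + C[8];
    double J23 = std::pow(J, -2.0 / 3.0);
    // D_qjmn = J^{-2/3} ( -2/3 d_qj Fi_nm + 2/9 Fi_nm Ci_qj IC
    //                     - 2/3 F_mn Ci_qj + IC/3 (Fi_qm Ci_nj + Fi_jm Ci_qn) )
    double D[81]; // index q + 3j + 9m + 27n
    for (int n = 0; n < 3; ++n)
      for (int m = 0; m < 3; ++m) {
        double finm = Fi[n + 3 * m], fmn = Fv[m + 3 * n];
        for (int j = 0; j < 3; ++j)
          for (int q = 0; q < 3; ++q) {
            double val = -(2.0 / 3.0) * (q == j) * finm +
                         (2.0 / 9.0) * finm * Ci[q + 3 * j] * IC -
                         (2.0 / 3.0) * fmn * Ci[q + 3 * j] +
                         (IC / 3.0) * (Fi[q + 3 * m] * Ci[n + 3 * j] +
                                       Fi[j + 3 * m] * Ci[q + 3 * n]);
            D[q + 3 * j + 9 * m + 27 * n] = J23 * val;
          }
      }
    // S_hat = J^{-2/3} (I - IC/3 Ci); tau = F S Fhat^T
    double S[9];
    for (int c = 0; c < 9; ++c)
      S[c] = J23 * (((c % 4 == 0) ? 1.0 : 0.0) - IC / 3.0 * Ci[c]);
    double FS[9], tau[9];
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int q = 0; q < 3; ++q) s += Fv[i + 3 * q] * S[q + 3 * j];
        FS[i + 3 * j] = s;
      }
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int q = 0; q < 3; ++q) s += FS[i + 3 * q] * Fv[j + 3 * q];
        tau[i + 3 * j] = s;
      }
    // H_ikml = 1/J ( F_iq D_qjmn F_ln F_kj + d_im tau_lk )
    double iJ = 1.0 / J;
    for (int l = 0; l < 3; ++l)
      for (int m = 0; m < 3; ++m) {
        // M_qj = sum_n D_qjmn F_ln
        double M[9];
        for (int j = 0; j < 3; ++j)
          for (int q = 0; q < 3; ++q) {
            double s = 0;
            for (int n = 0; n < 3; ++n)
              s += D[q + 3 * j + 9 * m + 27 * n] * Fv[l + 3 * n];
            M[q + 3 * j] = s;
          }
        // T_ik = F_iq M_qj F_kj
        for (int k = 0; k < 3; ++k)
          for (int i = 0; i < 3; ++i) {
            double s = 0;
            for (int q = 0; q < 3; ++q) {
              double fm = 0;
              for (int j = 0; j < 3; ++j) fm += M[q + 3 * j] * Fv[k + 3 * j];
              s += Fv[i + 3 * q] * fm;
            }
            double val = s + ((i == m) ? tau[l + 3 * k] : 0.0);
            H(v, i + 3 * k + 9 * m + 27 * l) = iJ * val;
          }
      }
  }
  return H;
}

// Phi_ik = H_ikml A_ml, complex A. H: N x 81, A: N x 9 (re, im).
// [[Rcpp::export]]
List cpp_contract_hprime(NumericMatrix H, NumericMatrix Are, NumericMatrix Aim) {
  const int N = H.nrow();
  NumericMatrix Pre(N, 9), Pim(N, 9);
  for (int v = 0; v < N; ++v) {
    double ar[9], ai[9];
    for (int c = 0; c < 9; ++c) { ar[c] = Are(v, c); ai[c] = Aim(v, c); }
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < 3; ++i) {
        double sr = 0, si = 0;
        const int base = i + 3 * k;
        for (int l = 0; l < 3; ++l)
          for (int m = 0; m < 3; ++m) {
            double h = H(v, base + 9 * m + 27 * l);
            sr += h * ar[m + 3 * l];
            si += h * ai[m + 3 * l];
          }
        Pre(v, i + 3 * k) = sr;
        Pim(v, i + 3 * k) = si;
      }
  }
  return List::create(_["re"] = Pre, _["im"] = Pim);
}

// Mask-aware finite-difference gradient of a (complex) vector field.
// 4th-order central where a full 5-point mask-valid stencil exists, falling
// back to 2nd-order central, one-sided 2nd, then one-sided 1st order.
// u: N x 3 (re, im); mask: logical N; dims: (n1,n2,n3); spacing: per-axis
// step in the caller's length unit (gradient is per that unit).
// [[Rcpp::export]]
List cpp_field_gradient(NumericMatrix ure, NumericMatrix uim,
                        LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int N = n1 * n2 * n3;
  NumericMatrix gre(N, 9), gim(N, 9);
  LogicalVector valid(N);
  const int strides[3] = {1, n1, n1 * n2};
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int p = i + n1 * (j + n2 * k);
        if (!mask[p]) { valid[p] = false; continue; }
        bool ok = true;
        const int pos[3] = {i, j, k};
        const int nn[3] = {n1, n2, n3};
        for (int ax = 0; ax < 3 && ok; ++ax) {
          const int st = strides[ax];
          const double h = spacing[ax];
          bool av[5]; // offsets -2,-1,+1,+2 -> av[0],av[1],av[3],av[4]
          for (int o = -2; o <= 2; ++o) {
            if (o == 0) { av[2] = true; continue; }
            int q = pos[ax] + o;
            av[o + 2] = (q >= 0 && q < nn[ax]) ? (bool)mask[p + o * st] : false;
          }
          double w[5] = {0, 0, 0, 0, 0}; // stencil weights at -2..+2 (per h)
          if (av[0] && av[1] && av[3] && av[4]) {
            w[0] = 1.0 / 12; w[1] = -8.0 / 12; w[3] = 8.0 / 12; w[4] = -1.0 / 12;
          } else if (av[1] && av[3]) {
            w[1] = -0.5; w[3] = 0.5;
          } else if (av[3] && av[4]) {
            w[2] = -1.5; w[3] = 2.0; w[4] = -0.5;
          } else if (av[1] && av[0]) {
            w[2] = 1.5; w[1] = -2.0; w[0] = 0.5;
          } else if (av[3]) {
            w[2] = -1.0; w[3] = 1.0;
          } else if (av[1]) {
            w[2] = 1.0; w[1] = -1.0;
          } else {
            ok = false;
            break;
          }
          for (int c = 0; c < 3; ++c) {
            double sr = 0, si = 0;
            for (int o = -2; o <= 2; ++o) {
              double wt = w[o + 2];
              if (wt == 0.0) continue;
              int q = p + o * st;
              sr += wt * ure(q, c);
              si += wt * uim(q, c);
            }
            gre(p, c + 3 * ax) = sr / h;
            gim(p, c + 3 * ax) = si / h;
          }
        }
        valid[p] = ok;
        if (!ok)
          for (int c = 0; c < 9; ++c) { gre(p, c) = 0; gim(p, c) = 0; }
      }
  return List::create(_["re"] = gre, _["im"] = gim, _["valid"] = valid);
}

// Local weak-form accumulation: for every target voxel, window sums
//   a_t = sum_q sum_c v_c(x+q) Ka[c + 3t, q]
//   b_t = sum_q sum_p Phi_p(x+q) Kb[p + 9t, q]
// over the window offsets q (precomputed kernels include quadrature weights
// and test-function values/gradients). Window voxels that fall outside the
// grid or carry an invalid gradient contribute zero; the quadrature-weighted
// valid fraction is returned for window-quality control.
// [[Rcpp::export]]
List cpp_recon_accumulate(NumericMatrix vre, NumericMatrix vim,
                          NumericMatrix pre, NumericMatrix pim,
                          LogicalVector valid, IntegerVector dims,
                          IntegerVector targets, IntegerMatrix offs,
                          NumericMatrix KaT, NumericMatrix KbT,
                          NumericVector qw, int T) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int NT = targets.size(), NQ = offs.nrow();
  const int N = n1 * n2 * n3;
  NumericMatrix are(NT, T), aim(NT, T), bre(NT, T), bim(NT, T);
  NumericVector frac(NT);
  double qtot = 0;
  for (int q = 0; q < NQ; ++q) qtot += qw[q];
  // repack kernels with t fastest (SIMD-friendly inner loop) and keep only
  // the nonzero component rows of each kernel (w has 2 of 3, grad w 6 of 9)
  std::vector<int> acomp, bcomp;
  for (int c = 0; c < 3; ++c) {
    bool nz = false;
    for (int t = 0; t < T && !nz; ++t)
      for (int q = 0; q < NQ; ++q)
        if (KaT(c + 3 * t, q) != 0.0) { nz = true; break; }
    if (nz) acomp.push_back(c);
  }
  for (int c = 0; c < 9; ++c) {
    bool nz = false;
    for (int t = 0; t < T && !nz; ++t)
      for (int q = 0; q < NQ; ++q)
        if (KbT(c + 9 * t, q) != 0.0) { nz = true; break; }
    if (nz) bcomp.push_back(c);
  }
  const int nA = (int)acomp.size(), nB = (int)bcomp.size();
  std::vector<double> Kap((size_t)NQ * nA * T), Kbp((size_t)NQ * nB * T);
  for (int q = 0; q < NQ; ++q) {
    for (int a = 0; a < nA; ++a)
      for (int t = 0; t < T; ++t)
        Kap[((size_t)q * nA + a) * T + t] = KaT(acomp[a] + 3 * t, q);
    for (int b = 0; b < nB; ++b)
      for (int t = 0; t < T; ++t)
        Kbp[((size_t)q * nB + b) * T + t] = KbT(bcomp[b] + 9 * t, q);
  }
  std::vector<int> doff(NQ);
  for (int q = 0; q < NQ; ++q)
    doff[q] = offs(q, 0) + n1 * (offs(q, 1) + n2 * offs(q, 2));
  const double *Vre = &vre(0, 0), *Vim = &vim(0, 0);
  const double *Pre = &pre(0, 0), *Pim = &pim(0, 0);
  const int *val = LOGICAL(valid);
  int W1 = 0, W2 = 0, W3 = 0;
  for (int q = 0; q < NQ; ++q) {
    W1 = std::max(W1, std::abs(offs(q, 0)));
    W2 = std::max(W2, std::abs(offs(q, 1)));
    W3 = std::max(W3, std::abs(offs(q, 2)));
  }
  std::vector<double> Ar(T), Ai(T), Br(T), Bi(T);
  for (int s = 0; s < NT; ++s) {
    const int p0 = targets[s];
    const int i0 = p0 % n1, j0 = (p0 / n1) % n2, k0 = p0 / (n1 * n2);
    const bool interior = (i0 >= W1 && i0 < n1 - W1 && j0 >= W2 &&
                           j0 < n2 - W2 && k0 >= W3 && k0 < n3 - W3);
    double qok = 0;
    std::fill(Ar.begin(), Ar.end(), 0.0);
    std::fill(Ai.begin(), Ai.end(), 0.0);
    std::fill(Br.begin(), Br.end(), 0.0);
    std::fill(Bi.begin(), Bi.end(), 0.0);
    for (int q = 0; q < NQ; ++q) {
      int p;
      if (interior) {
        p = p0 + doff[q];
      } else {
        const int i = i0 + offs(q, 0), j = j0 + offs(q, 1), k = k0 + offs(q, 2);
        if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) continue;
        p = i + n1 * (j + n2 * k);
      }
      if (!val[p]) continue;
      qok += qw[q];
      const double *ka = &Kap[(size_t)q * nA * T];
      const double *kb = &Kbp[(size_t)q * nB * T];
      for (int a = 0; a < nA; ++a) {
        const double xr = Vre[p + (size_t)N * acomp[a]];
        const double xi = Vim[p + (size_t)N * acomp[a]];
        const double *kk = ka + (size_t)a * T;
        for (int t = 0; t < T; ++t) {
          Ar[t] += kk[t] * xr;
          Ai[t] += kk[t] * xi;
        }
      }
      for (int b = 0; b < nB; ++b) {
        const double xr = Pre[p + (size_t)N * bcomp[b]];
        const double xi = Pim[p + (size_t)N * bcomp[b]];
        const double *kk = kb + (size_t)b * T;
        for (int t = 0; t < T; ++t) {
          Br[t] += kk[t] * xr;
          Bi[t] += kk[t] * xi;
        }
      }
    }
    for (int t = 0; t < T; ++t) {
      are(s, t) = Ar[t]; aim(s, t) = Ai[t];
      bre(s, t) = Br[t]; bim(s, t) = Bi[t];
    }
    frac[s] = qok / qtot;
  }
  return List::create(_["are"] = are, _["aim"] = aim, _["bre"] = bre,
                      _["bim"] = bim, _["frac"] = frac);
}

// Matrix-free application of the discrete wave operator
//   A(v) = rho w^2 v + D.( g(x) * (H(x):Dv) ) + D( lam(x) * D.v )
// with 4th-order central differences on a periodic grid (the simulator uses
// periodic boundaries with an interior body-force source). g is the complex
// per-voxel stiffness coefficient (G* scaled down inside the void), lam the
// real incompressibility-penalty coefficient.
// [[Rcpp::export]]
List cpp_sim_matvec(NumericMatrix vre, NumericMatrix vim, NumericMatrix H,
                    NumericVector gre, NumericVector gim, NumericVector lam,
                    IntegerVector dims, NumericVector h, NumericVector rho_om2) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int N = n1 * n2 * n3;
  const int strides[3] = {1, n1, n1 * n2};
  const double c1 = 8.0 / 12.0, c2 = 1.0 / 12.0;
  // gradient of v (zero extension), then flux, then divergence
  NumericMatrix Fre(N, 9), Fim(N, 9); // flux g * (H:Dv)
  NumericVector divr(N), divi(N);      // lam * div v
  {
    std::vector<double> gr(9), gi(9);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          const int p = i + n1 * (j + n2 * k);
          const int pos[3] = {i, j, k};
          const int nn[3] = {n1, n2, n3};
          for (int ax = 0; ax < 3; ++ax) {
            const int st = strides[ax];
            const double ih = 1.0 / h[ax];
            const int wrap = nn[ax] * st;
            const int pp1 = p + ((pos[ax] + 1 < nn[ax]) ? st : st - wrap);
            const int pp2 = p + ((pos[ax] + 2 < nn[ax]) ? 2 * st : 2 * st - wrap);
            const int pm1 = p - ((pos[ax] - 1 >= 0) ? st : st - wrap);
            const int pm2 = p - ((pos[ax] - 2 >= 0) ? 2 * st : 2 * st - wrap);
            for (int c = 0; c < 3; ++c) {
              gr[c + 3 * ax] = (c1 * (vre(pp1, c) - vre(pm1, c)) -
                                c2 * (vre(pp2, c) - vre(pm2, c))) * ih;
              gi[c + 3 * ax] = (c1 * (vim(pp1, c) - vim(pm1, c)) -
                                c2 * (vim(pp2, c) - vim(pm2, c))) * ih;
            }
          }
          // Phi = H : grad v ; flux = g * Phi ; divv accumulation
          const double gvr = gre[p], gvi = gim[p];
          for (int kk = 0; kk < 3; ++kk)
            for (int ii = 0; ii < 3; ++ii) {
              double sr = 0, si = 0;
              const int base = ii + 3 * kk;
              for (int l = 0; l < 3; ++l)
                for (int m = 0; m < 3; ++m) {
                  const double hh = H(p, base + 9 * m + 27 * l);
                  sr += hh * gr[m + 3 * l];
                  si += hh * gi[m + 3 * l];
                }
              Fre(p, base) = gvr * sr - gvi * si;
              Fim(p, base) = gvr * si + gvi * sr;
            }
          double dr = gr[0] + gr[4] + gr[8], di = gi[0] + gi[4] + gi[8];
          divr[p] = lam[p] * dr;
          divi[p] = lam[p] * di;
        }
  }
  NumericMatrix outr(N, 3), outi(N, 3);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int p = i + n1 * (j + n2 * k);
        const int pos[3] = {i, j, k};
        const int nn[3] = {n1, n2, n3};
        double accr[3], acci[3];
        for (int c = 0; c < 3; ++c) {
          accr[c] = rho_om2[p] * vre(p, c);
          acci[c] = rho_om2[p] * vim(p, c);
        }
        for (int ax = 0; ax < 3; ++ax) {
          const int st = strides[ax];
          const double ih = 1.0 / h[ax];
          const int wrap = nn[ax] * st;
          const int pp1 = p + ((pos[ax] + 1 < nn[ax]) ? st : st - wrap);
          const int pp2 = p + ((pos[ax] + 2 < nn[ax]) ? 2 * st : 2 * st - wrap);
          const int pm1 = p - ((pos[ax] - 1 >= 0) ? st : st - wrap);
          const int pm2 = p - ((pos[ax] - 2 >= 0) ? 2 * st : 2 * st - wrap);
          for (int c = 0; c < 3; ++c) {
            const int fc = c + 3 * ax; // flux component (c, ax)
            accr[c] += (c1 * (Fre(pp1, fc) - Fre(pm1, fc)) -
                        c2 * (Fre(pp2, fc) - Fre(pm2, fc))) * ih;
            acci[c] += (c1 * (Fim(pp1, fc) - Fim(pm1, fc)) -
                        c2 * (Fim(pp2, fc) - Fim(pm2, fc))) * ih;
          }
          // + d/dx_ax ( lam div v ), contributes to component ax
          accr[ax] += (c1 * (divr[pp1] - divr[pm1]) -
                       c2 * (divr[pp2] - divr[pm2])) * ih;
          acci[ax] += (c1 * (divi[pp1] - divi[pm1]) -
                       c2 * (divi[pp2] - divi[pm2])) * ih;
        }
        for (int c = 0; c < 3; ++c) { outr(p, c) = accr[c]; outi(p, c) = acci[c]; }
      }
  return List::create(_["re"] = outr, _["im"] = outi);
}

// Mask-weighted separable-kernel smoothing of a scalar volume: out(p) =
// sum_q K(q) f(p+q) m(p+q) / sum_q K(q) m(p+q), with a dense 3D kernel of
// odd side; invalid (masked) voxels never bleed into valid ones.
// [[Rcpp::export]]
NumericVector cpp_masked_smooth(NumericVector f, LogicalVector mask,
                                IntegerVector dims, NumericVector kern,
                                IntegerVector ksize) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int h1 = ksize[0] / 2, h2 = ksize[1] / 2, h3 = ksize[2] / 2;
  NumericVector out(f.size());
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int p = i + n1 * (j + n2 * k);
        if (!mask[p]) { out[p] = f[p]; continue; }
        double num = 0, den = 0;
        int qi = 0;
        for (int dk = -h3; dk <= h3; ++dk)
          for (int dj = -h2; dj <= h2; ++dj)
            for (int di = -h1; di <= h1; ++di, ++qi) {
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
                continue;
              const int q = ii + n1 * (jj + n2 * kk);
              if (!mask[q]) continue;
              num += kern[qi] * f[q];
              den += kern[qi] * 1.0;
            }
        out[p] = (den > 0) ? num / den : f[p];
      }
  return out;
}
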