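// Gaussian AO integrals by the McMurchie-Davidson scheme.
// Shells are contracted Cartesian Gaussians; contraction coefficients are
// expected to already include primitive and contraction normalisation.
// Supported angular momenta: s, p, d (fixtures use s/p only).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(int mmax, double T, double *F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T > 35.0) {
    // upward recursion is stable at large T
    F[0] = 0.5 * std::sqrt(PI / T) * std::erf(std::sqrt(T));
    double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  // convergent series for F_mmax, then downward recursion (stable)
  double eT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0);
  double sum = term;
  for (int k = 1; k < 500; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = sum * eT;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// ------------------------------------------------- Hermite expansion E_t^{ij}
// Et(i,j,t) for the product of two 1D Cartesian Gaussians; index layout
// E[(i*(maxj+1)+j)*(maxi+maxj+1)+t].
struct Etab {
  int maxi, maxj;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (maxj + 1) + j) * (maxi + maxj + 1) + t];
  }
};

static Etab build_E(double a, double b, double A, double B, int maxi, int maxj) {
  Etab E;
  E.maxi = maxi; E.maxj = maxj;
  int tdim = maxi + maxj + 1;
  E.v.assign((size_t)(maxi + 1) * (maxj + 1) * tdim, 0.0);
  double p = a + b, mu = a * b / p;
  double Xab = A - B, Xpa = -b * Xab / p, Xpb = a * Xab / p;
  auto idx = [&](int i, int j, int t) { return (size_t)(i * (maxj + 1) + j) * tdim + t; };
  E.v[idx(0, 0, 0)] = std::exp(-mu * Xab * Xab);
  for (int i = 1; i <= maxi; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t > 0) val += E.v[idx(i - 1, 0, t - 1)] / (2.0 * p);
      val += Xpa * ((t <= i - 1) ? E.v[idx(i - 1, 0, t)] : 0.0);
      if (t + 1 <= i - 1) val += (t + 1.0) * E.v[idx(i - 1, 0, t + 1)];
      E.v[idx(i, 0, t)] = val;
    }
  for (int j = 1; j <= maxj; ++j)
    for (int i = 0; i <= maxi; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t > 0) val += E.v[idx(i, j - 1, t - 1)] / (2.0 * p);
        if (t <= i + j - 1) val += Xpb * E.v[idx(i, j - 1, t)];
        if (t + 1 <= i + j - 1) val += (t + 1.0) * E.v[idx(i, j - 1, t + 1)];
        E.v[idx(i, j, t)] = val;
      }
  return E;
}

// ----------------------------------------------- Hermite Coulomb R_{tuv}(p,PC)
static double Rtuv(int t, int u, int v, int n, double p,
                   double X, double Y, double Z, const double *F) {
  if (t == 0 && u == 0 && v == 0) {
    double r = F[n];
    for (int k = 0; k < n; ++k) r *= -2.0 * p;
    return r;
  }
  if (t > 0) {
    double r = X * Rtuv(t - 1, u, v, n + 1, p, X, Y, Z, F);
    if (t > 1) r += (t - 1.0) * Rtuv(t - 2, u, v, n + 1, p, X, Y, Z, F);
    return r;
  }
  if (u > 0) {
    double r = Y * Rtuv(t, u - 1, v, n + 1, p, X, Y, Z, F);
    if (u > 1) r += (u - 1.0) * Rtuv(t, u - 2, v, n + 1, p, X, Y, Z, F);
    return r;
  }
  double r = Z * Rtuv(t, u, v - 1, n + 1, p, X, Y, Z, F);
  if (v > 1) r += (v - 1.0) * Rtuv(t, u, v - 2, n + 1, p, X, Y, Z, F);
  return r;
}

// ---------------------------------------------------------------- shell model
struct Shell {
  int l;
  double A[3];
  std::vector<double> exps, coefs; // coefs include all normalisation
};

struct Cart { int lx, ly, lz; };

static std::vector<Cart> cart_components(int l) {
  std::vector<Cart> out;
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      out.push_back({lx, ly, l - lx - ly});
  return out;
}

static std::vector<Shell> parse_shells(const List &shells) {
  std::vector<Shell> out;
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    if (S.l > 2) stop("angular momenta above d are not supported");
    NumericVector A = sh["center"];
    S.A[0] = A[0]; S.A[1] = A[1]; S.A[2] = A[2];
    S.exps = as<std::vector<double>>(sh["exps"]);
    S.coefs = as<std::vector<double>>(sh["coefs"]);
    if (S.exps.size() != S.coefs.size()) stop("exps/coefs length mismatch");
    out.push_back(S);
  }
  return out;
}

static int n_ao_total(const std::vector<Shell> &sh) {
  int n = 0;
  for (const Shell &s : sh) n += (s.l + 1) * (s.l + 2) / 2;
  return n;
}

// overlap/kinetic for one shell pair; fills dense blocks
// 1D overlap with prefactor sqrt(pi/p) folded in at the end.
// [[Rcpp::export(name = ".cpp_ov_kin")]]
List cpp_ov_kin(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = n_ao_total(sh);
  NumericMatrix S(n, n), T(n, n);
  int off_i = 0;
  for (size_t si = 0; si < sh.size(); ++si) {
    const Shell &shi = sh[si];
    std::vector<Cart> ci = cart_components(shi.l);
    int off_j = 0;
    for (size_t sj = 0; sj < sh.size(); ++sj) {
      const Shell &shj = sh[sj];
      std::vector<Cart> cj = cart_components(shj.l);
      if (sj < si) { off_j += cj.size(); continue; }
      for (size_t pa = 0; pa < shi.exps.size(); ++pa)
        for (size_t pb = 0; pb < shj.exps.size(); ++pb) {
          double a = shi.exps[pa], b = shj.exps[pb];
          double p = a + b;
          double cc = shi.coefs[pa] * shj.coefs[pb];
          double pref = cc * std::pow(PI / p, 1.5);
          Etab Ex = build_E(a, b, shi.A[0], shj.A[0], shi.l, shj.l + 2);
          Etab Ey = build_E(a, b, shi.A[1], shj.A[1], shi.l, shj.l + 2);
          Etab Ez = build_E(a, b, shi.A[2], shj.A[2], shi.l, shj.l + 2);
          for (size_t ai = 0; ai < ci.size(); ++ai)
            for (size_t aj = 0; aj < cj.size(); ++aj) {
              int ix = ci[ai].lx, iy = ci[ai].ly, iz = ci[ai].lz;
              int jx = cj[aj].lx, jy = cj[aj].ly, jz = cj[aj].lz;
              double sx = Ex.at(ix, jx, 0), sy = Ey.at(iy, jy, 0), sz = Ez.at(iz, jz, 0);
              S(off_i + ai, off_j + aj) += pref * sx * sy * sz;
              // 1D kinetic: <i|-1/2 d2|j> in terms of overlaps with j-2, j, j+2
              auto kin1d = [&](const Etab &E, int i1, int j1) {
                double t = -2.0 * b * (2.0 * j1 + 1.0) * E.at(i1, j1, 0)
                           + 4.0 * b * b * E.at(i1, j1 + 2, 0);
                if (j1 >= 2) t += j1 * (j1 - 1.0) * E.at(i1, j1 - 2, 0);
                return -0.5 * t;
              };
              double tx = kin1d(Ex, ix, jx), ty = kin1d(Ey, iy, jy), tz = kin1d(Ez, iz, jz);
              T(off_i + ai, off_j + aj) +=
                pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
            }
        }
      off_j += cj.size();
    }
    off_i += ci.size();
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j) { S(i, j) = S(j, i); T(i, j) = T(j, i); }
  return List::create(_["S"] = S, _["T"] = T);
}

// <mu | 1/|r - C_k| | nu> for every centre k; positive-definite kernels.
// [[Rcpp::export(name = ".cpp_nuclear")]]
NumericVector cpp_nuclear(List shells, NumericMatrix centers) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = n_ao_total(sh), nc = centers.nrow();
  NumericVector out(Dimension(n, n, nc));
  double F[16];
  int off_i = 0;
  for (size_t si = 0; si < sh.size(); ++si) {
    const Shell &shi = sh[si];
    std::vector<Cart> ci = cart_components(shi.l);
    int off_j = 0;
    for (size_t sj = 0; sj < sh.size(); ++sj) {
      const Shell &shj = sh[sj];
      std::vector<Cart> cj = cart_components(shj.l);
      if (sj < si) { off_j += cj.size(); continue; }
      int L = shi.l + shj.l;
      for (size_t pa = 0; pa < shi.exps.size(); ++pa)
        for (size_t pb = 0; pb < shj.exps.size(); ++pb) {
          double a = shi.exps[pa], b = shj.exps[pb];
          double p = a + b;
          double cc = shi.coefs[pa] * shj.coefs[pb];
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * shi.A[d] + b * shj.A[d]) / p;
          Etab Ex = build_E(a, b, shi.A[0], shj.A[0], shi.l, shj.l);
          Etab Ey = build_E(a, b, shi.A[1], shj.A[1], shi.l, shj.l);
          Etab Ez = build_E(a, b, shi.A[2], shj.A[2], shi.l, shj.l);
          for (int k = 0; k < nc; ++k) {
            double X = P[0] - centers(k, 0), Y = P[1] - centers(k, 1),
                   Z = P[2] - centers(k, 2);
            double T2 = p * (X * X + Y * Y + Z * Z);
            boys(L, T2, F);
            for (size_t ai = 0; ai < ci.size(); ++ai)
              for (size_t aj = 0; aj < cj.size(); ++aj) {
                int ix = ci[ai].lx, iy = ci[ai].ly, iz = ci[ai].lz;
                int jx = cj[aj].lx, jy = cj[aj].ly, jz = cj[aj].lz;
                double val = 0.0;
                for (int t = 0; t <= ix + jx; ++t)
                  for (int u = 0; u <= iy + jy; ++u)
                    for (int v = 0; v <= iz + jz; ++v) {
                      double e = Ex.at(ix, jx, t) * Ey.at(iy, jy, u) * Ez.at(iz, jz, v);
                      if (e == 0.0) continue;
                      val += e * Rtuv(t, u, v, 0, p, X, Y, Z, F);
                    }
                out[(size_t)k * n * n + (size_t)(off_j + aj) * n + (off_i + ai)] +=
                  cc * (2.0 * PI / p) * val;
              }
          }
        }
      off_j += cj.size();
    }
    off_i += ci.size();
  }
  // symmetrise each slice
  for (int k = 0; k < nc; ++k)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < i; ++j) {
        // computed entries live at row <= col; mirror them to row > col
        size_t lower = (size_t)k * n * n + (size_t)j * n + i;
        size_t upper = (size_t)k * n * n + (size_t)i * n + j;
        out[lower] = out[upper];
      }
  return out;
}

// precomputed primitive-pair data for ERI shell pairs
struct PrimPair {
  double p, P[3], cc;
  Etab Ex, Ey, Ez;
};

static std::vector<PrimPair> pair_data(const Shell &sa, const Shell &sb) {
  std::vector<PrimPair> out;
  for (size_t i = 0; i < sa.exps.size(); ++i)
    for (size_t j = 0; j < sb.exps.size(); ++j) {
      PrimPair pp;
      double a = sa.exps[i], b = sb.exps[j];
      pp.p = a + b;
      pp.cc = sa.coefs[i] * sb.coefs[j];
      for (int d = 0; d < 3; ++d) pp.P[d] = (a * sa.A[d] + b * sb.A[d]) / pp.p;
      pp.Ex = build_E(a, b, sa.A[0], sb.A[0], sa.l, sb.l);
      pp.Ey = build_E(a, b, sa.A[1], sb.A[1], sa.l, sb.l);
      pp.Ez = build_E(a, b, sa.A[2], sb.A[2], sa.l, sb.l);
      out.push_back(pp);
    }
  return out;
}

// Full two-electron repulsion tensor (mu nu | la si), chemists' notation.
// [[Rcpp::export(name = ".cpp_eri")]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  int n = n_ao_total(sh);
  std::vector<int> off(nsh, 0);
  for (int s = 1; s < nsh; ++s) off[s] = off[s - 1] + (sh[s - 1].l + 1) * (sh[s - 1].l + 2) / 2;
  NumericVector out((R_xlen_t)n * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  double *o = REAL(out);
  double F[32];

  // all shell pairs (bra: a>=b ordering not needed, use full pair list a<=b)
  struct SP { int a, b; std::vector<PrimPair> pp; };
  std::vector<SP> pairs;
  for (int a = 0; a < nsh; ++a)
    for (int b = a; b < nsh; ++b) pairs.push_back({a, b, pair_data(sh[a], sh[b])});

  for (size_t ip = 0; ip < pairs.size(); ++ip) {
    const SP &AB = pairs[ip];
    const Shell &sa = sh[AB.a], &sb = sh[AB.b];
    std::vector<Cart> ca = cart_components(sa.l), cb = cart_components(sb.l);
    for (size_t jp = ip; jp < pairs.size(); ++jp) {
      const SP &CD = pairs[jp];
      const Shell &sc = sh[CD.a], &sd = sh[CD.b];
      std::vector<Cart> cc_ = cart_components(sc.l), cd = cart_components(sd.l);
      int L = sa.l + sb.l + sc.l + sd.l;
      size_t nab = ca.size() * cb.size(), ncd = cc_.size() * cd.size();
      std::vector<double> block(nab * ncd, 0.0);
      for (const PrimPair &pp1 : AB.pp)
        for (const PrimPair &pp2 : CD.pp) {
          double p = pp1.p, q = pp2.p;
          double alpha = p * q / (p + q);
          double X = pp1.P[0] - pp2.P[0], Y = pp1.P[1] - pp2.P[1], Z = pp1.P[2] - pp2.P[2];
          double T2 = alpha * (X * X + Y * Y + Z * Z);
          boys(L, T2, F);
          double pref = pp1.cc * pp2.cc * 2.0 * std::pow(PI, 2.5) /
                        (p * q * std::sqrt(p + q));
          size_t ij = 0;
          for (size_t ai = 0; ai < ca.size(); ++ai)
            for (size_t aj = 0; aj < cb.size(); ++aj, ++ij) {
              int ix = ca[ai].lx, iy = ca[ai].ly, iz = ca[ai].lz;
              int jx = cb[aj].lx, jy = cb[aj].ly, jz = cb[aj].lz;
              size_t kl = 0;
              for (size_t ak = 0; ak < cc_.size(); ++ak)
                for (size_t al = 0; al < cd.size(); ++al, ++kl) {
                  int kx = cc_[ak].lx, ky = cc_[ak].ly, kz = cc_[ak].lz;
                  int lx = cd[al].lx, ly = cd[al].ly, lz = cd[al].lz;
                  double val = 0.0;
                  for (int t = 0; t <= ix + jx; ++t)
                    for (int u = 0; u <= iy + jy; ++u)
                      for (int v = 0; v <= iz + jz; ++v) {
                        double e1 = pp1.Ex.at(ix, jx, t) * pp1.Ey.at(iy, jy, u) *
                                    pp1.Ez.at(iz, jz, v);
                        if (e1 == 0.0) continue;
                        for (int tt = 0; tt <= kx + lx; ++tt)
                          for (int uu = 0; uu <= ky + ly; ++uu)
                            for (int vv = 0; vv <= kz + lz; ++vv) {
                              double e2 = pp2.Ex.at(kx, lx, tt) * pp2.Ey.at(ky, ly, uu) *
                                          pp2.Ez.at(kz, lz, vv);
                              if (e2 == 0.0) continue;
                              double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                              val += e1 * sgn * e2 *
                                     Rtuv(t + tt, u + uu, v + vv, 0, alpha, X, Y, Z, F);
                            }
                      }
                  block[ij * ncd + kl] += pref * val;
                }
            }
        }
      // scatter with 8-fold symmetry
      size_t ij = 0;
      for (size_t ai = 0; ai < ca.size(); ++ai)
        for (size_t aj = 0; aj < cb.size(); ++aj, ++ij) {
          int mu = off[AB.a] + ai, nu = off[AB.b] + aj;
          size_t kl = 0;
          for (size_t ak = 0; ak < cc_.size(); ++ak)
            for (size_t al = 0; al < cd.size(); ++al, ++kl) {
              int la = off[CD.a] + ak, si = off[CD.b] + al;
              double v = block[ij * ncd + kl];
              size_t N = n;
              int m1[4] = {mu, nu, la, si};
              int perms[8][4] = {
                {m1[0], m1[1], m1[2], m1[3]}, {m1[1], m1[0], m1[2], m1[3]},
                {m1[0], m1[1], m1[3], m1[2]}, {m1[1], m1[0], m1[3], m1[2]},
                {m1[2], m1[3], m1[0], m1[1]}, {m1[3], m1[2], m1[0], m1[1]},
                {m1[2], m1[3], m1[1], m1[0]}, {m1[3], m1[2], m1[1], m1[0]}};
              for (int pi = 0; pi < 8; ++pi) {
                size_t idx = perms[pi][0] + N * (perms[pi][1] + N * (perms[pi][2] + N * perms[pi][3]));
                o[idx] = v;
              }
            }
        }
    }
  }
  return out;
}
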