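// Gaussian AO integrals over contracted Cartesian shells (s, p, d, ...)
// via McMurchie-Davidson Hermite expansions.  Dense output: this backend
// targets small molecules in small bases where the full ERI tensor fits
// comfortably in memory.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Boys function F_m(x) for m = 0..mmax, stable in both regimes.
static void boys(double x, int mmax, std::vector<double>& F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / x);
    double ex = std::exp(-x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
    return;
  }
  // convergent series for F_mmax, then downward recursion
  double num = 1.0, denom = 2.0 * mmax + 1.0, term = 1.0 / denom, sum = term;
  for (int k = 1; k < 200; ++k) {
    num *= 2.0 * x;
    denom *= 2.0 * mmax + 2.0 * k + 1.0;
    term = num / denom;
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  double ex = std::exp(-x);
  F[mmax] = ex * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// Hermite expansion coefficients E_t^{ij} for a primitive pair along one axis.
// E[(i,j,t)] indexed via helper; filled by the standard two-term recurrences.
struct Etab {
  int imax, jmax, tmax;
  std::vector<double> v;
  double& at(int i, int j, int t) { return v[(i * (jmax + 1) + j) * (tmax + 1) + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (tmax + 1) + t];
  }
};

static void build_E(int imax, int jmax, double a, double b, double AB, Etab& E) {
  double p = a + b, mu = a * b / p;
  E.imax = imax; E.jmax = jmax; E.tmax = imax + jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (E.tmax + 1), 0.0);
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  double PA = -b * AB / p;  // P - A with AB = A - B
  double PB = a * AB / p;   // wait: P = (aA+bB)/p; P-A = b(B-A)/p = -b*AB/p; P-B = a(A-B)/p = a*AB/p
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          val = E.get(i - 1, j, t - 1) / (2.0 * p)
              + PA * E.get(i - 1, j, t)
              + (t + 1) * E.get(i - 1, j, t + 1);
        } else {
          val = E.get(i, j - 1, t - 1) / (2.0 * p)
              + PB * E.get(i, j - 1, t)
              + (t + 1) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// Hermite Coulomb integrals R^0_{tuv} up to given total order.
struct Rtab {
  int n;
  std::vector<double> v;  // indexed [t][u][vv]
  double& at(int t, int u, int w) { return v[(t * (n + 1) + u) * (n + 1) + w]; }
  double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (n + 1) + u) * (n + 1) + w];
  }
};

static void build_R(double p, double X, double Y, double Z, int tmax, Rtab& R) {
  double r2 = X * X + Y * Y + Z * Z;
  std::vector<double> F;
  boys(p * r2, tmax, F);
  // R^n_{000} = (-2p)^n F_n
  // iterate order by order: store R^n tables, reduce n
  int N = tmax;
  R.n = N;
  std::vector<Rtab> tabs(N + 1);
  for (int n = 0; n <= N; ++n) {
    tabs[n].n = N;
    tabs[n].v.assign((N + 1) * (N + 1) * (N + 1), 0.0);
    tabs[n].at(0, 0, 0) = std::pow(-2.0 * p, n) * F[n];
  }
  for (int total = 1; total <= N; ++total) {
    for (int n = 0; n <= N - total; ++n) {
      for (int t = 0; t <= total; ++t)
        for (int u = 0; u <= total - t; ++u) {
          int w = total - t - u;
          double val;
          if (t > 0) {
            val = (t - 1) * tabs[n + 1].get(t - 2, u, w) + X * tabs[n + 1].get(t - 1, u, w);
          } else if (u > 0) {
            val = (u - 1) * tabs[n + 1].get(t, u - 2, w) + Y * tabs[n + 1].get(t, u - 1, w);
          } else {
            val = (w - 1) * tabs[n + 1].get(t, u, w - 2) + Z * tabs[n + 1].get(t, u, w - 1);
          }
          tabs[n].at(t, u, w) = val;
        }
    }
  }
  R.v = tabs[0].v;
}

// Cartesian component list for angular momentum l, ordered (x first):
// l=0: (0,0,0); l=1: (1,0,0),(0,1,0),(0,0,1); l=2: xx,xy,xz,yy,yz,zz ...
static void cart_components(int l, std::vector<std::array<int,3>>& comps) {
  comps.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comps.push_back({lx, ly, l - lx - ly});
}

struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> exps, coefs;  // coefs already primitive-normalized
  int nfun;                         // number of Cartesian components
  int offset;                       // index of first basis function
  std::vector<std::array<int,3>> comps;
};

static double dfact(int n) {  // (2n-1)!! with n>=0 -> product of odd numbers
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

// primitive normalization for Cartesian Gaussian x^i y^j z^k exp(-a r^2)
static double prim_norm(double a, int i, int j, int k) {
  int l = i + j + k;
  double pref = std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * l);
  return pref / std::sqrt(dfact(i) * dfact(j) * dfact(k));
}

// [[Rcpp::export]]
List cpp_ao_integrals(List shells_in, NumericMatrix atom_xyz, NumericVector atom_z) {
  int nsh = shells_in.size();
  std::vector<Shell> sh(nsh);
  int nbf = 0;
  for (int s = 0; s < nsh; ++s) {
    List L = shells_in[s];
    sh[s].l = as<int>(L["l"]);
    NumericVector c = L["center"];
    sh[s].cx = c[0]; sh[s].cy = c[1]; sh[s].cz = c[2];
    sh[s].exps = as<std::vector<double>>(L["exponents"]);
    sh[s].coefs = as<std::vector<double>>(L["coefficients"]);
    cart_components(sh[s].l, sh[s].comps);
    sh[s].nfun = sh[s].comps.size();
    sh[s].offset = nbf;
    nbf += sh[s].nfun;
  }
  NumericMatrix S(nbf, nbf), T(nbf, nbf), V(nbf, nbf);
  NumericVector eri((R_xlen_t)nbf * nbf * nbf * nbf);
  int natom = atom_xyz.nrow();

  // one-electron integrals
  for (int sa = 0; sa < nsh; ++sa) {
    for (int sb = 0; sb <= sa; ++sb) {
      const Shell &A = sh[sa], &B = sh[sb];
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      int la = A.l, lb = B.l;
      for (size_t pa = 0; pa < A.exps.size(); ++pa) {
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb];
          double p = a + b;
          double cc = A.coefs[pa] * B.coefs[pb];
          Etab Ex, Ey, Ez;
          build_E(la + 2, lb + 2, a, b, ABx, Ex);
          build_E(la + 2, lb + 2, a, b, ABy, Ey);
          build_E(la + 2, lb + 2, a, b, ABz, Ez);
          double Px = (a * A.cx + b * B.cx) / p;
          double Py = (a * A.cy + b * B.cy) / p;
          double Pz = (a * A.cz + b * B.cz) / p;
          double sfac = std::pow(PI / p, 1.5);
          for (int fa = 0; fa < A.nfun; ++fa) {
            for (int fb = 0; fb < B.nfun; ++fb) {
              int i1 = A.comps[fa][0], j1 = A.comps[fa][1], k1 = A.comps[fa][2];
              int i2 = B.comps[fb][0], j2 = B.comps[fb][1], k2 = B.comps[fb][2];
              double sx = Ex.get(i1, i2, 0), sy = Ey.get(j1, j2, 0), sz = Ez.get(k1, k2, 0);
              double sval = sfac * sx * sy * sz;
              // kinetic: 1-d pieces T_ij = -2b^2 S_{i,j+2} + b(2j+1) S_{ij} - j(j-1)/2 S_{i,j-2}
              auto tx = [&](Etab& E, int i, int j) {
                double t = -2.0 * b * b * E.get(i, j + 2, 0)
                         + b * (2.0 * j + 1.0) * E.get(i, j, 0);
                if (j >= 2) t -= 0.5 * j * (j - 1.0) * E.get(i, j - 2, 0);
                return t;
              };
              double txv = tx(Ex, i1, i2), tyv = tx(Ey, j1, j2), tzv = tx(Ez, k1, k2);
              double tval = sfac * (txv * sy * sz + sx * tyv * sz + sx * sy * tzv);
              // nuclear attraction
              double vval = 0.0;
              int tmax = la + lb;
              for (int at = 0; at < natom; ++at) {
                Rtab R;
                build_R(p, Px - atom_xyz(at, 0), Py - atom_xyz(at, 1),
                        Pz - atom_xyz(at, 2), tmax, R);
                double acc = 0.0;
                for (int t = 0; t <= i1 + i2; ++t)
                  for (int u = 0; u <= j1 + j2; ++u)
                    for (int w = 0; w <= k1 + k2; ++w)
                      acc += Ex.get(i1, i2, t) * Ey.get(j1, j2, u) * Ez.get(k1, k2, w)
                             * R.get(t, u, w);
                vval -= atom_z[at] * (2.0 * PI / p) * acc;
              }
              int ia = A.offset + fa, ib = B.offset + fb;
              S(ia, ib) += cc * sval;
              T(ia, ib) += cc * tval;
              V(ia, ib) += cc * vval;
            }
          }
        }
      }
    }
  }
  for (int i = 0; i < nbf; ++i)
    for (int j = 0; j < i; ++j) {
      S(j, i) = S(i, j); T(j, i) = T(i, j); V(j, i) = V(i, j);
    }

  // two-electron integrals, chemist notation (ab|cd); loop unique shell quartets
  for (int sa = 0; sa < nsh; ++sa)
  for (int sb = 0; sb <= sa; ++sb)
  for (int sc = 0; sc <= sa; ++sc)
  for (int sd = 0; sd <= (sc == sa ? sb : sc); ++sd) {
    const Shell &A = sh[sa], &B = sh[sb], &C = sh[sc], &D = sh[sd];
    int la = A.l, lb = B.l, lc = C.l, ld = D.l;
    int n1 = A.nfun * B.nfun * C.nfun * D.nfun;
    std::vector<double> block(n1, 0.0);
    for (size_t pa = 0; pa < A.exps.size(); ++pa)
    for (size_t pb = 0; pb < B.exps.size(); ++pb) {
      double a = A.exps[pa], b = B.exps[pb], p = a + b;
      double Px = (a * A.cx + b * B.cx) / p;
      double Py = (a * A.cy + b * B.cy) / p;
      double Pz = (a * A.cz + b * B.cz) / p;
      Etab E1x, E1y, E1z;
      build_E(la, lb, a, b, A.cx - B.cx, E1x);
      build_E(la, lb, a, b, A.cy - B.cy, E1y);
      build_E(la, lb, a, b, A.cz - B.cz, E1z);
      double cab = A.coefs[pa] * B.coefs[pb];
      for (size_t pc = 0; pc < C.exps.size(); ++pc)
      for (size_t pd = 0; pd < D.exps.size(); ++pd) {
        double c = C.exps[pc], d = D.exps[pd], q = c + d;
        double Qx = (c * C.cx + d * D.cx) / q;
        double Qy = (c * C.cy + d * D.cy) / q;
        double Qz = (c * C.cz + d * D.cz) / q;
        Etab E2x, E2y, E2z;
        build_E(lc, ld, c, d, C.cx - D.cx, E2x);
        build_E(lc, ld, c, d, C.cy - D.cy, E2y);
        build_E(lc, ld, c, d, C.cz - D.cz, E2z);
        double alpha = p * q / (p + q);
        int tmax = la + lb + lc + ld;
        Rtab R;
        build_R(alpha, Px - Qx, Py - Qy, Pz - Qz, tmax, R);
        double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
        double ccc = cab * C.coefs[pc] * D.coefs[pd];
        int idx = 0;
        for (int fa = 0; fa < A.nfun; ++fa)
        for (int fb = 0; fb < B.nfun; ++fb)
        for (int fc = 0; fc < C.nfun; ++fc)
        for (int fd = 0; fd < D.nfun; ++fd, ++idx) {
          int i1 = A.comps[fa][0], j1 = A.comps[fa][1], k1 = A.comps[fa][2];
          int i2 = B.comps[fb][0], j2 = B.comps[fb][1], k2 = B.comps[fb][2];
          int i3 = C.comps[fc][0], j3 = C.comps[fc][1], k3 = C.comps[fc][2];
          int i4 = D.comps[fd][0], j4 = D.comps[fd][1], k4 = D.comps[fd][2];
          double acc = 0.0;
          for (int t = 0; t <= i1 + i2; ++t)
          for (int u = 0; u <= j1 + j2; ++u)
          for (int w = 0; w <= k1 + k2; ++w) {
            double e1 = E1x.get(i1, i2, t) * E1y.get(j1, j2, u) * E1z.get(k1, k2, w);
            if (e1 == 0.0) continue;
            for (int tt = 0; tt <= i3 + i4; ++tt)
            for (int uu = 0; uu <= j3 + j4; ++uu)
            for (int ww = 0; ww <= k3 + k4; ++ww) {
              double e2 = E2x.get(i3, i4, tt) * E2y.get(j3, j4, uu) * E2z.get(k3, k4, ww);
              if (e2 == 0.0) continue;
              double sign = ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
              acc += e1 * e2 * sign * R.get(t + tt, u + uu, w + ww);
            }
          }
          block[idx] += ccc * pref * acc;
        }
      }
    }
    // scatter block with 8-fold permutational symmetry
    int idx = 0;
    for (int fa = 0; fa < A.nfun; ++fa)
    for (int fb = 0; fb < B.nfun; ++fb)
    for (int fc = 0; fc < C.nfun; ++fc)
    for (int fd = 0; fd < D.nfun; ++fd, ++idx) {
      int i = A.offset + fa, j = B.offset + fb, k = C.offset + fc, l = D.offset + fd;
      double v = block[idx];
      auto set = [&](int a1, int b1, int c1, int d1) {
        eri[((d1 * nbf + c1) * nbf + b1) * nbf + a1] = v;  // column-major [a,b,c,d]
      };
      set(i, j, k, l); set(j, i, k, l); set(i, j, l, k); set(j, i, l, k);
      set(k, l, i, j); set(l, k, i, j); set(k, l, j, i); set(l, k, j, i);
    }
  }

  // nuclear repulsion
  double enuc = 0.0;
  for (int i = 0; i < natom; ++i)
    for (int j = 0; j < i; ++j) {
      double dx = atom_xyz(i, 0) - atom_xyz(j, 0);
      double dy = atom_xyz(i, 1) - atom_xyz(j, 1);
      double dz = atom_xyz(i, 2) - atom_xyz(j, 2);
      enuc += atom_z[i] * atom_z[j] / std::sqrt(dx * dx + dy * dy + dz * dz);
    }

  return List::create(_["overlap"] = S, _["kinetic"] = T, _["nuclear"] = V,
                      _["eri"] = eri, _["nuclear_repulsion"] = enuc,
                      _["n_ao"] = nbf);
}

// [[Rcpp::export]]
NumericVector cpp_prim_norms(NumericVector exps, int l) {
  // normalization constants for the first Cartesian component (x^l)
  int n = exps.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = prim_norm(exps[i], l, 0, 0);
  return out;
}
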