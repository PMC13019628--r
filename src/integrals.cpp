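// McMurchie-Davidson Gaussian integral engine.
//
// All two-electron kernels are reduced to an auxiliary function array
// Fm(T) entering the Hermite recursion R^n_{000} = (-2*alpha)^n Fm(T),
// with alpha = p*q/(p+q) and T = alpha*|P-Q|^2:
//   coulomb : Fm = Boys_m(T)
//   gauss   : kernel exp(-z u^2),   Fm = (1-a)^m * sqrt(pi)/(2 sqrt(alpha))
//             * a^{3/2} * exp(-(1-a) T),          a = alpha/(alpha+z)
//   gauss_r : kernel exp(-z u^2)/u, Fm = a * exp(-(1-a) T) *
//             sum_k C(m,k) (1-a)^{m-k} a^k Boys_k(a T)
// The gauss/gauss_r forms follow from the integral representation
// 1/u = 2/sqrt(pi) * int_0^inf exp(-u^2 s^2) ds and are verified against
// numerical quadrature in the test suite.  Linear combinations of such
// kernels (Gaussian expansions of Slater geminals) are summed in place.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys
static void boys_array(double T, int mmax, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T <= 30.0) {
    // series at mmax, downward recursion
    double num = 1.0, den = 2.0 * mmax + 1.0, term = 1.0 / den, sum = term;
    for (int k = 1; k < 300; ++k) {
      num *= 2.0 * T;
      den *= (2.0 * mmax + 2.0 * k + 1.0);
      term = num / den;
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double eT = std::exp(-T);
    F[mmax] = eT * sum;
    for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
  } else {
    double eT = std::exp(-T);
    F[0] = 0.5 * std::sqrt(PI / T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
  }
}

// kernel types
enum KernelType { K_COULOMB = 0, K_GAUSS = 1, K_GAUSS_R = 2 };

// Fm array for a (possibly contracted) kernel; pref = 2 pi^{5/2}/(p q sqrt(p+q))
// applied by caller.
static void kernel_fm(int type, double alpha, double T, int mmax,
                      const std::vector<double>& zetas,
                      const std::vector<double>& coefs, double* F) {
  if (type == K_COULOMB) {
    boys_array(T, mmax, F);
    return;
  }
  for (int m = 0; m <= mmax; ++m) F[m] = 0.0;
  std::vector<double> Fb(mmax + 1);
  const size_t ng = zetas.size();
  if (type == K_GAUSS) {
    for (size_t g = 0; g < ng; ++g) {
      double a = alpha / (alpha + zetas[g]);
      double base = coefs[g] * 0.5 * std::sqrt(PI / alpha) * a * std::sqrt(a) *
                    std::exp(-(1.0 - a) * T);
      double fac = 1.0;
      for (int m = 0; m <= mmax; ++m) { F[m] += base * fac; fac *= (1.0 - a); }
    }
  } else { // K_GAUSS_R
    for (size_t g = 0; g < ng; ++g) {
      double a = alpha / (alpha + zetas[g]);
      boys_array(a * T, mmax, Fb.data());
      double eb = coefs[g] * a * std::exp(-(1.0 - a) * T);
      for (int m = 0; m <= mmax; ++m) {
        // binomial sum over Boys orders
        double s = 0.0, binom = 1.0;
        for (int k = 0; k <= m; ++k) {
          double w = binom * std::pow(1.0 - a, m - k) * std::pow(a, k);
          s += w * Fb[k];
          binom = binom * (m - k) / (k + 1.0);
        }
        F[m] += eb * s;
      }
    }
  }
}

// ------------------------------------------------------ Hermite E coefficients
// E[t + (MAXT+1)*(i + (li+1)*j)] layout, per direction.
struct EArr {
  int li, lj, nt;
  std::vector<double> v; // (li+1)*(lj+1)*(li+lj+1)
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)t + (size_t)nt * (i + (li + 1) * j)];
  }
};

static void build_E(EArr& E, int li, int lj, double a, double b, double AB) {
  E.li = li; E.lj = lj; E.nt = li + lj + 1;
  E.v.assign((size_t)(li + 1) * (lj + 1) * (li + lj + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double XPA = -b * AB / p; // P - A with AB = A - B => P = (aA+bB)/p; P-A = -b(A-B)/p
  double XPB = a * AB / p;  // P - B =  a(A-B)/p
  // base
  E.v[0] = std::exp(-mu * AB * AB);
  // increase i then j
  auto idx = [&](int i, int j, int t) { return (size_t)t + (size_t)E.nt * (i + (li + 1) * j); };
  for (int i = 0; i <= li; ++i) {
    for (int j = 0; j <= lj; ++j) {
      if (i == 0 && j == 0) continue;
      if (j == 0) {
        for (int t = 0; t <= i + j; ++t) {
          double val = 0.0;
          if (t - 1 >= 0) val += E.at(i - 1, 0, t - 1) / (2.0 * p);
          val += XPA * E.at(i - 1, 0, t);
          val += (t + 1.0) * E.at(i - 1, 0, t + 1);
          E.v[idx(i, 0, t)] = val;
        }
      } else {
        for (int t = 0; t <= i + j; ++t) {
          double val = 0.0;
          if (t - 1 >= 0) val += E.at(i, j - 1, t - 1) / (2.0 * p);
          val += XPB * E.at(i, j - 1, t);
          val += (t + 1.0) * E.at(i, j - 1, t + 1);
          E.v[idx(i, j, t)] = val;
        }
      }
    }
  }
}

// ------------------------------------------------------ Hermite R integrals
// R_{tuv} = R^0_{tuv}; dense table over 0..Lt etc., built by recursion.
static void build_R(int Lt, int Lu, int Lv, double alpha,
                    double X, double Y, double Z, const double* F, double* R) {
  // R indexed [t][u][v]; helper with order n folded via auxiliary buffer
  int L = Lt + Lu + Lv;
  int nt = Lt + 1, nu = Lu + 1, nv = Lv + 1;
  std::vector<double> buf((size_t)(L + 1) * nt * nu * nv, 0.0);
  auto at = [&](int n, int t, int u, int v) -> double& {
    return buf[(((size_t)n * nt + t) * nu + u) * nv + v];
  };
  for (int n = 0; n <= L; ++n) {
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * alpha;
    at(n, 0, 0, 0) = f * F[n];
  }
  for (int t = 0; t <= Lt; ++t)
    for (int u = 0; u <= Lu; ++u)
      for (int v = 0; v <= Lv; ++v) {
        if (t + u + v == 0) continue;
        int rem = L - (t + u + v);
        for (int n = 0; n <= rem; ++n) {
          double val;
          if (t > 0) {
            val = X * at(n + 1, t - 1, u, v);
            if (t > 1) val += (t - 1) * at(n + 1, t - 2, u, v);
          } else if (u > 0) {
            val = Y * at(n + 1, t, u - 1, v);
            if (u > 1) val += (u - 1) * at(n + 1, t, u - 2, v);
          } else {
            val = Z * at(n + 1, t, u, v - 1);
            if (v > 1) val += (v - 1) * at(n + 1, t, u, v - 2);
          }
          at(n, t, u, v) = val;
        }
      }
  for (int t = 0; t <= Lt; ++t)
    for (int u = 0; u <= Lu; ++u)
      for (int v = 0; v <= Lv; ++v)
        R[((size_t)t * nu + u) * nv + v] = at(0, t, u, v);
}

// ------------------------------------------------------------ AO basis holder
struct AO {
  int l[3];
  double A[3];
  std::vector<double> ex, cf;
  int ltot() const { return l[0] + l[1] + l[2]; }
};

static std::vector<AO> parse_aos(const List& basis) {
  IntegerMatrix lmat = basis["l"];
  NumericMatrix cen = basis["center"];
  List exps = basis["exps"], coefs = basis["coefs"];
  int n = lmat.nrow();
  std::vector<AO> aos(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) { aos[i].l[d] = lmat(i, d); aos[i].A[d] = cen(i, d); }
    NumericVector e = exps[i], c = coefs[i];
    aos[i].ex.assign(e.begin(), e.end());
    aos[i].cf.assign(c.begin(), c.end());
  }
  return aos;
}

// precomputed primitive-pair data for a list of AO pairs
struct PrimPair {
  double p;          // a + b
  double P[3];       // gaussian product center
  double coef;       // c_a * c_b (E base factors folded in E arrays)
  EArr E[3];
};
struct AOPair {
  int i, j;
  std::vector<PrimPair> pp;
  int L;             // total angular momentum of the pair
  double schwarz;    // sqrt((ij|ij)) for the active kernel
};

static void build_pairs(const std::vector<AO>& A, const std::vector<AO>& B,
                        bool same, std::vector<AOPair>& pairs) {
  size_t nA = A.size(), nB = B.size();
  pairs.clear();
  for (size_t i = 0; i < nA; ++i) {
    size_t j0 = same ? i : 0;
    for (size_t j = j0; j < nB; ++j) {
      AOPair pr; pr.i = (int)i; pr.j = (int)j; pr.schwarz = 1.0;
      pr.L = A[i].ltot() + B[j].ltot();
      for (size_t pa = 0; pa < A[i].ex.size(); ++pa)
        for (size_t pb = 0; pb < B[j].ex.size(); ++pb) {
          PrimPair q;
          double a = A[i].ex[pa], b = B[j].ex[pb];
          q.p = a + b;
          q.coef = A[i].cf[pa] * B[j].cf[pb];
          for (int d = 0; d < 3; ++d) {
            q.P[d] = (a * A[i].A[d] + b * B[j].A[d]) / q.p;
            build_E(q.E[d], A[i].l[d], B[j].l[d], a, b, A[i].A[d] - B[j].A[d]);
          }
          // screen negligible primitive pairs by their E base product
          double base = q.E[0].at(0, 0, 0) * q.E[1].at(0, 0, 0) * q.E[2].at(0, 0, 0);
          if (std::fabs(base * q.coef) > 1e-16) pr.pp.push_back(q);
        }
      if (!pr.pp.empty()) pairs.push_back(pr);
    }
  }
}

// contract one pair-pair combination for a kernel; returns scalar integral
static double pair_pair_integral(const AOPair& bra, const std::vector<AO>& Abra,
                                 const std::vector<AO>& Bbra,
                                 const AOPair& ket, const std::vector<AO>& Aket,
                                 const std::vector<AO>& Bket,
                                 int ktype, const std::vector<double>& zetas,
                                 const std::vector<double>& coefs) {
  const AO& a1 = Abra[bra.i]; const AO& a2 = Bbra[bra.j];
  const AO& a3 = Aket[ket.i]; const AO& a4 = Bket[ket.j];
  int Lt = a1.l[0] + a2.l[0] + a3.l[0] + a4.l[0];
  int Lu = a1.l[1] + a2.l[1] + a3.l[1] + a4.l[1];
  int Lv = a1.l[2] + a2.l[2] + a3.l[2] + a4.l[2];
  int L = Lt + Lu + Lv;
  std::vector<double> F(L + 1), R((size_t)(Lt + 1) * (Lu + 1) * (Lv + 1));
  double out = 0.0;
  for (const PrimPair& pb : bra.pp) {
    for (const PrimPair& pk : ket.pp) {
      double p = pb.p, q = pk.p;
      double alpha = p * q / (p + q);
      double X = pb.P[0] - pk.P[0], Y = pb.P[1] - pk.P[1], Z = pb.P[2] - pk.P[2];
      double T = alpha * (X * X + Y * Y + Z * Z);
      kernel_fm(ktype, alpha, T, L, zetas, coefs, F.data());
      double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q)) *
                    pb.coef * pk.coef;
      build_R(Lt, Lu, Lv, alpha, X, Y, Z, F.data(), R.data());
      int nu = Lu + 1, nv = Lv + 1;
      double s = 0.0;
      int lbx = a1.l[0] + a2.l[0], lby = a1.l[1] + a2.l[1], lbz = a1.l[2] + a2.l[2];
      int lkx = a3.l[0] + a4.l[0], lky = a3.l[1] + a4.l[1], lkz = a3.l[2] + a4.l[2];
      for (int t = 0; t <= lbx; ++t) {
        double Ebx = pb.E[0].at(a1.l[0], a2.l[0], t); if (Ebx == 0.0) continue;
        for (int u = 0; u <= lby; ++u) {
          double Eby = pb.E[1].at(a1.l[1], a2.l[1], u); if (Eby == 0.0) continue;
          for (int v = 0; v <= lbz; ++v) {
            double Ebz = pb.E[2].at(a1.l[2], a2.l[2], v); if (Ebz == 0.0) continue;
            double Eb = Ebx * Eby * Ebz;
            for (int tt = 0; tt <= lkx; ++tt) {
              double Ekx = pk.E[0].at(a3.l[0], a4.l[0], tt); if (Ekx == 0.0) continue;
              double sgx = (tt % 2) ? -1.0 : 1.0;
              for (int uu = 0; uu <= lky; ++uu) {
                double Eky = pk.E[1].at(a3.l[1], a4.l[1], uu); if (Eky == 0.0) continue;
                double sgy = (uu % 2) ? -1.0 : 1.0;
                for (int vv = 0; vv <= lkz; ++vv) {
                  double Ekz = pk.E[2].at(a3.l[2], a4.l[2], vv); if (Ekz == 0.0) continue;
                  double sgz = (vv % 2) ? -1.0 : 1.0;
                  s += Eb * Ekx * Eky * Ekz * sgx * sgy * sgz *
                       R[((size_t)(t + tt) * nu + (u + uu)) * nv + (v + vv)];
                }
              }
            }
          }
        }
      }
      out += pref * s;
    }
  }
  return out;
}

static std::vector<double> to_vec(NumericVector x) {
  return std::vector<double>(x.begin(), x.end());
}

// Schwarz factors sqrt(|(ij|ij)|) for each pair
static void schwarz_fill(std::vector<AOPair>& pairs, const std::vector<AO>& A,
                         const std::vector<AO>& B, int ktype,
                         const std::vector<double>& zetas,
                         const std::vector<double>& coefs) {
  for (AOPair& pr : pairs) {
    double d = pair_pair_integral(pr, A, B, pr, A, B, ktype, zetas, coefs);
    pr.schwarz = std::sqrt(std::fabs(d));
  }
}

// ------------------------------------------------------------- exported API

// [[Rcpp::export(name = ".cpp_two_center")]]
NumericMatrix cpp_two_center(List basP, List basQ, int ktype,
                             NumericVector zetas, NumericVector coefs) {
  std::vector<AO> P = parse_aos(basP), Q = parse_aos(basQ);
  // dummy s partner for one-function "pairs"
  std::vector<AO> dumP(P.size()), dumQ(Q.size());
  for (size_t i = 0; i < P.size(); ++i) {
    AO d; d.l[0] = d.l[1] = d.l[2] = 0;
    for (int k = 0; k < 3; ++k) d.A[k] = P[i].A[k];
    d.ex.assign(1, 0.0); d.cf.assign(1, 1.0); dumP[i] = d;
  }
  for (size_t i = 0; i < Q.size(); ++i) {
    AO d; d.l[0] = d.l[1] = d.l[2] = 0;
    for (int k = 0; k < 3; ++k) d.A[k] = Q[i].A[k];
    d.ex.assign(1, 0.0); d.cf.assign(1, 1.0); dumQ[i] = d;
  }
  std::vector<double> zv = to_vec(zetas), cv = to_vec(coefs);
  NumericMatrix out(P.size(), Q.size());
  // build singleton "pairs"
  for (size_t i = 0; i < P.size(); ++i) {
    std::vector<AO> ai(1, P[i]), di(1, dumP[i]);
    std::vector<AOPair> bp; build_pairs(ai, di, false, bp);
    for (size_t j = 0; j < Q.size(); ++j) {
      std::vector<AO> aj(1, Q[j]), dj(1, dumQ[j]);
      std::vector<AOPair> kp; build_pairs(aj, dj, false, kp);
      out(i, j) = pair_pair_integral(bp[0], ai, di, kp[0], aj, dj, ktype, zv, cv);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_three_center")]]
NumericVector cpp_three_center(List basA, List basB, List basP, int ktype,
                               NumericVector zetas, NumericVector coefs,
                               double screen) {
  std::vector<AO> A = parse_aos(basA), B = parse_aos(basB), P = parse_aos(basP);
  bool same = (basA.inherits("lmf12_same") || false);
  (void)same;
  std::vector<AO> dumP(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    AO d; d.l[0] = d.l[1] = d.l[2] = 0;
    for (int k = 0; k < 3; ++k) d.A[k] = P[i].A[k];
    d.ex.assign(1, 0.0); d.cf.assign(1, 1.0); dumP[i] = d;
  }
  std::vector<double> zv = to_vec(zetas), cv = to_vec(coefs);
  std::vector<AOPair> bra; build_pairs(A, B, false, bra);
  schwarz_fill(bra, A, B, ktype, zv, cv);
  // aux singleton pairs
  std::vector<AOPair> aux;
  {
    std::vector<AOPair> tmp;
    for (size_t j = 0; j < P.size(); ++j) {
      std::vector<AO> aj(1, P[j]), dj(1, dumP[j]);
      std::vector<AOPair> kp; build_pairs(aj, dj, false, kp);
      kp[0].i = (int)j;
      aux.push_back(kp[0]);
    }
    (void)tmp;
  }
  // schwarz for aux
  std::vector<double> auxs(P.size());
  for (size_t j = 0; j < P.size(); ++j) {
    std::vector<AO> aj(1, P[j]), dj(1, dumP[j]);
    AOPair pr = aux[j]; pr.i = 0;
    double d = pair_pair_integral(pr, aj, dj, pr, aj, dj, ktype, zv, cv);
    auxs[j] = std::sqrt(std::fabs(d));
  }
  size_t nA = A.size(), nB = B.size(), nP = P.size();
  NumericVector out((R_xlen_t)(nA * nB * nP));
  for (const AOPair& pr : bra) {
    for (size_t j = 0; j < nP; ++j) {
      if (pr.schwarz * auxs[j] < screen) continue;
      std::vector<AO> aj(1, P[j]), dj(1, dumP[j]);
      AOPair kp = aux[j]; kp.i = 0;
      double v = pair_pair_integral(pr, A, B, kp, aj, dj, ktype, zv, cv);
      out[(R_xlen_t)pr.i + nA * ((R_xlen_t)pr.j + nB * j)] = v;
    }
  }
  out.attr("dim") = IntegerVector::create((int)nA, (int)nB, (int)nP);
  return out;
}

// [[Rcpp::export(name = ".cpp_four_center")]]
NumericVector cpp_four_center(List basA, List basB, List basC, List basD,
                              int ktype, NumericVector zetas, NumericVector coefs,
                              double screen) {
  std::vector<AO> A = parse_aos(basA), B = parse_aos(basB);
  std::vector<AO> C = parse_aos(basC), D = parse_aos(basD);
  std::vector<double> zv = to_vec(zetas), cv = to_vec(coefs);
  std::vector<AOPair> bra, ket;
  build_pairs(A, B, false, bra);
  build_pairs(C, D, false, ket);
  schwarz_fill(bra, A, B, ktype, zv, cv);
  schwarz_fill(ket, C, D, ktype, zv, cv);
  size_t nA = A.size(), nB = B.size(), nC = C.size(), nD = D.size();
  NumericVector out((R_xlen_t)(nA * nB * nC * nD));
  for (const AOPair& pb : bra) {
    for (const AOPair& pk : ket) {
      if (pb.schwarz * pk.schwarz < screen) continue;
      double v = pair_pair_integral(pb, A, B, pk, C, D, ktype, zv, cv);
      out[(R_xlen_t)pb.i + nA * ((R_xlen_t)pb.j + nB * ((R_xlen_t)pk.i + nC * (R_xlen_t)pk.j))] = v;
    }
  }
  out.attr("dim") = IntegerVector::create((int)nA, (int)nB, (int)nC, (int)nD);
  return out;
}

// one-electron integrals between two AO sets:
// returns list(S, T, V, DX, DY, DZ) with V = nuclear attraction,
// D* = dipole moment integrals about `origin`.
// [[Rcpp::export(name = ".cpp_one_electron")]]
List cpp_one_electron(List basA, List basB, NumericVector charges,
                      NumericMatrix coords, NumericVector origin) {
  std::vector<AO> A = parse_aos(basA), B = parse_aos(basB);
  size_t nA = A.size(), nB = B.size();
  NumericMatrix S(nA, nB), Tm(nA, nB), V(nA, nB), DX(nA, nB), DY(nA, nB), DZ(nA, nB);
  int nat = charges.size();
  for (size_t i = 0; i < nA; ++i) {
    for (size_t j = 0; j < nB; ++j) {
      const AO& ai = A[i]; const AO& aj = B[j];
      double s = 0.0, t = 0.0, v = 0.0, dx = 0.0, dy = 0.0, dz = 0.0;
      for (size_t pa = 0; pa < ai.ex.size(); ++pa) {
        for (size_t pb = 0; pb < aj.ex.size(); ++pb) {
          double a = ai.ex[pa], b = aj.ex[pb], p = a + b;
          double cc = ai.cf[pa] * aj.cf[pb];
          double P[3];
          EArr E[3];
          for (int d = 0; d < 3; ++d) {
            P[d] = (a * ai.A[d] + b * aj.A[d]) / p;
            // margin +2 on ket for kinetic
            build_E(E[d], ai.l[d], aj.l[d] + 2, a, b, ai.A[d] - aj.A[d]);
          }
          double pref = std::pow(PI / p, 1.5);
          double S0[3], S2[3], Sm2[3], S1[3];
          for (int d = 0; d < 3; ++d) {
            int li = ai.l[d], lj = aj.l[d];
            S0[d] = E[d].at(li, lj, 0);
            S2[d] = E[d].at(li, lj + 2, 0);
            Sm2[d] = (lj >= 2) ? E[d].at(li, lj - 2, 0) : 0.0;
            // dipole about origin: <x> = E1 + (P-origin) E0
            S1[d] = E[d].at(li, lj, 1) + (P[d] - origin[d]) * S0[d];
          }
          double sv = pref * S0[0] * S0[1] * S0[2];
          s += cc * sv;
          // kinetic
          double tk = 0.0;
          for (int d = 0; d < 3; ++d) {
            int lj = aj.l[d];
            double td = -0.5 * (lj * (lj - 1.0) * Sm2[d] - 2.0 * b * (2.0 * lj + 1.0) * S0[d] +
                                4.0 * b * b * S2[d]);
            double o1 = S0[(d + 1) % 3], o2 = S0[(d + 2) % 3];
            tk += td * o1 * o2;
          }
          t += cc * pref * tk;
          dx += cc * pref * S1[0] * S0[1] * S0[2];
          dy += cc * pref * S0[0] * S1[1] * S0[2];
          dz += cc * pref * S0[0] * S0[1] * S1[2];
          // nuclear attraction via Hermite/Boys
          int Lt = ai.l[0] + aj.l[0], Lu = ai.l[1] + aj.l[1], Lv = ai.l[2] + aj.l[2];
          int L = Lt + Lu + Lv;
          std::vector<double> F(L + 1), R((size_t)(Lt + 1) * (Lu + 1) * (Lv + 1));
          for (int c = 0; c < nat; ++c) {
            double X = P[0] - coords(c, 0), Y = P[1] - coords(c, 1), Z = P[2] - coords(c, 2);
            double T2 = p * (X * X + Y * Y + Z * Z);
            boys_array(T2, L, F.data());
            build_R(Lt, Lu, Lv, p, X, Y, Z, F.data(), R.data());
            double sacc = 0.0;
            int nu = Lu + 1, nv = Lv + 1;
            for (int tt = 0; tt <= Lt; ++tt) {
              double Ex = E[0].at(ai.l[0], aj.l[0], tt); if (Ex == 0.0) continue;
              for (int uu = 0; uu <= Lu; ++uu) {
                double Ey = E[1].at(ai.l[1], aj.l[1], uu); if (Ey == 0.0) continue;
                for (int vv = 0; vv <= Lv; ++vv) {
                  double Ez = E[2].at(ai.l[2], aj.l[2], vv); if (Ez == 0.0) continue;
                  sacc += Ex * Ey * Ez * R[((size_t)tt * nu + uu) * nv + vv];
                }
              }
            }
            v += cc * (-charges[c]) * 2.0 * PI / p * sacc;
          }
        }
      }
      S(i, j) = s; Tm(i, j) = t; V(i, j) = v;
      DX(i, j) = dx; DY(i, j) = dy; DZ(i, j) = dz;
    }
  }
  return List::create(_["S"] = S, _["T"] = Tm, _["V"] = V,
                      _["DX"] = DX, _["DY"] = DY, _["DZ"] = DZ);
}
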