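// Nearest-neighbor secondary-structure engine: minimum free energy (Zuker
// recursions with affine multiloops) and McCaskill partition function with
// base-pair probabilities.  Energies come from a parameter table supplied by
// the R side; structures are nested (no pseudoknots), lonely pairs allowed.
//
// Sequence codes: A=0, C=1, G=2, U=3, N=4 (N never pairs).
// Loop penalty vectors (hairpin/bulge/interior) are precomputed in R up to
// the sequence length, indexed by loop size.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = 1e9;

struct Model {
  double stack[7][7];      // pair types 1..6
  std::vector<double> hp;  // hairpin penalty by loop size
  std::vector<double> bu;  // bulge penalty by total size
  std::vector<double> in_; // interior penalty by total size
  double term_au, ml_a, ml_b, ml_c, asym, asym_max, rt;
  int max_interior, min_hairpin;
};

static inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 1; // AU
  if (a == 3 && b == 0) return 2; // UA
  if (a == 1 && b == 2) return 3; // CG
  if (a == 2 && b == 1) return 4; // GC
  if (a == 2 && b == 3) return 5; // GU
  if (a == 3 && b == 2) return 6; // UG
  return 0;
}

static inline double au_pen(const Model &m, int t) {
  return (t == 1 || t == 2 || t == 5 || t == 6) ? m.term_au : 0.0;
}

static Model build_model(const List &par) {
  Model m;
  NumericMatrix st = par["stack"];
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b) m.stack[a][b] = st(a - 1, b - 1);
  m.hp  = as<std::vector<double> >(par["hp_by_size"]);
  m.bu  = as<std::vector<double> >(par["bu_by_size"]);
  m.in_ = as<std::vector<double> >(par["in_by_size"]);
  m.term_au = as<double>(par["terminal_au"]);
  m.ml_a = as<double>(par["ml_close"]);
  m.ml_b = as<double>(par["ml_branch"]);
  m.ml_c = as<double>(par["ml_unpaired"]);
  m.asym = as<double>(par["interior_asym"]);
  m.asym_max = as<double>(par["interior_asym_max"]);
  m.rt = as<double>(par["rt"]);
  m.max_interior = as<int>(par["max_interior"]);
  m.min_hairpin = as<int>(par["min_hairpin"]);
  return m;
}

static inline double loop_pen(const std::vector<double> &v, int size) {
  if (size <= 0 || size >= (int)v.size()) return INF;
  return v[size];
}

// interior/bulge/stack energy between closing pair (i,j) and inner pair
// (k,l); d1, d2 are the unpaired lengths on each side
static inline double interior_energy(const Model &m, int t_out, int t_in,
                                     int d1, int d2) {
  if (d1 == 0 && d2 == 0) return m.stack[t_out][t_in];
  double both = au_pen(m, t_out) + au_pen(m, t_in);
  if (d1 == 0 || d2 == 0) return loop_pen(m.bu, d1 + d2) + both;
  double asym = m.asym * std::abs(d1 - d2);
  if (asym > m.asym_max) asym = m.asym_max;
  return loop_pen(m.in_, d1 + d2) + asym + both;
}

// ---------------------------------------------------------------- MFE ----

// [[Rcpp::export(name = ".c_mfe")]]
List c_mfe(IntegerVector seq, List par) {
  const Model m = build_model(par);
  const int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["dg"] = 0.0, _["structure"] = db);

  std::vector<int> s(seq.begin(), seq.end());
  std::vector<double> V((size_t)n * n, INF), M((size_t)n * n, INF),
      M1((size_t)n * n, INF);
  std::vector<double> W(n, 0.0);
#define IX(i, j) ((size_t)(i) * n + (j))

  for (int d = m.min_hairpin + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int t = ptype(s[i], s[j]);
      double v = INF;
      if (t != 0) {
        v = loop_pen(m.hp, j - i - 1) + au_pen(m, t); // hairpin
        int d1max = std::min(m.max_interior, j - i - 2);
        for (int d1 = 0; d1 <= d1max; ++d1) {
          int k = i + 1 + d1;
          int d2max = std::min(m.max_interior - d1, j - k - 2);
          for (int d2 = 0; d2 <= d2max; ++d2) {
            int l = j - 1 - d2;
            if (l - k - 1 < m.min_hairpin) break;
            double vi = V[IX(k, l)];
            if (vi >= INF) continue;
            int t2 = ptype(s[k], s[l]);
            double e = interior_energy(m, t, t2, d1, d2) + vi;
            if (e < v) v = e;
          }
        }
        // multiloop: close with (i,j); need >=2 branches inside
        double base = m.ml_a + m.ml_b + au_pen(m, t);
        for (int k = i + 2; k <= j - 2; ++k) {
          double a = M[IX(i + 1, k - 1)], b = M1[IX(k, j - 1)];
          if (a >= INF || b >= INF) continue;
          double e = base + a + b;
          if (e < v) v = e;
        }
      }
      V[IX(i, j)] = v;
      // M1: exactly one branch starting at i, optional trailing unpaired
      double m1 = INF;
      if (j > i) {
        double prev = M1[IX(i, j - 1)];
        if (prev < INF) m1 = prev + m.ml_c;
      }
      if (t != 0 && v < INF) {
        double e = v + m.ml_b + au_pen(m, t);
        if (e < m1) m1 = e;
      }
      M1[IX(i, j)] = m1;
      // M: >=1 branch
      double mm = m1;
      {
        double prev = M[IX(i + 1, j)];
        if (i + 1 <= j && prev < INF && prev + m.ml_c < mm) mm = prev + m.ml_c;
        for (int k = i + 1; k <= j; ++k) {
          double a = M[IX(i, k - 1)], b = M1[IX(k, j)];
          if (a >= INF || b >= INF) continue;
          if (a + b < mm) mm = a + b;
        }
      }
      M[IX(i, j)] = mm;
    }
  }

  for (int j = 0; j < n; ++j) {
    double w = (j > 0) ? W[j - 1] : 0.0;
    for (int k = 0; k <= j; ++k) {
      double v = V[IX(k, j)];
      if (v >= INF) continue;
      double e = ((k > 0) ? W[k - 1] : 0.0) + v +
                 au_pen(m, ptype(s[k], s[j]));
      if (e < w) w = e;
    }
    W[j] = w;
  }
  double dg = W[n - 1];
  if (dg > 0) dg = 0.0;

  // traceback (only when something pairs; ties resolved by scan order,
  // pairing checked before leaving a base unpaired => 5'-most opening pair)
  const double EPS = 1e-7;
  if (dg < 0) {
    struct Item { int i, j, mat; }; // mat: 0=V 1=M 2=M1
    std::vector<Item> stk;
    {
      int j = n - 1;
      while (j >= 0) {
        bool found = false;
        for (int k = 0; k <= j && !found; ++k) {
          double v = V[IX(k, j)];
          if (v >= INF) continue;
          double e = ((k > 0) ? W[k - 1] : 0.0) + v +
                     au_pen(m, ptype(s[k], s[j]));
          if (std::fabs(e - W[j]) < EPS) {
            stk.push_back(Item{k, j, 0});
            j = k - 1;
            found = true;
          }
        }
        if (!found) --j;
      }
    }
    while (!stk.empty()) {
      Item it = stk.back();
      stk.pop_back();
      int i = it.i, j = it.j;
      if (it.mat == 2) { // M1
        while (j > i && std::fabs(M1[IX(i, j)] - (M1[IX(i, j - 1)] + m.ml_c)) < EPS)
          --j;
        stk.push_back(Item{i, j, 0});
        continue;
      }
      if (it.mat == 1) { // M
        for (;;) {
          if (std::fabs(M[IX(i, j)] - M1[IX(i, j)]) < EPS) {
            stk.push_back(Item{i, j, 2});
            break;
          }
          if (i + 1 <= j && M[IX(i + 1, j)] < INF &&
              std::fabs(M[IX(i, j)] - (M[IX(i + 1, j)] + m.ml_c)) < EPS) {
            ++i;
            continue;
          }
          bool split = false;
          for (int k = i + 1; k <= j && !split; ++k) {
            double a = M[IX(i, k - 1)], b = M1[IX(k, j)];
            if (a >= INF || b >= INF) continue;
            if (std::fabs(M[IX(i, j)] - (a + b)) < EPS) {
              stk.push_back(Item{i, k - 1, 1});
              stk.push_back(Item{k, j, 2});
              split = true;
            }
          }
          break;
        }
        continue;
      }
      // V
      db[i] = '(';
      db[j] = ')';
      int t = ptype(s[i], s[j]);
      double v = V[IX(i, j)];
      if (std::fabs(v - (loop_pen(m.hp, j - i - 1) + au_pen(m, t))) < EPS)
        continue;
      bool done = false;
      int d1max = std::min(m.max_interior, j - i - 2);
      for (int d1 = 0; d1 <= d1max && !done; ++d1) {
        int k = i + 1 + d1;
        int d2max = std::min(m.max_interior - d1, j - k - 2);
        for (int d2 = 0; d2 <= d2max; ++d2) {
          int l = j - 1 - d2;
          if (l - k - 1 < m.min_hairpin) break;
          double vi = V[IX(k, l)];
          if (vi >= INF) continue;
          int t2 = ptype(s[k], s[l]);
          if (std::fabs(v - (interior_energy(m, t, t2, d1, d2) + vi)) < EPS) {
            stk.push_back(Item{k, l, 0});
            done = true;
            break;
          }
        }
      }
      if (done) continue;
      double base = m.ml_a + m.ml_b + au_pen(m, t);
      for (int k = i + 2; k <= j - 2; ++k) {
        double a = M[IX(i + 1, k - 1)], b = M1[IX(k, j - 1)];
        if (a >= INF || b >= INF) continue;
        if (std::fabs(v - (base + a + b)) < EPS) {
          stk.push_back(Item{i + 1, k - 1, 1});
          stk.push_back(Item{k, j - 1, 2});
          break;
        }
      }
    }
  }
  return List::create(_["dg"] = dg, _["structure"] = db);
#undef IX
}

// --------------------------------------------- partition function --------

// [[Rcpp::export(name = ".c_partition")]]
List c_partition(IntegerVector seq, List par, double mfe_dg, bool want_bpp) {
  const Model m = build_model(par);
  const int n = seq.size();
  if (n == 0)
    return List::create(_["lnz"] = 0.0,
                        _["bpp"] = NumericMatrix(0, 0));
  std::vector<int> s(seq.begin(), seq.end());

  // per-base rescaling to keep weights in double range on long sequences
  double sigma = 1.07 * mfe_dg / n; // <= 0
  double s0 = std::exp(-sigma / m.rt);
  double u = 1.0 / s0; // weight of one consumed base
  std::vector<double> upow(n + 1);
  upow[0] = 1.0;
  for (int k = 1; k <= n; ++k) upow[k] = upow[k - 1] * u;

  std::vector<double> Qb((size_t)n * n, 0.0), Qm((size_t)n * n, 0.0),
      Qm1((size_t)n * n, 0.0);
  std::vector<double> Ql(n, 0.0), Qr(n, 0.0);
#define IX(i, j) ((size_t)(i) * n + (j))
  const double rt = m.rt;
  const double u2 = u * u;

  for (int d = m.min_hairpin + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int t = ptype(s[i], s[j]);
      double qb = 0.0;
      if (t != 0) {
        qb = std::exp(-(loop_pen(m.hp, j - i - 1) + au_pen(m, t)) / rt) *
             upow[j - i + 1];
        int d1max = std::min(m.max_interior, j - i - 2);
        for (int d1 = 0; d1 <= d1max; ++d1) {
          int k = i + 1 + d1;
          int d2max = std::min(m.max_interior - d1, j - k - 2);
          for (int d2 = 0; d2 <= d2max; ++d2) {
            int l = j - 1 - d2;
            if (l - k - 1 < m.min_hairpin) break;
            double qi = Qb[IX(k, l)];
            if (qi == 0.0) continue;
            int t2 = ptype(s[k], s[l]);
            qb += std::exp(-interior_energy(m, t, t2, d1, d2) / rt) *
                  upow[d1 + d2 + 2] * qi;
          }
        }
        double wclose =
            std::exp(-(m.ml_a + m.ml_b + au_pen(m, t)) / rt) * u2;
        double qm2 = 0.0;
        for (int k = i + 2; k <= j - 2; ++k)
          qm2 += Qm[IX(i + 1, k - 1)] * Qm1[IX(k, j - 1)];
        qb += wclose * qm2;
      }
      Qb[IX(i, j)] = qb;
      // Qm1
      double q1 = (j > i) ? Qm1[IX(i, j - 1)] * u *
                                std::exp(-m.ml_c / rt)
                          : 0.0;
      if (t != 0 && qb > 0)
        q1 += qb * std::exp(-(m.ml_b + au_pen(m, t)) / rt);
      Qm1[IX(i, j)] = q1;
      // Qm: last branch starts at k; before it all-unpaired or Qm
      double qm = 0.0;
      for (int k = i; k <= j; ++k) {
        double b = Qm1[IX(k, j)];
        if (b == 0.0) continue;
        double pre = upow[k - i] * std::exp(-m.ml_c * (k - i) / rt);
        if (k > i) pre += Qm[IX(i, k - 1)];
        qm += pre * b;
      }
      Qm[IX(i, j)] = qm;
    }
  }

  // exterior, prefix and suffix
  for (int j = 0; j < n; ++j) {
    double q = ((j > 0) ? Ql[j - 1] : 1.0) * u;
    for (int k = 0; k <= j; ++k) {
      double qb = Qb[IX(k, j)];
      if (qb == 0.0) continue;
      q += ((k > 0) ? Ql[k - 1] : 1.0) * qb *
           std::exp(-au_pen(m, ptype(s[k], s[j])) / rt);
    }
    Ql[j] = q;
  }
  for (int i = n - 1; i >= 0; --i) {
    double q = ((i < n - 1) ? Qr[i + 1] : 1.0) * u;
    for (int l = i; l < n; ++l) {
      double qb = Qb[IX(i, l)];
      if (qb == 0.0) continue;
      q += qb * std::exp(-au_pen(m, ptype(s[i], s[l])) / rt) *
           ((l < n - 1) ? Qr[l + 1] : 1.0);
    }
    Qr[i] = q;
  }
  double Z = Ql[n - 1];
  double lnz = std::log(Z) + n * std::log(s0);

  NumericMatrix bpp(want_bpp ? n : 0, want_bpp ? n : 0);
  if (want_bpp) {
    std::vector<double> Ob((size_t)n * n, 0.0);
    // unpaired-or-Qm "filler" weight for a multiloop segment [a, b]
    auto fill = [&](int a, int b) -> double {
      int len = b - a + 1;
      if (len <= 0) return 1.0;
      double f = upow[len] * std::exp(-m.ml_c * len / rt);
      f += Qm[IX(a, b)];
      return f;
    };
    auto fill_up = [&](int a, int b) -> double {
      int len = b - a + 1;
      if (len <= 0) return 1.0;
      return upow[len] * std::exp(-m.ml_c * len / rt);
    };
    for (int d = n - 1; d >= m.min_hairpin + 1; --d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        if (Qb[IX(i, j)] == 0.0) continue;
        int t = ptype(s[i], s[j]);
        double ob = ((i > 0) ? Ql[i - 1] : 1.0) *
                    ((j < n - 1) ? Qr[j + 1] : 1.0) *
                    std::exp(-au_pen(m, t) / rt);
        // enclosed in an interior loop closed by (k,l)
        int d1max = std::min(m.max_interior, i - 1 >= 0 ? i : 0);
        for (int d1 = 0; d1 <= d1max; ++d1) {
          int k = i - 1 - d1;
          if (k < 0) break;
          int d2max = m.max_interior - d1;
          for (int d2 = 0; d2 <= d2max; ++d2) {
            int l = j + 1 + d2;
            if (l >= n) break;
            double oo = Ob[IX(k, l)];
            if (oo == 0.0) continue;
            int to = ptype(s[k], s[l]);
            if (to == 0) continue;
            ob += oo * std::exp(-interior_energy(m, to, t, d1, d2) / rt) *
                  upow[d1 + d2 + 2];
          }
        }
        // branch of a multiloop closed by (k,l)
        double wbr = std::exp(-(m.ml_b + au_pen(m, t)) / rt);
        for (int k = 0; k < i; ++k) {
          for (int l = j + 1; l < n; ++l) {
            double oo = Ob[IX(k, l)];
            if (oo == 0.0) continue;
            int to = ptype(s[k], s[l]);
            if (to == 0) continue;
            double wclose =
                std::exp(-(m.ml_a + m.ml_b + au_pen(m, to)) / rt) * u2;
            double ways = fill(k + 1, i - 1) * fill(j + 1, l - 1) -
                          fill_up(k + 1, i - 1) * fill_up(j + 1, l - 1);
            if (ways <= 0) continue;
            ob += oo * wclose * wbr * ways;
          }
        }
        Ob[IX(i, j)] = ob;
        double p = Qb[IX(i, j)] * ob / Z;
        bpp(i, j) = p;
        bpp(j, i) = p;
      }
    }
  }
  return List::create(_["lnz"] = lnz, _["bpp"] = bpp);
#undef IX
}
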