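// Joint CDS design dynamic program.
//
// Minimizes  mu * E(structure) + sum_path cw(position, state)  over all
// pairs (lattice path, pseudoknot-free structure), where cw carries the
// per-codon kappa * (-ln w) charge on third-position lattice states.
// Zuker-style span matrices over (position, variant-state) node pairs:
//   W  - cheapest all-unpaired state path between two fixed nodes
//   C  - span closed by a pair
//   M1 - multiloop segment whose single/leading branch starts at the left end
//   M  - multiloop segment with >= 1 branch
//   M2 - multiloop segment with >= 2 branches
//   F  - external loop, left-to-right
// Beam pruning keeps the `beam` lowest entries per right endpoint in the
// C, M1 and M2 matrices (deterministic tie-break by value, then indices);
// W, M and F are never pruned, so every stored value remains reproducible
// by the traceback under pruning.
//
// Folding a fixed sequence is the degenerate case: one state per position,
// cw = 0, mu = 1.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double BIG = 1e18;
static const double EPS = 1e-9;

struct Engine {
  int L;
  std::vector<int> ns;          // states per position
  std::vector<int> nuc;         // 6 * L, base code 0..3 (A C G U)
  std::vector<char> adjv;       // (L-1) * 36
  std::vector<double> cw;       // 6 * L
  // model terms
  double stack[6][6];
  std::vector<double> hairpinL, bulgeL, internalL;
  double lxc, ml_a, ml_b, ml_c, term_au, mu;
  bool bulge1_stacks;
  int minloop, maxloop, beam;

  size_t NS;
  std::vector<double> W, C, M, M1, M1adj, M2;
  std::vector<double> F;        // 6 * L
  double ops_twoloop = 0, ops_split = 0;

  inline size_t id(int i, int s) const { return (size_t)i * 6 + s; }
  inline size_t ix(int i, int si, int j, int sj) const {
    return id(i, si) * NS + id(j, sj);
  }
  inline bool adj(int p, int s, int t) const {   // p -> p+1
    return adjv[(size_t)p * 36 + s * 6 + t] != 0;
  }
  inline int base(int p, int s) const { return nuc[(size_t)p * 6 + s]; }
  inline double cwv(int p, int s) const { return cw[(size_t)p * 6 + s]; }

  static inline int ptype(int a, int b) {
    // 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA; 0 not pairable
    if (a == 1 && b == 2) return 1;
    if (a == 2 && b == 1) return 2;
    if (a == 2 && b == 3) return 3;
    if (a == 3 && b == 2) return 4;
    if (a == 0 && b == 3) return 5;
    if (a == 3 && b == 0) return 6;
    return 0;
  }
  inline double aupen(int t) const { return t >= 3 ? term_au : 0.0; }
  inline double lenterm(const std::vector<double>& tab, int n) const {
    if (n <= 30) return tab[n];
    return tab[30] + lxc * std::log((double)n / 30.0);
  }
  // energy of the loop between outer pair (types t_out) and inner pair
  // (t_in as (p,q), t_in_rev as (q,p)), with n1/n2 unpaired on each side
  inline double two_loop(int t_out, int t_in, int t_in_rev,
                         int n1, int n2) const {
    if (n1 == 0 && n2 == 0) return stack[t_out - 1][t_in_rev - 1];
    int n = n1 + n2;
    if (n1 == 0 || n2 == 0) {
      double e = lenterm(bulgeL, n);
      if (n == 1 && bulge1_stacks) e += stack[t_out - 1][t_in_rev - 1];
      else e += aupen(t_out) + aupen(t_in);
      return e;
    }
    return lenterm(internalL, n) + aupen(t_out) + aupen(t_in);
  }

  void compute_W() {
    W.assign(NS * NS, BIG);
    for (int i = 0; i < L; ++i)
      for (int si = 0; si < ns[i]; ++si) {
        W[ix(i, si, i, si)] = cwv(i, si);
        for (int j = i + 1; j < L; ++j)
          for (int sj = 0; sj < ns[j]; ++sj) {
            double best = BIG;
            for (int sp = 0; sp < ns[j - 1]; ++sp) {
              if (!adj(j - 1, sp, sj)) continue;
              double v = W[ix(i, si, j - 1, sp)];
              if (v < best) best = v;
            }
            if (best < BIG / 2)
              W[ix(i, si, j, sj)] = best + cwv(j, sj);
          }
      }
  }

  // keep the `beam` smallest finite entries in column j of `mat`
  void prune_column(std::vector<double>& mat, int j) {
    if (beam <= 0) return;
    struct Ent { double v; int i, si, sj; };
    std::vector<Ent> ents;
    for (int i = 0; i < j; ++i)
      for (int si = 0; si < ns[i]; ++si)
        for (int sj = 0; sj < ns[j]; ++sj) {
          double v = mat[ix(i, si, j, sj)];
          if (v < BIG / 2) ents.push_back({v, i, si, sj});
        }
    if ((int)ents.size() <= beam) return;
    std::sort(ents.begin(), ents.end(), [](const Ent& a, const Ent& b) {
      if (a.v != b.v) return a.v < b.v;
      if (a.i != b.i) return a.i < b.i;
      if (a.si != b.si) return a.si < b.si;
      return a.sj < b.sj;
    });
    for (size_t k = beam; k < ents.size(); ++k)
      mat[ix(ents[k].i, ents[k].si, j, ents[k].sj)] = BIG;
  }

  double compute_C_entry(int i, int si, int j, int sj) {
    int t = ptype(base(i, si), base(j, sj));
    if (t == 0 || j - i - 1 < minloop) return BIG;
    double best = BIG;
    // hairpin
    {
      double wp = W[ix(i, si, j, sj)];
      if (wp < BIG / 2) {
        double cand = mu * (lenterm(hairpinL, j - i - 1) + aupen(t)) + wp;
        if (cand < best) best = cand;
      }
    }
    // stack / bulge / internal: inner pair (p, q)
    int pmax = std::min(i + maxloop + 1, j - 2);
    for (int p = i + 1; p <= pmax; ++p) {
      int n1 = p - i - 1;
      int qlo = std::max(p + minloop + 1, j - 1 - (maxloop - n1));
      for (int q = j - 1; q >= qlo; --q) {
        int n2 = j - q - 1;
        for (int sp = 0; sp < ns[p]; ++sp) {
          double wl = W[ix(i, si, p, sp)];
          if (wl >= BIG / 2) continue;
          for (int sq = 0; sq < ns[q]; ++sq) {
            ops_twoloop += 1;
            double cin = C[ix(p, sp, q, sq)];
            if (cin >= BIG / 2) continue;
            double wr = W[ix(q, sq, j, sj)];
            if (wr >= BIG / 2) continue;
            int tin = ptype(base(p, sp), base(q, sq));
            int tinr = ptype(base(q, sq), base(p, sp));
            double cand = mu * two_loop(t, tin, tinr, n1, n2) +
              (wl - cwv(p, sp)) + cin + (wr - cwv(q, sq));
            if (cand < best) best = cand;
          }
        }
      }
    }
    // multiloop: closing pair (i, j) around >= 2 branches
    if (j - i >= 10) {
      double inner = BIG;
      for (int s1 = 0; s1 < ns[i + 1]; ++s1) {
        if (!adj(i, si, s1)) continue;
        for (int s2 = 0; s2 < ns[j - 1]; ++s2) {
          if (!adj(j - 1, s2, sj)) continue;
          double v = M2[ix(i + 1, s1, j - 1, s2)];
          if (v < inner) inner = v;
        }
      }
      if (inner < BIG / 2) {
        double cand = mu * (ml_a + ml_b + aupen(t)) + cwv(i, si) +
          cwv(j, sj) + inner;
        if (cand < best) best = cand;
      }
    }
    return best;
  }

  void run() {
    NS = (size_t)L * 6;
    compute_W();
    C.assign(NS * NS, BIG);
    M.assign(NS * NS, BIG);
    M1.assign(NS * NS, BIG);
    M1adj.assign(NS * NS, BIG);
    M2.assign(NS * NS, BIG);
    for (int j = 1; j < L; ++j) {
      // C column
      for (int i = j - 1; i >= 0; --i)
        for (int si = 0; si < ns[i]; ++si)
          for (int sj = 0; sj < ns[j]; ++sj)
            C[ix(i, si, j, sj)] = compute_C_entry(i, si, j, sj);
      prune_column(C, j);
      // M1 column: branch starts at i, trailing unpaired
      for (int i = j - 1; i >= 0; --i)
        for (int si = 0; si < ns[i]; ++si)
          for (int sj = 0; sj < ns[j]; ++sj) {
            double best = BIG;
            double c = C[ix(i, si, j, sj)];
            if (c < BIG / 2) {
              int t = ptype(base(i, si), base(j, sj));
              best = c + mu * (ml_b + aupen(t));
            }
            if (j - 1 > i)
              for (int sp = 0; sp < ns[j - 1]; ++sp) {
                if (!adj(j - 1, sp, sj)) continue;
                double v = M1[ix(i, si, j - 1, sp)];
                if (v >= BIG / 2) continue;
                double cand = v + mu * ml_c + cwv(j, sj);
                if (cand < best) best = cand;
              }
            M1[ix(i, si, j, sj)] = best;
          }
      prune_column(M1, j);
      // M1adj column: min over first state of the segment starting at k+1
      for (int k = 0; k < j; ++k)
        for (int sk = 0; sk < ns[k]; ++sk)
          for (int sj = 0; sj < ns[j]; ++sj) {
            double best = BIG;
            for (int t = 0; t < ns[k + 1]; ++t) {
              if (!adj(k, sk, t)) continue;
              double v = M1[ix(k + 1, t, j, sj)];
              if (v < best) best = v;
            }
            M1adj[ix(k, sk, j, sj)] = best;
          }
      // M2 column: split into M [i..k] + M1 [k+1..j]
      for (int i = j - 1; i >= 0; --i)
        for (int si = 0; si < ns[i]; ++si)
          for (int sj = 0; sj < ns[j]; ++sj) {
            double best = BIG;
            for (int k = i + minloop + 1; k <= j - minloop - 2; ++k)
              for (int sk = 0; sk < ns[k]; ++sk) {
                ops_split += 1;
                double m = M[ix(i, si, k, sk)];
                if (m >= BIG / 2) continue;
                double a = M1adj[ix(k, sk, j, sj)];
                if (a >= BIG / 2) continue;
                if (m + a < best) best = m + a;
              }
            M2[ix(i, si, j, sj)] = best;
          }
      prune_column(M2, j);
      // M column: >= 1 branch (uses same-column M[i+1][j]; never pruned)
      for (int i = j - 1; i >= 0; --i)
        for (int si = 0; si < ns[i]; ++si)
          for (int sj = 0; sj < ns[j]; ++sj) {
            double best = M1[ix(i, si, j, sj)];
            double v2 = M2[ix(i, si, j, sj)];
            if (v2 < best) best = v2;
            if (i + 1 < j)
              for (int t = 0; t < ns[i + 1]; ++t) {
                if (!adj(i, si, t)) continue;
                double v = M[ix(i + 1, t, j, sj)];
                if (v >= BIG / 2) continue;
                double cand = v + mu * ml_c + cwv(i, si);
                if (cand < best) best = cand;
              }
            if (j - 1 > i)
              for (int sp = 0; sp < ns[j - 1]; ++sp) {
                if (!adj(j - 1, sp, sj)) continue;
                double v = M[ix(i, si, j - 1, sp)];
                if (v >= BIG / 2) continue;
                double cand = v + mu * ml_c + cwv(j, sj);
                if (cand < best) best = cand;
              }
            M[ix(i, si, j, sj)] = best;
          }
    }
    // external loop
    F.assign(NS, BIG);
    for (int s = 0; s < ns[0]; ++s) F[id(0, s)] = cwv(0, s);
    for (int j = 1; j < L; ++j)
      for (int sj = 0; sj < ns[j]; ++sj) {
        double best = BIG;
        for (int sp = 0; sp < ns[j - 1]; ++sp) {
          if (!adj(j - 1, sp, sj)) continue;
          double v = F[id(j - 1, sp)];
          if (v < BIG / 2 && v + cwv(j, sj) < best) best = v + cwv(j, sj);
        }
        for (int i = 0; i <= j - minloop - 1; ++i)
          for (int si = 0; si < ns[i]; ++si) {
            double c = C[ix(i, si, j, sj)];
            if (c >= BIG / 2) continue;
            int t = ptype(base(i, si), base(j, sj));
            double pen = mu * aupen(t);
            if (i == 0) {
              if (c + pen < best) best = c + pen;
            } else {
              for (int sp = 0; sp < ns[i - 1]; ++sp) {
                if (!adj(i - 1, sp, si)) continue;
                double f = F[id(i - 1, sp)];
                if (f >= BIG / 2) continue;
                double cand = f + c + pen;
                if (cand < best) best = cand;
              }
            }
          }
        F[id(j, sj)] = best;
      }
  }

  // -------- traceback --------
  std::vector<int> state;
  std::string db;

  struct Frame { int kind, i, si, j, sj; };  // kinds: 0 F, 1 C, 2 M, 3 M1, 4 M2, 5 PATH
  std::vector<Frame> tb;

  inline bool eq(double a, double b) const { return std::fabs(a - b) <= EPS; }

  void path_assign(int a, int sa, int b, int sb) {
    // assign interior states of the unpaired stretch a..b using W
    state[a] = sa; state[b] = sb;
    for (int p = b - 1; p > a; --p) {
      int nxt = state[p + 1];
      double target = W[ix(a, sa, p + 1, nxt)];
      int chosen = -1;
      for (int s = 0; s < ns[p]; ++s) {
        if (!adj(p, s, nxt)) continue;
        double v = W[ix(a, sa, p, s)];
        if (v < BIG / 2 && eq(v + cwv(p + 1, nxt), target)) { chosen = s; break; }
      }
      if (chosen < 0) stop("internal error: W traceback failed");
      state[p] = chosen;
    }
  }

  void trace_F(int j, int sj) {
    state[j] = sj;
    if (j == 0) return;
    double val = F[id(j, sj)];
    for (int sp = 0; sp < ns[j - 1]; ++sp) {          // j unpaired
      if (!adj(j - 1, sp, sj)) continue;
      double v = F[id(j - 1, sp)];
      if (v < BIG / 2 && eq(v + cwv(j, sj), val)) {
        tb.push_back({0, j - 1, sp, 0, 0});
        return;
      }
    }
    for (int i = 0; i <= j - minloop - 1; ++i)
      for (int si = 0; si < ns[i]; ++si) {
        double c = C[ix(i, si, j, sj)];
        if (c >= BIG / 2) continue;
        double pen = mu * aupen(ptype(base(i, si), base(j, sj)));
        if (i == 0) {
          if (eq(c + pen, val)) {
            tb.push_back({1, i, si, j, sj});
            return;
          }
        } else {
          for (int sp = 0; sp < ns[i - 1]; ++sp) {
            if (!adj(i - 1, sp, si)) continue;
            double f = F[id(i - 1, sp)];
            if (f < BIG / 2 && eq(f + c + pen, val)) {
              tb.push_back({0, i - 1, sp, 0, 0});
              tb.push_back({1, i, si, j, sj});
              return;
            }
          }
        }
      }
    stop("internal error: F traceback failed");
  }

  void trace_C(int i, int si, int j, int sj) {
    state[i] = si; state[j] = sj;
    db[i] = '('; db[j] = ')';
    double val = C[ix(i, si, j, sj)];
    int t = ptype(base(i, si), base(j, sj));
    double wp = W[ix(i, si, j, sj)];
    if (wp < BIG / 2 &&
        eq(mu * (lenterm(hairpinL, j - i - 1) + aupen(t)) + wp, val)) {
      path_assign(i, si, j, sj);
      return;
    }
    int pmax = std::min(i + maxloop + 1, j - 2);
    for (int p = i + 1; p <= pmax; ++p) {
      int n1 = p - i - 1;
      int qlo = std::max(p + minloop + 1, j - 1 - (maxloop - n1));
      for (int q = j - 1; q >= qlo; --q) {
        int n2 = j - q - 1;
        for (int sp = 0; sp < ns[p]; ++sp) {
          double wl = W[ix(i, si, p, sp)];
          if (wl >= BIG / 2) continue;
          for (int sq = 0; sq < ns[q]; ++sq) {
            double cin = C[ix(p, sp, q, sq)];
            if (cin >= BIG / 2) continue;
            double wr = W[ix(q, sq, j, sj)];
            if (wr >= BIG / 2) continue;
            int tin = ptype(base(p, sp), base(q, sq));
            int tinr = ptype(base(q, sq), base(p, sp));
            double cand = mu * two_loop(t, tin, tinr, n1, n2) +
              (wl - cwv(p, sp)) + cin + (wr - cwv(q, sq));
            if (eq(cand, val)) {
              path_assign(i, si, p, sp);
              path_assign(q, sq, j, sj);
              tb.push_back({1, p, sp, q, sq});
              return;
            }
          }
        }
      }
    }
    if (j - i >= 10) {
      for (int s1 = 0; s1 < ns[i + 1]; ++s1) {
        if (!adj(i, si, s1)) continue;
        for (int s2 = 0; s2 < ns[j - 1]; ++s2) {
          if (!adj(j - 1, s2, sj)) continue;
          double v = M2[ix(i + 1, s1, j - 1, s2)];
          if (v >= BIG / 2) continue;
          double cand = mu * (ml_a + ml_b + aupen(t)) + cwv(i, si) +
            cwv(j, sj) + v;
          if (eq(cand, val)) {
            tb.push_back({4, i + 1, s1, j - 1, s2});
            return;
          }
        }
      }
    }
    stop("internal error: C traceback failed");
  }

  void trace_M1(int i, int si, int j, int sj) {
    state[i] = si; state[j] = sj;
    double val = M1[ix(i, si, j, sj)];
    double c = C[ix(i, si, j, sj)];
    if (c < BIG / 2) {
      int t = ptype(base(i, si), base(j, sj));
      if (eq(c + mu * (ml_b + aupen(t)), val)) {
        tb.push_back({1, i, si, j, sj});
        return;
      }
    }
    if (j - 1 > i)
      for (int sp = 0; sp < ns[j - 1]; ++sp) {
        if (!adj(j - 1, sp, sj)) continue;
        double v = M1[ix(i, si, j - 1, sp)];
        if (v < BIG / 2 && eq(v + mu * ml_c + cwv(j, sj), val)) {
          tb.push_back({3, i, si, j - 1, sp});
          return;
        }
      }
    stop("internal error: M1 traceback failed");
  }

  void trace_M2(int i, int si, int j, int sj) {
    state[i] = si; state[j] = sj;
    double val = M2[ix(i, si, j, sj)];
    for (int k = i + minloop + 1; k <= j - minloop - 2; ++k)
      for (int sk = 0; sk < ns[k]; ++sk) {
        double m = M[ix(i, si, k, sk)];
        if (m >= BIG / 2) continue;
        double a = M1adj[ix(k, sk, j, sj)];
        if (a >= BIG / 2) continue;
        if (!eq(m + a, val)) continue;
        for (int t = 0; t < ns[k + 1]; ++t) {
          if (!adj(k, sk, t)) continue;
          double v = M1[ix(k + 1, t, j, sj)];
          if (v < BIG / 2 && eq(v, a)) {
            tb.push_back({2, i, si, k, sk});
            tb.push_back({3, k + 1, t, j, sj});
            return;
          }
        }
      }
    stop("internal error: M2 traceback failed");
  }

  void trace_M(int i, int si, int j, int sj) {
    state[i] = si; state[j] = sj;
    double val = M[ix(i, si, j, sj)];
    if (eq(M1[ix(i, si, j, sj)], val)) {
      tb.push_back({3, i, si, j, sj});
      return;
    }
    if (eq(M2[ix(i, si, j, sj)], val)) {
      tb.push_back({4, i, si, j, sj});
      return;
    }
    if (i + 1 < j)
      for (int t = 0; t < ns[i + 1]; ++t) {
        if (!adj(i, si, t)) continue;
        double v = M[ix(i + 1, t, j, sj)];
        if (v < BIG / 2 && eq(v + mu * ml_c + cwv(i, si), val)) {
          tb.push_back({2, i + 1, t, j, sj});
          return;
        }
      }
    if (j - 1 > i)
      for (int sp = 0; sp < ns[j - 1]; ++sp) {
        if (!adj(j - 1, sp, sj)) continue;
        double v = M[ix(i, si, j - 1, sp)];
        if (v < BIG / 2 && eq(v + mu * ml_c + cwv(j, sj), val)) {
          tb.push_back({2, i, si, j - 1, sp});
          return;
        }
      }
    stop("internal error: M traceback failed");
  }

  void traceback(int sj_final) {
    state.assign(L, -1);
    db.assign(L, '.');
    tb.clear();
    tb.push_back({0, L - 1, sj_final, 0, 0});
    while (!tb.empty()) {
      Frame f = tb.back(); tb.pop_back();
      switch (f.kind) {
        case 0: trace_F(f.i, f.si); break;
        case 1: trace_C(f.i, f.si, f.j, f.sj); break;
        case 2: trace_M(f.i, f.si, f.j, f.sj); break;
        case 3: trace_M1(f.i, f.si, f.j, f.sj); break;
        case 4: trace_M2(f.i, f.si, f.j, f.sj); break;
      }
    }
    for (int p = 0; p < L; ++p)
      if (state[p] < 0) stop("internal error: unassigned state in traceback");
  }
};

// [[Rcpp::export(name = ".design_dp")]]
List design_dp(int L, IntegerVector ns, IntegerVector nuc,
               LogicalVector adjv, NumericVector cw,
               NumericMatrix stack_mat, NumericVector hairpinL,
               NumericVector bulgeL, NumericVector internalL,
               double lxc, double ml_a, double ml_b, double ml_c,
               double term_au, bool bulge1_stacks, double mu,
               int minloop, int maxloop, int beam) {
  if (L < 1) stop("empty lattice");
  Engine e;
  e.L = L;
  e.ns.assign(ns.begin(), ns.end());
  e.nuc.assign(nuc.begin(), nuc.end());
  e.adjv.assign(adjv.begin(), adjv.end());
  e.cw.assign(cw.begin(), cw.end());
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      e.stack[a][b] = stack_mat(a, b);
  e.hairpinL.assign(hairpinL.begin(), hairpinL.end());
  e.bulgeL.assign(bulgeL.begin(), bulgeL.end());
  e.internalL.assign(internalL.begin(), internalL.end());
  e.lxc = lxc; e.ml_a = ml_a; e.ml_b = ml_b; e.ml_c = ml_c;
  e.term_au = term_au; e.bulge1_stacks = bulge1_stacks;
  e.mu = mu; e.minloop = minloop; e.maxloop = maxloop; e.beam = beam;
  e.run();
  double best = BIG; int bs = 0;
  for (int s = 0; s < e.ns[L - 1]; ++s)
    if (e.F[e.id(L - 1, s)] < best) { best = e.F[e.id(L - 1, s)]; bs = s; }
  if (best >= BIG / 2) stop("no feasible path through the lattice");
  e.traceback(bs);
  return List::create(
    _["value"] = best,
    _["states"] = IntegerVector(e.state.begin(), e.state.end()),
    _["structure"] = e.db,
    _["ops_twoloop"] = e.ops_twoloop,
    _["ops_split"] = e.ops_split);
}
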