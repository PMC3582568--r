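#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a nearest-neighbor
// model: stacking energies for the six WC/wobble pairs, logarithmic hairpin /
// bulge / internal-loop penalties and an affine multibranch term. Nested
// structures only (no pseudoknots); hairpin loops of >= 3 unpaired bases.
// Parameters come in from R so that the R-side evaluator and this DP share a
// single parameter table.

static const double INF = 1e9;
static const double EPS = 1e-9;

struct Params {
  std::vector<double> stack; // 6x6, row-major, 0-indexed by pair code - 1
  double ha, hb;             // hairpin: ha + hb * log(n / 3)
  double ba, bb;             // bulge:   ba + bb * log(n)
  double ia, ib;             // internal loop: ia + ib * log(n / 2)
  double ma, mb, mc;         // multibranch: closing + per-branch + per-unpaired
  int max_loop;              // max unpaired bases in a bulge/internal loop
};

// pair codes: AT=1 TA=2 GC=3 CG=4 GT=5 TG=6, 0 = not pairable
static inline int pair_code(char a, char b) {
  if (a == 'A' && b == 'T') return 1;
  if (a == 'T' && b == 'A') return 2;
  if (a == 'G' && b == 'C') return 3;
  if (a == 'C' && b == 'G') return 4;
  if (a == 'G' && b == 'T') return 5;
  if (a == 'T' && b == 'G') return 6;
  return 0;
}

static inline double hairpin_e(int n, const Params& p) {
  return p.ha + p.hb * std::log((double)n / 3.0);
}
static inline double loop_e(int d5, int d3, const Params& p) {
  int n = d5 + d3;
  if (d5 == 0 || d3 == 0) return p.ba + p.bb * std::log((double)n);
  return p.ia + p.ib * std::log((double)n / 2.0);
}

class Folder {
public:
  int n;
  std::string seq;
  Params par;
  std::vector<int> code; // code of (i,j) flattened would be big; compute on the fly
  std::vector<double> V, WM;
  std::vector<double> W;

  inline int idx(int i, int j) const { return i * n + j; }
  inline int pc(int i, int j) const { return pair_code(seq[i], seq[j]); }
  inline bool can_pair(int i, int j) const {
    return j - i - 1 >= 3 && pc(i, j) > 0;
  }

  Folder(const std::string& s, const Params& p) : n(s.size()), seq(s), par(p) {
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    W.assign(n + 1, 0.0);
    fill();
  }

  double v_hairpin(int i, int j) { return hairpin_e(j - i - 1, par); }

  double v_stack(int i, int j) {
    if (!can_pair(i + 1, j - 1)) return INF;
    double inner = V[idx(i + 1, j - 1)];
    if (inner >= INF) return INF;
    return par.stack[(pc(i, j) - 1) * 6 + (pc(i + 1, j - 1) - 1)] + inner;
  }

  // best interior loop (excluding the stack case), also used in traceback
  double v_interior(int i, int j, int* bk = 0, int* bl = 0) {
    double best = INF;
    for (int k = i + 1; k < j; ++k) {
      int d5 = k - i - 1;
      if (d5 > par.max_loop) break;
      for (int l = j - 1; l > k; --l) {
        int d3 = j - l - 1;
        if (d5 + d3 < 1) continue;       // (0,0) is the stack case
        if (d5 + d3 > par.max_loop) break;
        if (!can_pair(k, l)) continue;
        double e = loop_e(d5, d3, par) + V[idx(k, l)];
        if (e < best - EPS) { best = e; if (bk) { *bk = k; *bl = l; } }
      }
    }
    return best;
  }

  double v_multi(int i, int j, int* bk = 0) {
    double best = INF;
    for (int k = i + 2; k <= j - 2; ++k) {
      double a = WM[idx(i + 1, k - 1)], b = WM[idx(k, j - 1)];
      if (a >= INF || b >= INF) continue;
      double e = par.ma + par.mb + a + b;
      if (e < best - EPS) { best = e; if (bk) *bk = k; }
    }
    return best;
  }

  void fill() {
    for (int j = 0; j < n; ++j) {
      for (int i = j - 4; i >= 0; --i) {
        // V
        if (can_pair(i, j)) {
          double best = v_hairpin(i, j);
          double e = v_stack(i, j);       if (e < best) best = e;
          e = v_interior(i, j);           if (e < best) best = e;
          e = v_multi(i, j);              if (e < best) best = e;
          V[idx(i, j)] = best;
        }
        // WM over i..j
        double best = INF;
        if (can_pair(i, j) && V[idx(i, j)] < INF) best = V[idx(i, j)] + par.mb;
        if (i + 1 <= j && WM[idx(i + 1, j)] < INF)
          best = std::min(best, WM[idx(i + 1, j)] + par.mc);
        if (i <= j - 1 && WM[idx(i, j - 1)] < INF)
          best = std::min(best, WM[idx(i, j - 1)] + par.mc);
        for (int k = i + 1; k <= j; ++k) {
          double a = WM[idx(i, k - 1)], b = (can_pair(k, j) ? V[idx(k, j)] : INF);
          if (a < INF && b < INF) best = std::min(best, a + b + par.mb);
        }
        WM[idx(i, j)] = best;
      }
    }
    // external: W[j+1] = best energy of prefix 0..j, W[0] = empty prefix
    W[0] = 0.0;
    for (int j = 0; j < n; ++j) {
      double best = W[j]; // j unpaired
      for (int i = 0; i <= j - 4; ++i) {
        if (can_pair(i, j) && V[idx(i, j)] < INF) {
          double e = W[i] + V[idx(i, j)];
          if (e < best) best = e;
        }
      }
      W[j + 1] = best;
    }
  }

  // ---- traceback ----
  struct Seg { int i, j, state; }; // state 0=EXT 1=PAIR 2=WM

  void traceback(std::string& db) {
    db.assign(n, '.');
    std::stack<Seg> st;
    st.push({0, n - 1, 0});
    while (!st.empty()) {
      Seg s = st.top(); st.pop();
      int i = s.i, j = s.j;
      if (i > j) continue;
      if (s.state == 0) { // external region covering i..j (suffix logic on W)
        // peel from the right end; prefer j unpaired (fewer pairs)
        int jj = j;
        while (jj >= i) {
          double wj = W[jj + 1];
          if (std::fabs(W[jj] - wj) < EPS) { --jj; continue; }
          bool done = false;
          for (int k = i; k <= jj - 4; ++k) {
            if (can_pair(k, jj) && V[idx(k, jj)] < INF &&
                std::fabs(W[k] + V[idx(k, jj)] - wj) < EPS) {
              st.push({k, jj, 1});
              jj = k - 1;
              done = true;
              break;
            }
          }
          if (!done) --jj; // numerical safety
        }
      } else if (s.state == 1) { // i pairs j
        db[i] = '('; db[j] = ')';
        double v = V[idx(i, j)];
        if (std::fabs(v_hairpin(i, j) - v) < EPS) continue;
        double e = v_stack(i, j);
        if (e < INF && std::fabs(e - v) < EPS) { st.push({i + 1, j - 1, 1}); continue; }
        int bk = -1, bl = -1;
        e = v_interior(i, j, &bk, &bl);
        if (e < INF && std::fabs(e - v) < EPS) { st.push({bk, bl, 1}); continue; }
        int mk = -1;
        e = v_multi(i, j, &mk);
        if (e < INF && std::fabs(e - v) < EPS) {
          st.push({i + 1, mk - 1, 2});
          st.push({mk, j - 1, 2});
          continue;
        }
        // numerical safety: treat as hairpin
      } else { // WM region i..j
        double w = WM[idx(i, j)];
        if (w >= INF) continue;
        if (can_pair(i, j) && V[idx(i, j)] < INF &&
            std::fabs(V[idx(i, j)] + par.mb - w) < EPS) { st.push({i, j, 1}); continue; }
        if (i + 1 <= j && WM[idx(i + 1, j)] < INF &&
            std::fabs(WM[idx(i + 1, j)] + par.mc - w) < EPS) { st.push({i + 1, j, 2}); continue; }
        if (i <= j - 1 && WM[idx(i, j - 1)] < INF &&
            std::fabs(WM[idx(i, j - 1)] + par.mc - w) < EPS) { st.push({i, j - 1, 2}); continue; }
        bool done = false;
        for (int k = i + 1; k <= j; ++k) {
          double a = WM[idx(i, k - 1)], b = (can_pair(k, j) ? V[idx(k, j)] : INF);
          if (a < INF && b < INF && std::fabs(a + b + par.mb - w) < EPS) {
            st.push({i, k - 1, 2});
            st.push({k, j, 1});
            done = true;
            break;
          }
        }
        (void)done;
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, NumericMatrix stack_table,
                  NumericVector hairpin_par, NumericVector bulge_par,
                  NumericVector internal_par, NumericVector multi_par,
                  int max_loop) {
  Params p;
  p.stack.resize(36);
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) p.stack[r * 6 + c] = stack_table(r, c);
  p.ha = hairpin_par[0]; p.hb = hairpin_par[1];
  p.ba = bulge_par[0];   p.bb = bulge_par[1];
  p.ia = internal_par[0]; p.ib = internal_par[1];
  p.ma = multi_par[0]; p.mb = multi_par[1]; p.mc = multi_par[2];
  p.max_loop = max_loop;

  Folder f(seq, p);
  int n = seq.size();
  double mfe = f.W[n];
  std::string db(n, '.');
  if (mfe < -EPS) {
    f.traceback(db);
  } else {
    mfe = 0.0; // open chain is optimal (or tied): report no pairs
  }
  return List::create(_["structure"] = db, _["energy"] = mfe);
}
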