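#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Penalty-scored antiparallel complementarity between a miRNA and a
// transcript window: match 0, G:U wobble 0.5, mismatch 1, gap 1, penalties
// doubled at miRNA positions 2-13 from the 5' end (the "core"). At most one
// gap; windows of length len(miRNA) - 1, len(miRNA) and len(miRNA) + 1 are
// scanned at every transcript offset and those scoring <= cutoff reported.

static inline double base_pen(char m, char s) {
  // m = miRNA base, s = site base (both DNA alphabet), antiparallel pairing
  switch (m) {
  case 'A': return s == 'T' ? 0.0 : 1.0;
  case 'C': return s == 'G' ? 0.0 : 1.0;
  case 'G': return s == 'C' ? 0.0 : (s == 'T' ? 0.5 : 1.0);
  case 'T': return s == 'A' ? 0.0 : (s == 'G' ? 0.5 : 1.0);
  default: return 1.0;
  }
}

static inline double wt(int pos1based, int core_lo, int core_hi) {
  return (pos1based >= core_lo && pos1based <= core_hi) ? 2.0 : 1.0;
}

// score one window; site given 5'->3', miRNA position i pairs site position
// Ls - i + 1. gap_mode: 0 = ungapped (Ls == Lm), 1 = gap in miRNA (site
// bulge, Ls == Lm + 1), 2 = gap in site (Ls == Lm - 1). Returns min over gap
// placements.
static double score_site(const std::string& mi, const std::string& site,
                         double mismatch, double wobble, double gap,
                         int core_lo, int core_hi) {
  int lm = mi.size(), ls = site.size();
  auto s3 = [&](int k) { return site[ls - k]; }; // k-th base from 3' end (1-based)
  if (ls == lm) {
    double sc = 0.0;
    for (int i = 1; i <= lm; ++i) {
      double p = base_pen(mi[i - 1], s3(i));
      if (p == 1.0) p = mismatch; else if (p == 0.5) p = wobble;
      sc += p * wt(i, core_lo, core_hi);
    }
    return sc;
  }
  double best = R_PosInf;
  if (ls == lm + 1) {
    for (int g = 1; g <= ls; ++g) {
      double sc = 0.0;
      for (int k = 1; k <= ls; ++k) {
        if (k == g) {
          int pos = std::min(k, lm);
          sc += gap * wt(pos, core_lo, core_hi);
        } else {
          int i = (k < g) ? k : k - 1;
          double p = base_pen(mi[i - 1], s3(k));
          if (p == 1.0) p = mismatch; else if (p == 0.5) p = wobble;
          sc += p * wt(i, core_lo, core_hi);
        }
        if (sc >= best) break;
      }
      if (sc < best) best = sc;
    }
  } else if (ls == lm - 1) {
    for (int g = 1; g <= lm; ++g) {
      double sc = 0.0;
      for (int i = 1; i <= lm; ++i) {
        if (i == g) {
          sc += gap * wt(i, core_lo, core_hi);
        } else {
          int k = (i < g) ? i : i - 1;
          double p = base_pen(mi[i - 1], s3(k));
          if (p == 1.0) p = mismatch; else if (p == 0.5) p = wobble;
          sc += p * wt(i, core_lo, core_hi);
        }
        if (sc >= best) break;
      }
      if (sc < best) best = sc;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".scan_targets_cpp")]]
DataFrame scan_targets_cpp(std::string mirna, std::string transcript,
                           double cutoff, double mismatch, double wobble,
                           double gap, int core_lo, int core_hi) {
  int lm = mirna.size(), lt = transcript.size();
  std::vector<int> starts, ends;
  std::vector<double> scores;
  for (int len = lm - 1; len <= lm + 1; ++len) {
    if (len < 1) continue;
    for (int s = 0; s + len <= lt; ++s) {
      std::string site = transcript.substr(s, len);
      double sc = score_site(mirna, site, mismatch, wobble, gap,
                             core_lo, core_hi);
      if (sc <= cutoff + 1e-9) {
        starts.push_back(s);
        ends.push_back(s + len);
        scores.push_back(sc);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["score"] = scores);
}
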