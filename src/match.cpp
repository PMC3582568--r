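#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Bounded-mismatch end-to-end matching of tags against mature miRNA
// sequences: tag and mature are aligned ungapped at a small terminal offset;
// the total overhang (trimmed/extended terminal bases on both sequences)
// must not exceed max_end, and substitutions within the overlap must not
// exceed max_mm. Returns, per tag, the index (1-based) of the best-matching
// mature (fewest substitutions, ties to the lexicographically smallest id)
// and the substitution count, or 0 when no mature qualifies.

// [[Rcpp::export(name = ".match_mature_cpp")]]
IntegerMatrix match_mature_cpp(CharacterVector tags, CharacterVector matures,
                               CharacterVector mature_ids, int max_mm,
                               int max_end) {
  int nt = tags.size(), nm = matures.size();
  IntegerMatrix out(nt, 2); // col 0: 1-based mature index (0 = none), col 1: mm
  std::vector<std::string> mat(nm), ids(nm);
  for (int m = 0; m < nm; ++m) {
    mat[m] = as<std::string>(matures[m]);
    ids[m] = as<std::string>(mature_ids[m]);
  }
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    int lt = tag.size();
    int best_mm = max_mm + 1;
    int best_idx = -1;
    for (int m = 0; m < nm; ++m) {
      const std::string& ms = mat[m];
      int lm = ms.size();
      int local_best = max_mm + 1;
      // offset d: tag position 0 aligns with mature position d
      for (int d = -max_end; d <= max_end; ++d) {
        int lo_t = std::max(0, -d);          // first tag index in overlap
        int lo_m = std::max(0, d);           // first mature index in overlap
        int ov = std::min(lt - lo_t, lm - lo_m);
        if (ov <= 0) continue;
        int overhang = (lt - ov) + (lm - ov);
        if (overhang > max_end) continue;
        int mm = 0;
        for (int k = 0; k < ov && mm <= max_mm; ++k) {
          if (tag[lo_t + k] != ms[lo_m + k]) ++mm;
        }
        if (mm < local_best) local_best = mm;
      }
      if (local_best <= max_mm) {
        if (local_best < best_mm ||
            (local_best == best_mm && best_idx >= 0 && ids[m] < ids[best_idx])) {
          best_mm = local_best;
          best_idx = m;
        }
      }
    }
    if (best_idx >= 0) {
      out(t, 0) = best_idx + 1;
      out(t, 1) = best_mm;
    }
  }
  return out;
}
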