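#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning: reduces a mask to a 1-px-wide 8-connected
// skeleton.  Pixels outside the image count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix M(clone(img));
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return M(r, c) ? 1 : 0;
  };
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!M(r, c)) continue;
          int p2 = P(r - 1, c),     p3 = P(r - 1, c + 1),
              p4 = P(r, c + 1),     p5 = P(r + 1, c + 1),
              p6 = P(r + 1, c),     p7 = P(r + 1, c - 1),
              p8 = P(r, c - 1),     p9 = P(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k)
        M(del[k].first, del[k].second) = false;
    }
  }
  return M;
}
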