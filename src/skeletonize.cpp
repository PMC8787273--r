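#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary mask down to a 1-px
// medial line. Operates on a padded copy; neighbours are indexed
// clockwise from north (p2..p9). Row index increases downwards.
//
// Deletion conditions per sub-iteration:
//   1: 2 <= B <= 6, A == 1, p2*p4*p6 == 0, p4*p6*p8 == 0
//   2: 2 <= B <= 6, A == 1, p2*p4*p8 == 0, p2*p6*p8 == 0
// where B = number of set neighbours and A = number of 0->1 transitions
// in the circular sequence p2, p3, ..., p9, p2.

// [[Rcpp::export(name = ".thin_zs")]]
LogicalMatrix thin_zs(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int pr = nr + 2, pc = nc + 2;
  std::vector<unsigned char> p(static_cast<size_t>(pr) * pc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) p[(size_t)(j + 1) * pr + (i + 1)] = 1;

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 1; j <= nc; ++j) {
        const size_t col = (size_t)j * pr;
        for (int i = 1; i <= nr; ++i) {
          const size_t k = col + i;
          if (!p[k]) continue;
          const unsigned char p2 = p[k - 1];            // N
          const unsigned char p3 = p[k + pr - 1];       // NE
          const unsigned char p4 = p[k + pr];           // E
          const unsigned char p5 = p[k + pr + 1];       // SE
          const unsigned char p6 = p[k + 1];            // S
          const unsigned char p7 = p[k - pr + 1];       // SW
          const unsigned char p8 = p[k - pr];           // W
          const unsigned char p9 = p[k - pr - 1];       // NW
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          A += (!p2 && p3) + (!p3 && p4) + (!p4 && p5) + (!p5 && p6);
          A += (!p6 && p7) + (!p7 && p8) + (!p8 && p9) + (!p9 && p2);
          if (A != 1) continue;
          if (step == 0) {
            if ((p2 && p4 && p6) || (p4 && p6 && p8)) continue;
          } else {
            if ((p2 && p4 && p8) || (p2 && p6 && p8)) continue;
          }
          kill.push_back(k);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k : kill) p[k] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = p[(size_t)(j + 1) * pr + (i + 1)] != 0;
  return out;
}
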