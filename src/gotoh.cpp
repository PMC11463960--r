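#include <Rcpp.h>
#include <string>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Affine-gap semi-global alignment (Gotoh): the read is aligned end to
// end, gaps at either end of the reference are free. A gap of length L
// costs gap_open + L * gap_ext. Ties prefer the diagonal (match or
// mismatch) over gaps; indel placement is left-normalized downstream,
// so the residual gap tie-break is immaterial to called edits.
//
// Returns score, ref_start (0-based first consumed reference base) and
// the run-length encoded alignment operations over columns:
// M (align), I (read base absent from reference), D (reference base
// absent from read).
// [[Rcpp::export(name = ".gotoh_semiglobal")]]
List gotoh_semiglobal(const std::string& read, const std::string& ref,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int n = read.size(), m = ref.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state matrices, (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> Ix((n + 1) * (m + 1), NEG); // gap in ref (read insertion)
  std::vector<double> Iy((n + 1) * (m + 1), NEG); // gap in read (deletion)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) M[at(0, j)] = 0.0;   // free leading ref bases
  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    for (int j = 0; j <= m; ++j) {
      if (j > 0) {
        const char fc = ref[j - 1];
        // N never matches anything, itself included
        double s = (rc == fc && rc != 'N') ? match : mismatch;
        double best = M[at(i - 1, j - 1)];
        if (Ix[at(i - 1, j - 1)] > best) best = Ix[at(i - 1, j - 1)];
        if (Iy[at(i - 1, j - 1)] > best) best = Iy[at(i - 1, j - 1)];
        if (best > NEG) M[at(i, j)] = best + s;
        double dOpen = M[at(i, j - 1)] - (gap_open + gap_ext);
        double dExt = Iy[at(i, j - 1)] - gap_ext;
        Iy[at(i, j)] = dOpen > dExt ? dOpen : dExt;
      }
      double iOpen = M[at(i - 1, j)] - (gap_open + gap_ext);
      double iExt = Ix[at(i - 1, j)] - gap_ext;
      Ix[at(i, j)] = iOpen > iExt ? iOpen : iExt;
    }
  }
  // best end column: trailing reference bases are free
  int bestJ = 0, bestState = 0; // 0 = M, 1 = Ix
  double best = NEG;
  for (int j = 0; j <= m; ++j) {
    if (M[at(n, j)] > best) { best = M[at(n, j)]; bestJ = j; bestState = 0; }
    if (Ix[at(n, j)] > best) { best = Ix[at(n, j)]; bestJ = j; bestState = 1; }
  }
  if (best == NEG) stop("alignment failed");
  // traceback
  std::string ops;
  int i = n, j = bestJ, state = bestState;
  const double EPS = 1e-9;
  while (i > 0) {
    if (state == 0) { // M column
      const char rc = read[i - 1], fc = ref[j - 1];
      double s = (rc == fc && rc != 'N') ? match : mismatch;
      double v = M[at(i, j)] - s;
      ops.push_back('M');
      if (std::fabs(M[at(i - 1, j - 1)] - v) < EPS) state = 0;
      else if (std::fabs(Ix[at(i - 1, j - 1)] - v) < EPS) state = 1;
      else if (std::fabs(Iy[at(i - 1, j - 1)] - v) < EPS) state = 2;
      else stop("traceback error (M)");
      --i; --j;
    } else if (state == 1) { // Ix: read base against a gap in the ref
      ops.push_back('I');
      if (std::fabs(M[at(i - 1, j)] - (gap_open + gap_ext) - Ix[at(i, j)]) < EPS) {
        state = 0;
      }
      --i;
    } else { // Iy: ref base against a gap in the read
      ops.push_back('D');
      if (std::fabs(M[at(i, j - 1)] - (gap_open + gap_ext) - Iy[at(i, j)]) < EPS) {
        state = 0;
      }
      --j;
    }
  }
  int ref_start = j;
  // run-length encode the reversed ops
  std::vector<int> lens;
  std::vector<std::string> vals;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    char c = ops[k];
    if (!vals.empty() && vals.back()[0] == c) ++lens.back();
    else { vals.push_back(std::string(1, c)); lens.push_back(1); }
  }
  return List::create(_["score"] = best, _["ref_start"] = ref_start,
                      _["lengths"] = wrap(lens), _["values"] = wrap(vals));
}
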