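#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <climits>
using namespace Rcpp;

// Banded semiglobal affine-gap alignment of a read against a candidate
// window of graph-walk sequence: the read aligns end to end, the window may
// be entered and left anywhere (free leading/trailing window bases).
// Scoring: match/mismatch substitution scores, affine gaps (open includes
// the first extension).
//
// Returns ref_start/ref_end (0-based half-open window span of the
// alignment), the score, the number of matched bases, and run-length edit
// operations (0 = match/mismatch consuming both, 1 = insertion in the read,
// 2 = deletion in the read, i.e. skipped window bases).

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_band_align(std::string read, std::string ref, int band,
                    int match = 1, int mismatch = -4,
                    int gap_open = -6, int gap_extend = -1) {
  const int n = (int)read.size(), m = (int)ref.size();
  const int W = 2 * band + 1; // window positions j in [i, i + 2*band]
  if (n == 0 || m == 0)
    return List::create(_["score"] = NEG, _["ref_start"] = 0, _["ref_end"] = 0,
                        _["nmatch"] = 0, _["ops"] = IntegerVector(0),
                        _["lens"] = IntegerVector(0));
  // layers: M (diag), X (gap in ref: read insertion), Y (gap in read)
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<unsigned char> tbM((n + 1) * W, 0), tbX((n + 1) * W, 0), tbY((n + 1) * W, 0);
  auto idx = [&](int i, int j) { return i * W + (j - i); };
  auto inband = [&](int i, int j) { return j >= i && j <= i + 2 * band && j >= 0 && j <= m; };
  // i = 0: any window start is free
  for (int j = 0; j <= std::min(m, 2 * band); ++j) M[idx(0, j)] = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = i; j <= std::min(m, i + 2 * band); ++j) {
      int best;
      unsigned char tb;
      // M: consume read[i-1] vs ref[j-1]
      if (j >= 1 && inband(i - 1, j - 1)) {
        int p = idx(i - 1, j - 1);
        int prev = std::max(M[p], std::max(X[p], Y[p]));
        if (prev > NEG) {
          int sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
          best = prev + sub;
          tb = (M[p] >= X[p] && M[p] >= Y[p]) ? 0 : (X[p] >= Y[p] ? 1 : 2);
          M[idx(i, j)] = best;
          tbM[idx(i, j)] = tb;
        }
      }
      // X: gap in ref (consume read[i-1])
      if (inband(i - 1, j)) {
        int p = idx(i - 1, j);
        int open_from = std::max(M[p], Y[p]);
        int o = (open_from > NEG) ? open_from + gap_open : NEG;
        int e = (X[p] > NEG) ? X[p] + gap_extend : NEG;
        if (o > NEG || e > NEG) {
          X[idx(i, j)] = std::max(o, e);
          tbX[idx(i, j)] = (o >= e) ? (M[p] >= Y[p] ? 0 : 2) : 1;
        }
      }
      // Y: gap in read (consume ref[j-1])
      if (j >= 1 && inband(i, j - 1)) {
        int p = idx(i, j - 1);
        int open_from = std::max(M[p], X[p]);
        int o = (open_from > NEG) ? open_from + gap_open : NEG;
        int e = (Y[p] > NEG) ? Y[p] + gap_extend : NEG;
        if (o > NEG || e > NEG) {
          Y[idx(i, j)] = std::max(o, e);
          tbY[idx(i, j)] = (o >= e) ? (M[p] >= X[p] ? 0 : 1) : 2;
        }
      }
    }
  }
  // best end: free trailing window bases -> max over j at i = n (M or X only;
  // ending in Y would mean a trailing read deletion, equivalent to ending earlier)
  int best = NEG, bj = -1, blayer = 0;
  for (int j = n; j <= std::min(m, n + 2 * band); ++j) {
    if (M[idx(n, j)] > best) { best = M[idx(n, j)]; bj = j; blayer = 0; }
    if (X[idx(n, j)] > best) { best = X[idx(n, j)]; bj = j; blayer = 1; }
  }
  if (best <= NEG || bj < 0)
    return List::create(_["score"] = NA_INTEGER, _["ref_start"] = 0, _["ref_end"] = 0,
                        _["nmatch"] = 0, _["ops"] = IntegerVector(0),
                        _["lens"] = IntegerVector(0));
  // traceback
  std::vector<int> ops_rev;
  int i = n, j = bj, layer = blayer, nmatch = 0;
  while (i > 0) {
    if (layer == 0) {
      unsigned char tb = tbM[idx(i, j)];
      if (read[i - 1] == ref[j - 1]) ++nmatch;
      ops_rev.push_back(0);
      --i; --j; layer = tb;
    } else if (layer == 1) {
      unsigned char tb = tbX[idx(i, j)];
      ops_rev.push_back(1);
      --i; layer = tb;
    } else {
      unsigned char tb = tbY[idx(i, j)];
      ops_rev.push_back(2);
      --j; layer = tb;
    }
  }
  int ref_start = j, ref_end = bj;
  // run-length encode (in forward order)
  IntegerVector ops, lens;
  std::vector<int> o2, l2;
  for (int k = (int)ops_rev.size() - 1; k >= 0; --k) {
    int op = ops_rev[k];
    if (!o2.empty() && o2.back() == op) {
      ++l2.back();
    } else {
      o2.push_back(op);
      l2.push_back(1);
    }
  }
  return List::create(_["score"] = best, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["nmatch"] = nmatch,
                      _["ops"] = wrap(o2), _["lens"] = wrap(l2));
}
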