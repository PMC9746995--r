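#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Glocal (semi-global) affine-gap alignment: the read is aligned end to
// end, reference end-gaps are free. Gap of length L costs
// gap_open + L * gap_extend. States: M (diagonal), X (gap in read, ref
// consumed, CIGAR D), Y (gap in ref, read consumed, CIGAR I).
// Deterministic tie-breaking: smallest end position on the reference,
// traceback preferring M, then X, then Y.

// [[Rcpp::export]]
List glocal_align_cpp(std::string read, std::string ref,
                      int match = 1, int mismatch = -1,
                      int gap_open = -4, int gap_extend = -1) {
  const int m = (int)read.size();
  const int n = (int)ref.size();
  if (m == 0) stop("empty read");
  if (n == 0) stop("empty reference");
  const int NEG = -1000000000;
  const int W = n + 1;

  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
      Y((m + 1) * W, NEG);
  // traceback: tbM = predecessor state of the diagonal move (0=M,1=X,2=Y)
  // tbX/tbY: 0 = opened from M, 1 = extended
  std::vector<unsigned char> tbM((m + 1) * W, 0), tbX((m + 1) * W, 0),
      tbY((m + 1) * W, 0);

  for (int j = 0; j <= n; ++j) M[j] = 0;  // free leading reference gap
  for (int i = 1; i <= m; ++i) {          // read hanging off the ref start
    Y[i * W] = gap_open + i * gap_extend;
    tbY[i * W] = (i == 1) ? 0 : 1;        // opened from M[0][0], then extended
  }

  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1);
      const int s = (rc == ref[j - 1]) ? match : mismatch;
      int best = M[dg]; unsigned char st = 0;
      if (X[dg] > best) { best = X[dg]; st = 1; }
      if (Y[dg] > best) { best = Y[dg]; st = 2; }
      M[idx] = (best <= NEG / 2) ? NEG : best + s;
      tbM[idx] = st;

      const int lf = i * W + (j - 1);
      int xo = (M[lf] <= NEG / 2) ? NEG : M[lf] + gap_open + gap_extend;
      int xe = (X[lf] <= NEG / 2) ? NEG : X[lf] + gap_extend;
      if (xo >= xe) { X[idx] = xo; tbX[idx] = 0; }
      else          { X[idx] = xe; tbX[idx] = 1; }

      const int up = (i - 1) * W + j;
      int yo = (M[up] <= NEG / 2) ? NEG : M[up] + gap_open + gap_extend;
      int ye = (Y[up] <= NEG / 2) ? NEG : Y[up] + gap_extend;
      if (yo >= ye) { Y[idx] = yo; tbY[idx] = 0; }
      else          { Y[idx] = ye; tbY[idx] = 1; }
    }
  }

  // best over the last row (read fully consumed), smallest j wins ties
  int best = NEG, bj = 0, bstate = 0;
  for (int j = 0; j <= n; ++j) {
    const int idx = m * W + j;
    if (M[idx] > best) { best = M[idx]; bj = j; bstate = 0; }
    if (Y[idx] > best) { best = Y[idx]; bj = j; bstate = 2; }
  }

  // traceback
  std::string ops;
  int i = m, j = bj, state = bstate;
  while (i > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      if (j == 0) stop("traceback error");
      ops.push_back('M');
      state = tbM[idx];
      --i; --j;
    } else if (state == 1) {
      ops.push_back('D');
      state = (tbX[idx] == 0) ? 0 : 1;
      --j;
    } else {
      ops.push_back('I');
      state = (tbY[idx] == 0) ? 0 : 2;
      --i;
    }
  }
  const int ref_start = j;

  // run-length encode the reversed op string into CIGAR
  std::string cigar;
  int run = 0; char cur = 0;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    if (ops[k] == cur) ++run;
    else {
      if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }
      cur = ops[k]; run = 1;
    }
  }
  if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }

  return List::create(_["score"] = best, _["ref_start"] = ref_start,
                      _["cigar"] = cigar);
}
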