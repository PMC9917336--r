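#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global alignment of a read against a template under unit edit costs,
// template 'N' matching any read base at zero cost. Among minimum-edit
// alignments an infinitesimal gap-opening surcharge (1/SCALE of one edit)
// selects the alignment with the fewest gap runs, so a single long deletion
// is preferred over scattered equal-cost placements (substitutions beat
// paired indels the same way: one substitution carries no opening
// surcharge). Remaining ties place gap runs at their rightmost equivalent
// position, which pins a chimeric deletion at the ligatable nick instead of
// letting it slide through zero-cost wildcard columns. Affine three-state
// recursion (Gotoh).
//
// Returns the edit cost (number of substitutions + insertions + deletions)
// and the edit script:
//   op:   0 match, 1 substitution, 2 deletion, 3 insertion, 4 N-fill
//   tpos: 1-based template position (for insertion: template positions
//         consumed before the inserted base)
//   base: read base (substitution/insertion/N-fill) or template base
//         (deletion)
// [[Rcpp::export]]
List align_nw_cpp(std::string read, std::string tmpl) {
  const int m = (int) read.size();
  const int n = (int) tmpl.size();
  const long SCALE = 4096;          // > any possible gap-opening count
  const long EDIT = SCALE;
  const long OPEN = SCALE + 1;      // gap extension + opening surcharge
  const long INF = (long) 1 << 60;
  const int W = m + 1;
  std::vector<long> M((size_t)(n + 1) * W, INF);
  std::vector<long> X((size_t)(n + 1) * W, INF);  // ends in insertion
  std::vector<long> Y((size_t)(n + 1) * W, INF);  // ends in deletion
  // pointer low 2 bits: predecessor state (0 M, 1 Y, 2 X)
  std::vector<unsigned char> PM((size_t)(n + 1) * W), PX((size_t)(n + 1) * W),
      PY((size_t)(n + 1) * W);
  M[0] = 0;
  for (int j = 1; j <= m; ++j) {
    X[j] = OPEN + (long)(j - 1) * EDIT;
    PX[j] = 2;
    PX[1] = 0;
  }
  for (int i = 1; i <= n; ++i) {
    Y[(size_t)i * W] = OPEN + (long)(i - 1) * EDIT;
    PY[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    const char tc = tmpl[i - 1];
    const bool wild = (tc == 'N');
    const size_t row = (size_t)i * W, prev = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const long s = (wild || read[j - 1] == tc) ? 0 : EDIT;
      // Tie preferences push gap runs to their rightmost equivalent
      // placement: entering a gap is preferred over continuing matches
      // when tracing back (see note above the function).
      // M: diagonal from best of three states (tie order Y, X, M)
      long best = Y[prev + j - 1]; unsigned char p = 1;
      if (X[prev + j - 1] < best) { best = X[prev + j - 1]; p = 2; }
      if (M[prev + j - 1] < best) { best = M[prev + j - 1]; p = 0; }
      M[row + j] = best + s; PM[row + j] = p;
      // Y: deletion (consume template); tie order Y, M, X
      best = Y[prev + j] + EDIT; p = 1;
      if (M[prev + j] + OPEN < best) { best = M[prev + j] + OPEN; p = 0; }
      if (X[prev + j] + OPEN < best) { best = X[prev + j] + OPEN; p = 2; }
      Y[row + j] = best; PY[row + j] = p;
      // X: insertion (consume read); tie order X, M, Y
      best = X[row + j - 1] + EDIT; p = 2;
      if (M[row + j - 1] + OPEN < best) { best = M[row + j - 1] + OPEN; p = 0; }
      if (Y[row + j - 1] + OPEN < best) { best = Y[row + j - 1] + OPEN; p = 1; }
      X[row + j] = best; PX[row + j] = p;
    }
  }
  // traceback: prefer Y (deletion), then X (insertion), then M
  size_t end = (size_t)n * W + m;
  int state = 1;
  long best = Y[end];
  if (X[end] < best) { best = X[end]; state = 2; }
  if (M[end] < best) { best = M[end]; state = 0; }
  std::vector<int> op, tpos;
  std::vector<char> base;
  int i = n, j = m;
  int nedit = 0;
  while (i > 0 || j > 0) {
    const size_t cur = (size_t)i * W + j;
    if (state == 0) {
      const char tc = tmpl[i - 1], rc = read[j - 1];
      if (tc == 'N') { op.push_back(4); base.push_back(rc); }
      else if (tc != rc) { op.push_back(1); base.push_back(rc); ++nedit; }
      else { op.push_back(0); base.push_back(rc); }
      tpos.push_back(i);
      state = PM[cur]; --i; --j;
    } else if (state == 1) {
      op.push_back(2); tpos.push_back(i); base.push_back(tmpl[i - 1]);
      ++nedit;
      state = PY[cur]; --i;
    } else {
      op.push_back(3); tpos.push_back(i); base.push_back(read[j - 1]);
      ++nedit;
      state = PX[cur]; --j;
    }
  }
  const int K = (int) op.size();
  IntegerVector op_out(K), tpos_out(K);
  CharacterVector base_out(K);
  for (int k = 0; k < K; ++k) {
    op_out[k] = op[K - 1 - k];
    tpos_out[k] = tpos[K - 1 - k];
    base_out[k] = std::string(1, base[K - 1 - k]);
  }
  return List::create(_["cost"] = nedit,
                      _["op"] = op_out,
                      _["tpos"] = tpos_out,
                      _["base"] = base_out);
}
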