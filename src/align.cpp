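#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). q and s are
// 0-based indices into the rows/cols of the substitution matrix `sub`.
// A gap of length L costs gap_open + L * gap_extend (BLAST convention).
// Returns the single best-scoring local alignment: its raw score and the
// 1-based spans on query and subject (NA spans when the best score is 0).
// [[Rcpp::export(name = ".cpp_sw_affine")]]
List cpp_sw_affine(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                   int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int NEG = INT_MIN / 4;
  const int open_cost = gap_open + gap_extend;

  // full DP matrices for traceback; (m+1) x (n+1)
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG); // gap in query (move along subject)
  std::vector<int> F((m + 1) * (n + 1), NEG); // gap in subject (move along query)
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(E[idx(i, j - 1)] - gap_extend, H[idx(i, j - 1)] - open_cost);
      int f = std::max(F[idx(i - 1, j)] - gap_extend, H[idx(i - 1, j)] - open_cost);
      int d = H[idx(i - 1, j - 1)] + sub(q[i - 1], s[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0,
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["sstart"] = NA_INTEGER, _["send"] = NA_INTEGER);
  }

  // traceback from (bi, bj) until H == 0
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (left), 2 = F (up)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[idx(i, j)];
      if (h == 0) break;
      if (h == H[idx(i - 1, j - 1)] + sub(q[i - 1], s[j - 1])) { --i; --j; continue; }
      if (h == E[idx(i, j)]) { state = 1; continue; }
      state = 2;
      continue;
    } else if (state == 1) {
      int e = E[idx(i, j)];
      if (e == H[idx(i, j - 1)] - open_cost) { --j; state = 0; }
      else { --j; } // extended gap, stay in E
      continue;
    } else {
      int f = F[idx(i, j)];
      if (f == H[idx(i - 1, j)] - open_cost) { --i; state = 0; }
      else { --i; }
      continue;
    }
  }

  return List::create(_["score"] = best,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj);
}
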