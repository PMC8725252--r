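#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps (Gotoh) of a query
// against a target, scored by base-pair complementarity. The query is the
// reversed miRNA so that left-to-right alignment columns read 5'->3' on the
// target and 3'->5' on the miRNA (antiparallel duplex). Per-query-position
// weights implement seed-region up-weighting.
//
// Gap cost: first gap base gap_open, each further base gap_extend
// (both negative).

static inline double pair_base_score(char q, char t, double match,
                                     double wobble, double mismatch) {
  // q and t are RNA bases; complementary pairing between strands
  if ((q == 'A' && t == 'U') || (q == 'U' && t == 'A') ||
      (q == 'G' && t == 'C') || (q == 'C' && t == 'G'))
    return match;
  if ((q == 'G' && t == 'U') || (q == 'U' && t == 'G'))
    return wobble;
  return mismatch;
}

// [[Rcpp::export(name = ".cpp_best_local_duplex")]]
List cpp_best_local_duplex(std::string query, std::string target,
                           NumericVector qweight, double match,
                           double wobble, double mismatch,
                           double gap_open, double gap_extend) {
  const int m = query.size(), n = target.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0);
  const double NEG = -1e30;
  // DP matrices, (m+1) x (n+1), row-major
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> Ix((m + 1) * (n + 1), NEG); // gap in target (q aligned to -)
  std::vector<double> Iy((m + 1) * (n + 1), NEG); // gap in query  (t aligned to -)
  std::vector<signed char> ptrM((m + 1) * (n + 1), 0);  // 0 start,1 M,2 Ix,3 Iy
  std::vector<signed char> ptrX((m + 1) * (n + 1), 0);  // 1 from M, 2 extend
  std::vector<signed char> ptrY((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // gap states
      double xo = M[at(i - 1, j)] + gap_open;
      double xe = Ix[at(i - 1, j)] + gap_extend;
      if (xo >= xe) { Ix[at(i, j)] = xo; ptrX[at(i, j)] = 1; }
      else          { Ix[at(i, j)] = xe; ptrX[at(i, j)] = 2; }
      double yo = M[at(i, j - 1)] + gap_open;
      double ye = Iy[at(i, j - 1)] + gap_extend;
      if (yo >= ye) { Iy[at(i, j)] = yo; ptrY[at(i, j)] = 1; }
      else          { Iy[at(i, j)] = ye; ptrY[at(i, j)] = 2; }
      // match state
      double s = qweight[i - 1] *
        pair_base_score(query[i - 1], target[j - 1], match, wobble, mismatch);
      double dM = M[at(i - 1, j - 1)], dX = Ix[at(i - 1, j - 1)],
             dY = Iy[at(i - 1, j - 1)];
      double prev = 0.0;
      signed char p = 0;
      if (dM > prev) { prev = dM; p = 1; }
      if (dX > prev) { prev = dX; p = 2; }
      if (dY > prev) { prev = dY; p = 3; }
      double v = prev + s;
      if (v < 0.0) { v = 0.0; p = 0; }
      M[at(i, j)] = v;
      ptrM[at(i, j)] = p;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);

  // traceback from (bi, bj) in state M
  std::string qa, ta;
  int i = bi, j = bj, state = 1; // 1 M, 2 Ix, 3 Iy
  while (true) {
    if (state == 1) {
      signed char p = ptrM[at(i, j)];
      qa.push_back(query[i - 1]);
      ta.push_back(target[j - 1]);
      --i; --j;
      if (p == 0) break;
      state = p;
    } else if (state == 2) {
      signed char p = ptrX[at(i, j)];
      qa.push_back(query[i - 1]);
      ta.push_back('-');
      --i;
      state = (p == 1) ? 1 : 2;
    } else {
      signed char p = ptrY[at(i, j)];
      qa.push_back('-');
      ta.push_back(target[j - 1]);
      --j;
      state = (p == 1) ? 1 : 3;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = best,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["tstart"] = j + 1, _["tend"] = bj,
                      _["qaln"] = qa, _["taln"] = ta);
}
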