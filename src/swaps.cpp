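#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Checkerboard-swap Markov chain on a binary matrix. Proposals pick two
// 1-entries ("edges") uniformly at random; when they sit in distinct rows
// and columns and the opposite corners of their 2x2 submatrix are 0, the
// checkerboard pattern is swapped for the other one. Every accepted swap
// preserves all row and column sums exactly; rejected proposals make the
// chain aperiodic. Uses R's RNG, so set.seed() gives reproducibility.

// [[Rcpp::export]]
IntegerMatrix checkerboard_swap_cpp(const IntegerMatrix& m, int n_steps) {
  IntegerMatrix x = clone(m);
  const int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2 || n_steps <= 0) return x;
  std::vector<int> er, ec;
  er.reserve(nr * nc / 4); ec.reserve(nr * nc / 4);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (x(i, j) == 1) { er.push_back(i); ec.push_back(j); }
  const int ne = static_cast<int>(er.size());
  if (ne < 2) return x;
  for (int s = 0; s < n_steps; ++s) {
    int e1 = static_cast<int>(unif_rand() * ne); if (e1 == ne) e1 = ne - 1;
    int e2 = static_cast<int>(unif_rand() * ne); if (e2 == ne) e2 = ne - 1;
    const int i1 = er[e1], j1 = ec[e1], i2 = er[e2], j2 = ec[e2];
    if (i1 == i2 || j1 == j2) continue;
    if (x(i1, j2) == 1 || x(i2, j1) == 1) continue;
    x(i1, j1) = 0; x(i2, j2) = 0; x(i1, j2) = 1; x(i2, j1) = 1;
    ec[e1] = j2; ec[e2] = j1;
  }
  return x;
}
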