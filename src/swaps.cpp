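#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard (data-stream) swap chain on a binary presence matrix.
// Each successful swap picks two rows and two columns whose 2x2 submatrix is
// [[1,0],[0,1]] or [[0,1],[1,0]] and flips it, preserving all row and column
// sums. Runs until n_swaps successes or max_attempts proposals, whichever
// comes first. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
IntegerMatrix cb_swap_chain(IntegerMatrix m, int n_swaps, double max_attempts) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2)
    stop("presence matrix needs at least 2 rows and 2 columns");
  long long done = 0, attempts = 0;
  long long cap = (long long)max_attempts;
  while (done < n_swaps && attempts < cap) {
    attempts++;
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if ((a == 1 && d == 1 && b == 0 && c == 0) ||
        (a == 0 && d == 0 && b == 1 && c == 1)) {
      out(r1, c1) = 1 - a;
      out(r1, c2) = 1 - b;
      out(r2, c1) = 1 - c;
      out(r2, c2) = 1 - d;
      done++;
    }
  }
  out.attr("swaps_done") = (double)done;
  out.attr("attempts") = (double)attempts;
  return out;
}
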