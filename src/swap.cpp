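#include <Rcpp.h>
using namespace Rcpp;

// xorshift64* PRNG: fast, seedable, identical across platforms, independent
// of R's RNG stream so the swap chain is a pure function of `seed`.
static inline uint64_t xorshift64star(uint64_t &state) {
  state ^= state >> 12;
  state ^= state << 25;
  state ^= state >> 27;
  return state * 2685821657736338717ULL;
}

static inline int rand_below(uint64_t &state, int n) {
  return (int)(xorshift64star(state) % (uint64_t)n);
}

// Attempt `n_swaps` checkerboard flips on a binary matrix (rows x cols).
// Each attempt samples two distinct rows and two distinct columns; if the
// 2x2 submatrix is a checkerboard it is flipped, preserving all row and
// column sums exactly. Returns the randomized matrix; the number of
// successful swaps is attached as attribute "successes".
// [[Rcpp::export]]
IntegerMatrix cpp_independent_swap(IntegerMatrix m, int n_swaps, double seed) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2) {
    out.attr("successes") = 0;
    return out;
  }
  uint64_t state = (uint64_t)seed * 2654435761ULL + 1442695040888963407ULL;
  // warm up
  for (int i = 0; i < 8; ++i) xorshift64star(state);
  int successes = 0;
  for (int s = 0; s < n_swaps; ++s) {
    int r1 = rand_below(state, nr);
    int r2 = rand_below(state, nr - 1);
    if (r2 >= r1) ++r2;
    int c1 = rand_below(state, nc);
    int c2 = rand_below(state, nc - 1);
    if (c2 >= c1) ++c2;
    int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == d && b == c && a != b) {
      out(r1, c1) = b; out(r1, c2) = a;
      out(r2, c1) = d; out(r2, c2) = c;
      ++successes;
    }
  }
  out.attr("successes") = successes;
  return out;
}
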