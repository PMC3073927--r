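#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Maximal-length Fibonacci LFSR tap positions (1-indexed bit numbers) for
// register widths 2..32, from the classic Xilinx application-note table of
// primitive feedback polynomials. Each gives period 2^k - 1 over the
// non-zero states.
static const int TAPS[33][5] = {
    {0}, {0},
    {2, 2, 1, 0, 0},  {2, 3, 2, 0, 0},  {2, 4, 3, 0, 0},  {2, 5, 3, 0, 0},
    {2, 6, 5, 0, 0},  {2, 7, 6, 0, 0},  {4, 8, 6, 5, 4},  {2, 9, 5, 0, 0},
    {2, 10, 7, 0, 0}, {2, 11, 9, 0, 0}, {4, 12, 6, 4, 1}, {4, 13, 4, 3, 1},
    {4, 14, 5, 3, 1}, {2, 15, 14, 0, 0},{4, 16, 15, 13, 4},{2, 17, 14, 0, 0},
    {2, 18, 11, 0, 0},{4, 19, 6, 2, 1}, {2, 20, 17, 0, 0},{2, 21, 19, 0, 0},
    {2, 22, 21, 0, 0},{2, 23, 18, 0, 0},{4, 24, 23, 22, 17},{2, 25, 22, 0, 0},
    {4, 26, 6, 2, 1}, {4, 27, 5, 2, 1}, {2, 28, 25, 0, 0},{2, 29, 27, 0, 0},
    {4, 30, 6, 4, 1}, {2, 31, 28, 0, 0},{4, 32, 22, 2, 1}
};

static inline uint64_t lfsr_step(uint64_t state, int k) {
    // right-shift Fibonacci form: tap position p contributes bit (k - p)
    const int *t = TAPS[k];
    uint64_t bit = 0;
    for (int i = 1; i <= t[0]; ++i) bit ^= (state >> (k - t[i]));
    bit &= 1u;
    return (state >> 1) | (bit << (k - 1));
}

static int width_for(double n) {
    int k = 2;
    while (k <= 32 && (std::pow(2.0, k) - 1.0) < n) ++k;
    return k;
}

//' @noRd
// [[Rcpp::export]]
Rcpp::NumericVector lfsr_take_cpp(double n, double m) {
    if (n < 1) Rcpp::stop("n must be >= 1");
    if (n > 4294967295.0) Rcpp::stop("index space exceeds the 32-bit LFSR range");
    if (n == 1) {
        Rcpp::NumericVector one((int)std::min(m, 1.0));
        if (one.size() > 0) one[0] = 1.0;
        return one;
    }
    int k = width_for(n);
    uint64_t nn = (uint64_t)n;
    R_xlen_t want = (R_xlen_t)std::min(m, n);
    Rcpp::NumericVector out(want);
    uint64_t state = 1;  // deterministic start state
    R_xlen_t got = 0;
    uint64_t period = (k >= 64) ? 0 : ((1ULL << k) - 1);
    for (uint64_t step = 0; step < period && got < want; ++step) {
        if (state <= nn) out[got++] = (double)state;
        state = lfsr_step(state, k);
    }
    if (got < want) Rcpp::stop("LFSR failed to cover the requested range (bad taps?)");
    return out;
}

//' @noRd
// [[Rcpp::export]]
double lfsr_period_cpp(int k) {
    // walk the register until the start state recurs; used by unit tests
    if (k < 2 || k > 32) Rcpp::stop("width must be in 2..32");
    uint64_t state = 1;
    uint64_t count = 0;
    do {
        state = lfsr_step(state, k);
        ++count;
        if (count > (1ULL << (k + 1))) break;
    } while (state != 1);
    return (double)count;
}
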