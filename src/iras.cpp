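#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Signed maximum deviation of the target vs non-target rank CDFs, given the
// sorted 1-based rank positions of the m target genes among N genes.  The
// deviation d(i) rises only at target positions and falls linearly between
// them, so its extrema lie at target positions (maxima) and just before them
// (minima); scanning those candidates in index order with a strict ">"
// update reproduces the first-index tie rule of the reference R computation
// (which takes which.max(abs(d)) over all ranks), with bitwise-identical
// arithmetic: j/m and (p_j - j)/(N - m) are the same divisions the
// cumsum-based R version performs.
static double signed_ks(const int* pos, int m, int N) {
    const double dm = (double)m;
    const double dn = (double)(N - m);
    double best = 0.0, besta = 0.0;
    for (int j = 1; j <= m; ++j) {
        const int p = pos[j - 1];
        if (p > 1) {  // candidate at rank p-1 (minimum of |d| segment)
            const double d = (double)(j - 1) / dm - (double)(p - j) / dn;
            const double a = std::abs(d);
            if (a > besta) { besta = a; best = d; }
        }
        const double d2 = (double)j / dm - (double)(p - j) / dn;
        const double a2 = std::abs(d2);
        if (a2 > besta) { besta = a2; best = d2; }
    }
    return best;
}

// [[Rcpp::export]]
double cpp_signed_ks(IntegerVector positions, int N) {
    const int m = positions.size();
    if (m < 2 || N - m < 2)
        stop("need >= 2 targets and >= 2 non-targets");
    std::vector<int> p(positions.begin(), positions.end());
    std::sort(p.begin(), p.end());
    if (p.front() < 1 || p.back() > N)
        stop("positions must lie in [1, N]");
    return signed_ks(p.data(), m, N);
}

// Null distribution of the signed statistic: scores of R random target sets
// of size m drawn without replacement from ranks 1..N.  A partial
// Fisher-Yates shuffle on a persistent index buffer, undone after each
// draw, keeps every permutation O(m) instead of O(N).  Uses R's RNG
// (R_unif_index, as base::sample does), so set.seed() in R makes the draw
// reproducible.
// [[Rcpp::export]]
NumericVector cpp_perm_null(int N, int m, int R) {
    if (m < 2 || N - m < 2)
        stop("need >= 2 targets and >= 2 non-targets");
    if (R < 1)
        stop("at least one permutation is required");
    NumericVector out(R);
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i + 1;
    std::vector<int> p(m), swapped(m);
    for (int r = 0; r < R; ++r) {
        for (int i = 0; i < m; ++i) {
            int j = i + (int)R_unif_index((double)(N - i));
            swapped[i] = j;
            std::swap(idx[i], idx[j]);
            p[i] = idx[i];
        }
        // restore identity (undo in reverse order)
        for (int i = m - 1; i >= 0; --i)
            std::swap(idx[i], idx[swapped[i]]);
        std::sort(p.begin(), p.end());
        out[r] = signed_ks(p.data(), m, N);
    }
    return out;
}
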