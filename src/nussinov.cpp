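#include <Rcpp.h>
#include <vector>
#include <string>

// Simplified RNA folding energy: maximize canonical base pairs (AU, GC, GU;
// T read as U) over nested secondary structures with a minimum hairpin loop
// of `min_loop` unpaired bases; each pair scores -1 kcal/mol. Pairing is
// restricted to a maximum span of `max_span` nt (local folding); for
// sequences no longer than max_span the result equals the unrestricted
// optimum. dp is stored as a band of width max_span.

static inline int enc(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return 4;
    }
}

static const bool PAIR[5][5] = {
    // A      C      G      U      N
    {false, false, false, true,  false},  // A
    {false, false, true,  false, false},  // C
    {false, true,  false, true,  false},  // G
    {true,  false, true,  false, false},  // U
    {false, false, false, false, false}   // N
};

// [[Rcpp::export(name = ".nussinovPairs")]]
int nussinov_pairs(std::string seq, int min_loop = 3, int max_span = 0) {
    const int n = seq.size();
    if (n < 2) return 0;
    if (max_span <= 0 || max_span > n) max_span = n;
    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);

    const int W = max_span;                    // band width (span <= W)
    std::vector<int> dp((size_t)n * W, 0);     // dp[i*W + (j-i-1)], j>i
    // value of subinterval [a, b] (0 when empty or out of band)
    #define DPV(a, b) ((b) <= (a) ? 0 : dp[(size_t)(a) * W + ((b) - (a) - 1)])

    const int maxSpan = n < W ? n : W;
    for (int span = min_loop + 2; span <= maxSpan; ++span) {
        for (int i = 0; i + span - 1 < n; ++i) {
            int j = i + span - 1;
            int best = DPV(i, j - 1);
            const bool *prow = PAIR[s[j]];
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!prow[s[k]]) continue;
                int v = 1 + DPV(i, k - 1) + DPV(k + 1, j - 1);
                if (v > best) best = v;
            }
            dp[(size_t)i * W + (j - i - 1)] = best;
        }
    }
    if (n <= W) return DPV(0, n - 1);

    // combine banded intervals: best[j] = max pairs over prefix [0, j]
    // allowing any decomposition into banded blocks
    std::vector<int> best(n, 0);
    for (int j = 1; j < n; ++j) {
        int b = best[j - 1];                          // j unused
        int lo = j - W + 1; if (lo < 0) lo = 0;
        for (int i = lo; i <= j - min_loop - 1; ++i) {
            int v = (i > 0 ? best[i - 1] : 0) + DPV(i, j);
            if (v > b) b = v;
        }
        best[j] = b;
    }
    return best[n - 1];
}
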