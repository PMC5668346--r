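#include <Rcpp.h>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving randomization by iterated double-edge swaps:
// pick two edges (a,b), (c,d), rewire to (a,d), (c,b) unless that
// would create a self-loop or multi-edge. Each edge keeps its weight
// as its endpoints change, so the weight multiset is preserved and
// weights move with "randomly placed" edges. Draws come from R's RNG,
// so results are reproducible under set.seed().
//
// edges: m x 2, 1-based. niter: swap attempts. Returns the rewired
// m x 2 edge matrix (rows stay aligned with the input weight order).

// [[Rcpp::export]]
IntegerMatrix double_edge_swap(int n, IntegerMatrix edges, int niter) {
    int m = edges.nrow();
    std::vector<int> ea(m), eb(m);
    std::unordered_set<long long> present;
    present.reserve((size_t) m * 2);
    auto key = [n](int a, int b) {
        if (a > b) std::swap(a, b);
        return (long long) a * n + b;
    };
    for (int e = 0; e < m; ++e) {
        ea[e] = edges(e, 0) - 1;
        eb[e] = edges(e, 1) - 1;
        present.insert(key(ea[e], eb[e]));
    }
    if (m >= 2) {
        for (int it = 0; it < niter; ++it) {
            int e1 = (int) (unif_rand() * m);
            int e2 = (int) (unif_rand() * m);
            if (e1 == e2) continue;
            int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
            if (unif_rand() < 0.5) std::swap(c, d);
            // propose (a,d) and (c,b)
            if (a == d || c == b) continue;
            if (a == c || b == d) continue;   // would duplicate swap ends
            if (present.count(key(a, d)) || present.count(key(c, b)))
                continue;
            present.erase(key(a, b));
            present.erase(key(c, d));
            present.insert(key(a, d));
            present.insert(key(c, b));
            eb[e1] = d;
            ea[e2] = c; eb[e2] = b;
        }
    }
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) {
        out(e, 0) = ea[e] + 1;
        out(e, 1) = eb[e] + 1;
    }
    return out;
}
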