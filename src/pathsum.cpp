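#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs binary shortest-path sums for a graph and for every
// single-edge-removed variant of it, in one call. The generative model
// scores every candidate edge removal by the change in total path
// length; doing that through repeated graph copies at the R level
// dominates the run time, so the BFS lives here.
//
// Removing edge (u, v) changes distances from source s only if the
// edge lies on every shortest path from s to the farther endpoint,
// i.e. only if the farther endpoint's unique BFS parent is the nearer
// endpoint. Sources failing that test keep their entire distance row,
// so most of the m * n BFS re-runs are skipped.
//
// edges: m x 2 integer matrix, 1-based node ids, undirected simple
// graph. Returns a numeric vector of length m + 1: element 1 is the
// path sum of the intact graph, element e + 1 the path sum with edge e
// removed (NA_real_ if that removal disconnects the graph).

static double bfs_row(int n, const std::vector<int>& head,
                      const std::vector<int>& nbr,
                      const std::vector<int>& eid,
                      int s, int skip,
                      std::vector<int>& dist, std::vector<int>& q) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int hd = 0, tl = 0, seen = 1;
    double total = 0.0;
    q[tl++] = s;
    while (hd < tl) {
        int u = q[hd++];
        for (int k = head[u]; k < head[u + 1]; ++k) {
            if (eid[k] == skip) continue;
            int v = nbr[k];
            if (dist[v] < 0) {
                dist[v] = dist[u] + 1;
                total += dist[v];
                q[tl++] = v;
                ++seen;
            }
        }
    }
    return (seen < n) ? -1.0 : total;
}

// [[Rcpp::export]]
NumericVector pathsum_each_removed(int n, IntegerMatrix edges) {
    int m = edges.nrow();
    // CSR adjacency
    std::vector<int> deg(n, 0);
    for (int e = 0; e < m; ++e) {
        ++deg[edges(e, 0) - 1];
        ++deg[edges(e, 1) - 1];
    }
    std::vector<int> head(n + 1, 0);
    for (int i = 0; i < n; ++i) head[i + 1] = head[i] + deg[i];
    std::vector<int> nbr(2 * m), eid(2 * m), pos(head.begin(), head.end() - 1);
    for (int e = 0; e < m; ++e) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        nbr[pos[a]] = b; eid[pos[a]++] = e;
        nbr[pos[b]] = a; eid[pos[b]++] = e;
    }

    NumericVector out(m + 1);
    std::vector<int> dist(n), q(n);

    // baseline rows
    std::vector<int> D((size_t) n * n);
    std::vector<double> rowsum(n);
    double base = 0.0;
    bool connected = true;
    for (int s = 0; s < n && connected; ++s) {
        double r = bfs_row(n, head, nbr, eid, s, -1, dist, q);
        if (r < 0) { connected = false; break; }
        rowsum[s] = r;
        base += r;
        std::copy(dist.begin(), dist.end(), D.begin() + (size_t) s * n);
    }
    if (!connected) {
        std::fill(out.begin(), out.end(), NA_REAL);
        return out;
    }
    out[0] = base / 2.0;

    // parent counts: npar[s * n + b] = #neighbors of b one step closer to s
    std::vector<unsigned char> npar((size_t) n * n, 0);
    for (int s = 0; s < n; ++s) {
        const int* Ds = &D[(size_t) s * n];
        for (int b = 0; b < n; ++b) {
            int c = 0;
            for (int k = head[b]; k < head[b + 1] && c < 2; ++k)
                if (Ds[nbr[k]] == Ds[b] - 1) ++c;
            npar[(size_t) s * n + b] = (unsigned char) c;
        }
    }

    for (int e = 0; e < m; ++e) {
        int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
        double total = base;
        bool ok = true;
        for (int s = 0; s < n; ++s) {
            int du = D[(size_t) s * n + u], dv = D[(size_t) s * n + v];
            if (du == dv) continue;
            int far = (du < dv) ? v : u;
            if (npar[(size_t) s * n + far] != 1) continue;
            double r = bfs_row(n, head, nbr, eid, s, e, dist, q);
            if (r < 0) { ok = false; break; }
            total += r - rowsum[s];
        }
        out[e + 1] = ok ? total / 2.0 : NA_REAL;
    }
    return out;
}
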