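#include <climits>
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Partial-order alignment draft consensus.
//
// The graph is seeded from the first read as a base-labelled chain; each
// subsequent read is aligned to the graph by affine-gap dynamic programming
// over a topological order (free end gaps on the graph side, the read aligned
// end-to-end) and fused in: a matching base increments node support, a
// mismatching or inserted base adds a branch node, a skipped node adds a
// bypass edge.  Edge weights count read traversals.  The consensus is the
// heaviest source-to-sink path by total edge weight, ties broken by node
// support and then node index.

static inline double subscore(char a, char b, double match, double mismatch) {
    return (a == b && a != 'N') ? match : mismatch;
}

#define S_M 0u
#define S_I 1u
#define S_D 2u
static const uint32_t PTR_START = 0xFFFFFFFFu;
static inline uint32_t mkptr(uint32_t state, uint32_t predIdx) {
    return (state << 30) | (predIdx & 0x3FFFFFFFu);
}

struct Graph {
    std::vector<char> base;
    std::vector<double> support;
    std::vector<std::vector<int> > preds, succs;
    std::vector<std::vector<double> > predw, succw;

    int add_node(char b) {
        base.push_back(b); support.push_back(0.0);
        preds.push_back(std::vector<int>());
        succs.push_back(std::vector<int>());
        predw.push_back(std::vector<double>());
        succw.push_back(std::vector<double>());
        return (int) base.size() - 1;
    }
    void add_edge(int u, int v) {
        for (size_t e = 0; e < succs[u].size(); ++e) {
            if (succs[u][e] == v) {
                succw[u][e] += 1.0;
                for (size_t f = 0; f < preds[v].size(); ++f)
                    if (preds[v][f] == u) { predw[v][f] += 1.0; break; }
                return;
            }
        }
        succs[u].push_back(v); succw[u].push_back(1.0);
        preds[v].push_back(u); predw[v].push_back(1.0);
    }
    size_t n_edges() const {
        size_t k = 0;
        for (size_t v = 0; v < succs.size(); ++v) k += succs[v].size();
        return k;
    }
    std::vector<int> topo_order() const {
        const int N = (int) base.size();
        std::vector<int> indeg(N), order; order.reserve(N);
        std::vector<int> stack;
        for (int v = 0; v < N; ++v) indeg[v] = (int) preds[v].size();
        for (int v = N - 1; v >= 0; --v) if (indeg[v] == 0) stack.push_back(v);
        while (!stack.empty()) {
            int v = stack.back(); stack.pop_back();
            order.push_back(v);
            for (size_t e = 0; e < succs[v].size(); ++e) {
                int u = succs[v][e];
                if (--indeg[u] == 0) stack.push_back(u);
            }
        }
        return order;
    }
};

// Event codes for the fused read path
#define EV_MATCH 0
#define EV_INS   1
#define EV_DEL   2

struct Event { int type; int node; int readpos; };

static void align_and_fuse(Graph &g, const std::string &s,
                           double match, double mismatch,
                           double gap_open, double gap_ext) {
    const int m = (int) s.size();
    const int N = (int) g.base.size();
    const double NEG = -1e30;
    std::vector<int> topo = g.topo_order();
    std::vector<int> rank(N);
    for (int t = 0; t < N; ++t) rank[topo[t]] = t;

    const size_t W = (size_t) m + 1;
    std::vector<float> M((size_t) N * W, (float) NEG);
    std::vector<float> I((size_t) N * W, (float) NEG);
    std::vector<float> D((size_t) N * W, (float) NEG);
    std::vector<uint32_t> pM((size_t) N * W, PTR_START);
    std::vector<uint32_t> pI((size_t) N * W, PTR_START);
    std::vector<uint32_t> pD((size_t) N * W, PTR_START);

    // leading-insertion chain score: S(i) read prefix i unaligned before any node
    std::vector<double> S(W);
    S[0] = 0.0;
    for (int i = 1; i <= m; ++i) S[i] = gap_open + (i - 1) * gap_ext;

    for (int t = 0; t < N; ++t) {
        const int v = topo[t];
        const size_t row = (size_t) v * W;
        const std::vector<int> &pv = g.preds[v];
        for (int i = 1; i <= m; ++i) {
            // M: read base i aligned to node v.  Equal-scoring predecessors
            // resolve toward the heavier edge so reads pile onto the
            // majority path instead of scattering over parallel branches.
            {
                double best = NEG; uint32_t ptr = PTR_START; double bw = -1.0;
                for (size_t e = 0; e < pv.size(); ++e) {
                    const size_t prow = (size_t) pv[e] * W + (i - 1);
                    const double w = g.predw[v][e];
                    // priority entering a diagonal: I > D > M
                    if (I[prow] > best || (I[prow] == best && w > bw)) {
                        best = I[prow]; ptr = mkptr(S_I, (uint32_t) e); bw = w;
                    }
                    if (D[prow] > best || (D[prow] == best && w > bw)) {
                        best = D[prow]; ptr = mkptr(S_D, (uint32_t) e); bw = w;
                    }
                    if (M[prow] > best || (M[prow] == best && w > bw)) {
                        best = M[prow]; ptr = mkptr(S_M, (uint32_t) e); bw = w;
                    }
                }
                if (S[i - 1] > best) { best = S[i - 1]; ptr = PTR_START; }
                M[row + i] = (float) (best + subscore(s[i - 1], g.base[v], match, mismatch));
                pM[row + i] = ptr;
            }
            // I: read base i unaligned after node v
            {
                double vM = M[row + i - 1] + gap_open;
                double vI = I[row + i - 1] + gap_ext;
                double vD = D[row + i - 1] + gap_open;
                double best = vM; uint32_t ptr = mkptr(S_M, 0);
                if (vI > best) { best = vI; ptr = mkptr(S_I, 0); }
                if (vD > best) { best = vD; ptr = mkptr(S_D, 0); }
                I[row + i] = (float) best; pI[row + i] = ptr;
            }
            // D: node v skipped after >= 1 read base consumed
            {
                double best = NEG; uint32_t ptr = PTR_START; double bw = -1.0;
                for (size_t e = 0; e < pv.size(); ++e) {
                    const size_t prow = (size_t) pv[e] * W + i;
                    const double w = g.predw[v][e];
                    double dM = M[prow] + gap_open;
                    double dI = I[prow] + gap_open;
                    double dD = D[prow] + gap_ext;
                    if (dM > best || (dM == best && w > bw)) { best = dM; ptr = mkptr(S_M, (uint32_t) e); bw = w; }
                    if (dI > best || (dI == best && w > bw)) { best = dI; ptr = mkptr(S_I, (uint32_t) e); bw = w; }
                    if (dD > best || (dD == best && w > bw)) { best = dD; ptr = mkptr(S_D, (uint32_t) e); bw = w; }
                }
                D[row + i] = (float) best; pD[row + i] = ptr;
            }
        }
    }

    // best final state over all nodes (trailing graph nodes free)
    double bestScore = NEG; int bv = topo[0]; uint32_t bstate = S_M;
    for (int t = 0; t < N; ++t) {
        const int v = topo[t];
        const size_t row = (size_t) v * W;
        if (M[row + m] > bestScore) { bestScore = M[row + m]; bv = v; bstate = S_M; }
        if (I[row + m] > bestScore) { bestScore = I[row + m]; bv = v; bstate = S_I; }
    }

    // traceback into events (reverse order)
    std::vector<Event> ev; ev.reserve((size_t) m * 2);
    int v = bv, i = m; uint32_t st = bstate;
    while (i > 0) {
        const size_t row = (size_t) v * W;
        if (st == S_M) {
            Event e; e.type = EV_MATCH; e.node = v; e.readpos = i; ev.push_back(e);
            uint32_t ptr = pM[row + i];
            --i;
            if (ptr == PTR_START) {
                while (i > 0) { Event li; li.type = EV_INS; li.node = -1; li.readpos = i; ev.push_back(li); --i; }
                break;
            }
            st = ptr >> 30; v = g.preds[v][ptr & 0x3FFFFFFFu];
        } else if (st == S_I) {
            Event e; e.type = EV_INS; e.node = -1; e.readpos = i; ev.push_back(e);
            uint32_t ptr = pI[row + i];
            st = ptr >> 30; --i;
        } else {
            Event e; e.type = EV_DEL; e.node = v; e.readpos = 0; ev.push_back(e);
            uint32_t ptr = pD[row + i];
            if (ptr == PTR_START) break;  // defensive; D never starts a path
            st = ptr >> 30; v = g.preds[v][ptr & 0x3FFFFFFFu];
        }
    }
    std::reverse(ev.begin(), ev.end());

    // Fuse the read path into the graph.  An inserted or mismatching base
    // reuses an existing branch node when one with the same base already
    // bridges the same neighbours (both flanking edges present, so no new
    // edge can create a cycle); otherwise a fresh branch node is added.
    // Without the reuse, equal-scoring alignments scatter reads over
    // duplicated parallel branches around homopolymer runs.
    std::vector<int> nextTrue(ev.size(), -1);
    {
        int nt = -1;
        for (int k = (int) ev.size() - 1; k >= 0; --k) {
            nextTrue[k] = nt;
            if (ev[k].type == EV_MATCH &&
                g.base[ev[k].node] == s[ev[k].readpos - 1])
                nt = ev[k].node;
        }
    }
    int prev = -1;
    for (size_t e = 0; e < ev.size(); ++e) {
        int cur = -1;
        char c = (ev[e].type == EV_DEL) ? 0 : s[ev[e].readpos - 1];
        if (ev[e].type == EV_MATCH && g.base[ev[e].node] == c) {
            g.support[ev[e].node] += 1.0;
            cur = ev[e].node;
        } else if (ev[e].type == EV_DEL) {
            continue;  // node skipped, no emission, no edge
        } else {
            // branch base (mismatch or insertion): try to reuse
            const int w = nextTrue[e];
            int reuse = -1; double rsup = -1.0;
            if (prev >= 0 && w >= 0) {
                for (size_t k = 0; k < g.succs[prev].size(); ++k) {
                    const int x = g.succs[prev][k];
                    if (x == w || g.base[x] != c) continue;
                    bool tow = false;
                    for (size_t k2 = 0; k2 < g.succs[x].size(); ++k2)
                        if (g.succs[x][k2] == w) { tow = true; break; }
                    if (tow && g.support[x] > rsup) { reuse = x; rsup = g.support[x]; }
                }
            }
            if (reuse >= 0) {
                g.support[reuse] += 1.0;
                cur = reuse;
            } else {
                cur = g.add_node(c);
                g.support[cur] = 1.0;
            }
        }
        if (prev >= 0) g.add_edge(prev, cur);
        prev = cur;
    }
}

static void seed_graph(Graph &g, const std::string &seed, double weight) {
    int prev = -1;
    for (size_t c = 0; c < seed.size(); ++c) {
        int v = g.add_node(seed[c]);
        g.support[v] = weight;
        if (prev >= 0) {
            g.add_edge(prev, v);
            g.succw[prev].back() = weight;
            g.predw[v].back() = weight;
        }
        prev = v;
    }
}

static std::vector<int> heaviest_path(const Graph &g);

// [[Rcpp::export(name = ".poa_consensus_cpp")]]
List poa_consensus_cpp(CharacterVector reads, double match, double mismatch,
                       double gap_open, double gap_ext) {
    const int R = reads.size();
    if (R < 1) stop("no reads");
    for (int rd = 0; rd < R; ++rd)
        if (as<std::string>(reads[rd]).empty()) stop("empty read");

    // Pass 1: graph seeded from the first read, remaining reads fused in.
    Graph g1;
    seed_graph(g1, as<std::string>(reads[0]), 1.0);
    for (int rd = 1; rd < R; ++rd) {
        align_and_fuse(g1, as<std::string>(reads[rd]),
                       match, mismatch, gap_open, gap_ext);
        Rcpp::checkUserInterrupt();
    }
    std::vector<int> path1 = heaviest_path(g1);
    std::string cons1; cons1.reserve(path1.size());
    for (size_t k = 0; k < path1.size(); ++k) cons1.push_back(g1.base[path1[k]]);

    // Refinement passes: the first read is as error-ridden as any, so the
    // pass-1 trunk is a patchwork of branches.  Re-seed with the current
    // consensus at zero support/weight and fuse every read against that
    // trunk; supports and weights then reflect reads only.  Iterate until
    // the consensus is stable (at most two refinement rounds).
    Graph g;
    std::vector<int> path;
    if (R > 1) {
        std::string cons = cons1;
        for (int pass = 0; pass < 2; ++pass) {
            Graph g2;
            seed_graph(g2, cons, 0.0);
            for (int rd = 0; rd < R; ++rd) {
                align_and_fuse(g2, as<std::string>(reads[rd]),
                               match, mismatch, gap_open, gap_ext);
                Rcpp::checkUserInterrupt();
            }
            path = heaviest_path(g2);
            std::string next; next.reserve(path.size());
            for (size_t k = 0; k < path.size(); ++k)
                next.push_back(g2.base[path[k]]);
            g = g2;
            if (next == cons) break;
            cons = next;
        }
    } else {
        seed_graph(g, cons1, 1.0);
        path = heaviest_path(g);
    }

    std::string seq; seq.reserve(path.size());
    NumericVector sup((int) path.size());
    const int N = (int) g.base.size();
    for (size_t k = 0; k < path.size(); ++k) {
        seq.push_back(g.base[path[k]]);
        sup[(int) k] = g.support[path[k]];
    }

    // graph dump (edge list) for introspection and tests
    size_t ne = g.n_edges();
    IntegerVector eu((int) ne), evv((int) ne);
    NumericVector ew((int) ne);
    IntegerVector pathv((int) path.size());
    {
        int k = 0;
        for (int u = 0; u < N; ++u)
            for (size_t e = 0; e < g.succs[u].size(); ++e) {
                eu[k] = u; evv[k] = g.succs[u][e]; ew[k] = g.succw[u][e]; ++k;
            }
        for (size_t i2 = 0; i2 < path.size(); ++i2) pathv[(int) i2] = path[i2];
    }
    CharacterVector bases(N);
    NumericVector supall(N);
    for (int v2 = 0; v2 < N; ++v2) {
        bases[v2] = std::string(1, g.base[v2]);
        supall[v2] = g.support[v2];
    }
    return List::create(_["seq"] = seq,
                        _["support"] = sup,
                        _["n_nodes"] = N,
                        _["n_edges"] = (double) ne,
                        _["node_base"] = bases,
                        _["node_support"] = supall,
                        _["edge_from"] = eu,
                        _["edge_to"] = evv,
                        _["edge_weight"] = ew,
                        _["path"] = pathv);
}

static std::vector<int> heaviest_path(const Graph &g) {
    // Heaviest path by edge weight, with a per-edge cost of 0.2x the
    // maximum edge weight and free restart (local-segment semantics).
    // A plain cumulative sum is biased toward longer parallel detours
    // (two half-weight edges outweigh one direct edge) and always absorbs
    // stray read-tail chains at the termini; the per-edge cost makes a
    // detour pay for its extra step and leaves weakly supported termini
    // out of the path.  Node support breaks remaining ties.
    const int N = (int) g.base.size();
    std::vector<int> topo = g.topo_order();
    double wmax = 0.0;
    for (int v = 0; v < N; ++v)
        for (size_t e = 0; e < g.succw[v].size(); ++e)
            wmax = std::max(wmax, g.succw[v][e]);
    const double lambda = 0.2 * wmax;
    std::vector<double> best(N, 0.0);
    std::vector<int> ptr(N, -1);
    for (int t = 0; t < N; ++t) {
        const int v = topo[t];
        double b = 0.0; int p = -1; double psup = -1.0;  // b = 0: fresh start
        for (size_t e = 0; e < g.preds[v].size(); ++e) {
            const int u = g.preds[v][e];
            const double cand = best[u] + g.predw[v][e] - lambda;
            if (cand > b ||
                (cand == b && p >= 0 &&
                 (g.support[u] > psup || (g.support[u] == psup && u < p)))) {
                b = cand; p = u; psup = g.support[u];
            }
        }
        best[v] = b; ptr[v] = p;
    }
    double bb = -1.0; int endv = -1; double bsup = -1.0;
    for (int v = 0; v < N; ++v) {
        if (best[v] > bb ||
            (best[v] == bb && (g.support[v] > bsup ||
                               (g.support[v] == bsup && (endv < 0 || v < endv))))) {
            bb = best[v]; endv = v; bsup = g.support[v];
        }
    }
    std::vector<int> path;
    for (int v = endv; v >= 0; v = ptr[v]) path.push_back(v);
    std::reverse(path.begin(), path.end());

    return path;
}
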