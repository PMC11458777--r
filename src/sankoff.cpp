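#include <Rcpp.h>
using namespace Rcpp;

// Linear-cost (Wagner) Sankoff dynamic programming over ordered multistate
// characters. Cost of a state change i -> j along a branch is |i - j|, so the
// per-branch distance transform min_j(|i - j| + f(j)) is computed in O(S) by a
// forward pass (allow decreasing j) and a backward pass (allow increasing j)
// instead of the generic O(S^2) min-plus product.

static const double BIG = 1e18;

// In-place distance transform of one cost vector of length S.
static void dtransform(std::vector<double> &f) {
    const int S = (int)f.size();
    for (int i = 1; i < S; i++)
        if (f[i - 1] + 1.0 < f[i]) f[i] = f[i - 1] + 1.0;
    for (int i = S - 2; i >= 0; i--)
        if (f[i + 1] + 1.0 < f[i]) f[i] = f[i + 1] + 1.0;
}

// Down-pass cost vectors L[node][char * S + state] for every node of a tree
// given in postorder edge orientation (parent, child). Nodes are 1-based ape
// ids: tips 1..nTip, internals nTip+1 .. nTip+nNode. states is an nTip x nChar
// integer matrix of tip states (0-based), rows in tip-id order.
static void down_pass(const IntegerMatrix &edge, int nTip, int nNodeTotal,
                      const IntegerMatrix &states, int S,
                      std::vector< std::vector<double> > &L) {
    const int nChar = states.ncol();
    L.assign(nNodeTotal + 1, std::vector<double>());
    for (int v = 1; v <= nNodeTotal; v++) {
        L[v].assign((size_t)nChar * S, 0.0);
        if (v <= nTip) {
            for (int c = 0; c < nChar; c++) {
                int obs = states(v - 1, c);
                for (int s = 0; s < S; s++)
                    L[v][(size_t)c * S + s] = (s == obs) ? 0.0 : BIG;
            }
        }
    }
    // postorder: children are complete before their parent edge is seen
    std::vector<double> buf(S);
    for (int e = 0; e < edge.nrow(); e++) {
        int p = edge(e, 0), c = edge(e, 1);
        for (int ch = 0; ch < nChar; ch++) {
            for (int s = 0; s < S; s++) buf[s] = L[c][(size_t)ch * S + s];
            dtransform(buf);
            for (int s = 0; s < S; s++) L[p][(size_t)ch * S + s] += buf[s];
        }
    }
}

// [[Rcpp::export(name = ".sankoff_score_cpp")]]
double sankoff_score_cpp(IntegerMatrix edge, int nTip, int nNodeTotal,
                         IntegerMatrix states, int S) {
    std::vector< std::vector<double> > L;
    down_pass(edge, nTip, nNodeTotal, states, S, L);
    int root = edge(edge.nrow() - 1, 0);
    const int nChar = states.ncol();
    double total = 0.0;
    for (int c = 0; c < nChar; c++) {
        double best = BIG;
        for (int s = 0; s < S; s++)
            best = std::min(best, L[root][(size_t)c * S + s]);
        total += best;
    }
    return total;
}

// Cost of attaching a hypothetical ancestor tip (fixed state vector anc,
// 0-based, length nChar) to every edge in turn. Returns one total tree length
// per edge, in the row order of `edge`. Uses the standard inside/outside
// decomposition: for edge (p, c) with new node n,
//   cost = sum_chars min_x [ |x - anc| + T(L_c)(x) + T(O_c)(x) ]
// where O_c(y) = U_p(y) + sum_{siblings s} T(L_s)(y) is the cost of the
// p-side component given state(p) = y, and U_c = T(O_c) is the outside
// vector propagated in preorder (U_root = 0).
// [[Rcpp::export(name = ".sankoff_edge_costs_cpp")]]
NumericVector sankoff_edge_costs_cpp(IntegerMatrix edge, int nTip,
                                     int nNodeTotal, IntegerMatrix states,
                                     int S, IntegerVector anc) {
    const int nChar = states.ncol();
    std::vector< std::vector<double> > L;
    down_pass(edge, nTip, nNodeTotal, states, S, L);

    // T(L_c) for every edge child c, reused twice
    int nE = edge.nrow();
    std::vector< std::vector<double> > TL(nE);
    std::vector<double> buf(S);
    for (int e = 0; e < nE; e++) {
        int c = edge(e, 1);
        TL[e].assign((size_t)nChar * S, 0.0);
        for (int ch = 0; ch < nChar; ch++) {
            for (int s = 0; s < S; s++) buf[s] = L[c][(size_t)ch * S + s];
            dtransform(buf);
            for (int s = 0; s < S; s++) TL[e][(size_t)ch * S + s] = buf[s];
        }
    }

    int root = edge(nE - 1, 0);
    std::vector< std::vector<double> > U(nNodeTotal + 1);
    U[root].assign((size_t)nChar * S, 0.0);

    // preorder over edges (reverse postorder): parent's U ready before child's
    NumericVector out(nE);
    for (int e = nE - 1; e >= 0; e--) {
        int p = edge(e, 0), c = edge(e, 1);
        // O_c = U_p + (L_p - T(L_c))  [sum over siblings = parent's own
        // down-pass total minus this child's transformed contribution]
        std::vector<double> O((size_t)nChar * S);
        for (size_t i = 0; i < O.size(); i++)
            O[i] = U[p][i] + (L[p][i] - TL[e][i]);
        // attachment cost on this edge
        double tot = 0.0;
        for (int ch = 0; ch < nChar; ch++) {
            // T(O) for this char
            for (int s = 0; s < S; s++) buf[s] = O[(size_t)ch * S + s];
            dtransform(buf);
            double best = BIG;
            int a = anc[ch];
            for (int x = 0; x < S; x++) {
                double v = std::abs((double)(x - a)) +
                           TL[e][(size_t)ch * S + x] + buf[x];
                best = std::min(best, v);
            }
            tot += best;
            // store T(O) into O slot to build U_c afterwards
            for (int s = 0; s < S; s++) O[(size_t)ch * S + s] = buf[s];
        }
        out[e] = tot;
        if (c > nTip) U[c] = O;  // internal child needs its outside vector
    }
    return out;
}
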