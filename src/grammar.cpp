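#include <Rcpp.h>
using namespace Rcpp;

// Iterated application of a recurrence grammar to a symbol sequence.
//
// The rule set is induced by the recurrent pairs (ei[k], ej[k]) of a
// recurrence plot: whenever two time points are recurrent, the larger
// current symbol at either position is rewritten to the smaller one. One
// pass applies every rule once, synchronously, to the current sequence;
// passes repeat until a fixed point is reached (maxPasses < 0) or the pass
// budget is exhausted. At the fixed point every symbol equals the minimal
// symbol of its connected component in the recurrence graph.
//
// [[Rcpp::export(name = ".grammar_iterate")]]
IntegerVector grammar_iterate(IntegerVector init, IntegerVector ei,
                              IntegerVector ej, int maxPasses = -1) {
    const R_xlen_t n = init.size(), m = ei.size();
    if (ej.size() != m) stop("edge vectors must have equal length");
    IntegerVector s = clone(init);
    IntegerVector ns(n);
    int pass = 0;
    for (;;) {
        if (maxPasses >= 0 && pass >= maxPasses) break;
        std::copy(s.begin(), s.end(), ns.begin());
        for (R_xlen_t k = 0; k < m; ++k) {
            const int a = ei[k] - 1, b = ej[k] - 1;
            if (a < 0 || b < 0 || a >= n || b >= n)
                stop("edge index out of range");
            if (s[b] < ns[a]) ns[a] = s[b];
            if (s[a] < ns[b]) ns[b] = s[a];
        }
        ++pass;
        bool changed = false;
        for (R_xlen_t t = 0; t < n; ++t)
            if (ns[t] != s[t]) { changed = true; break; }
        std::copy(ns.begin(), ns.end(), s.begin());
        if (!changed) break;
    }
    return s;
}
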