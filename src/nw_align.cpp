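#include <Rcpp.h>
#include <vector>
#include <string>

// Global (Needleman-Wunsch) alignment of query a against reference b with
// linear gap penalty. Scoring: match +1, mismatch -1, gap -2 (defaults set
// on the R side). Deterministic tie-breaking at every DP cell: prefer the
// diagonal move, then up (consume a query base), then left (consume a
// reference base). Traceback pointers are stored as one byte per cell, so
// memory is (n+1)*(m+1) bytes; mitochondrial-scale sequences (~16.5 kb)
// need ~274 MB transiently.
// [[Rcpp::export]]
Rcpp::List nw_align_cpp(const std::string& a, const std::string& b,
                        double match, double mismatch, double gap) {
    const size_t n = a.size(), m = b.size();
    std::vector<unsigned char> tb((n + 1) * (m + 1)); // 1=diag 2=up 3=left
    std::vector<double> prev(m + 1), cur(m + 1);

    for (size_t j = 0; j <= m; ++j) { prev[j] = gap * (double)j; tb[j] = 3; }
    tb[0] = 0;
    for (size_t i = 1; i <= n; ++i) {
        cur[0] = gap * (double)i;
        tb[i * (m + 1)] = 2;
        for (size_t j = 1; j <= m; ++j) {
            double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
            double u = prev[j] + gap;
            double l = cur[j - 1] + gap;
            unsigned char p;
            double s;
            if (d >= u && d >= l)      { s = d; p = 1; }
            else if (u >= l)           { s = u; p = 2; }
            else                       { s = l; p = 3; }
            cur[j] = s;
            tb[i * (m + 1) + j] = p;
        }
        std::swap(prev, cur);
    }
    double score = prev[m];

    // Traceback from (n, m); collect aligned (query, reference) pairs.
    std::vector<int> qa, rb;
    size_t i = n, j = m;
    while (i > 0 || j > 0) {
        unsigned char p = tb[i * (m + 1) + j];
        if (p == 1)      { qa.push_back((int)i); rb.push_back((int)j); --i; --j; }
        else if (p == 2) { --i; }
        else             { --j; }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(rb.begin(), rb.end());
    return Rcpp::List::create(Rcpp::Named("score") = score,
                              Rcpp::Named("query_pos") = qa,
                              Rcpp::Named("ref_pos") = rb);
}
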