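#include <Rcpp.h>
using namespace Rcpp;

// Sequences are encoded as integer vectors with A=0, C=1, G=2, T=3, N=-1.
// The log-odds matrix `lo` is L x 4, row j giving log2(p_j[base]/q[base]) for
// the plus strand.  A minus-strand window is scored on its reverse
// complement: position j of the reverse complement of window [i, i+L) is the
// complement (3 - b) of the base at i + L - 1 - j; equivalently, the minus
// score of the window equals the plus score under the row-reversed,
// column-complemented matrix, which we precompute.  Windows containing N are
// skipped on both strands.

static void flatten_lo(const NumericMatrix &lo, std::vector<double> &fwd,
                       std::vector<double> &rev) {
    const int L = lo.nrow();
    fwd.resize(4 * L);
    rev.resize(4 * L);
    for (int j = 0; j < L; ++j)
        for (int b = 0; b < 4; ++b) {
            fwd[4 * j + b] = lo(j, b);
            rev[4 * j + b] = lo(L - 1 - j, 3 - b);
        }
}

// [[Rcpp::export]]
DataFrame scan_pwm_cpp(IntegerVector seq, NumericMatrix lo, double threshold) {
    const int n = seq.size();
    const int L = lo.nrow();
    std::vector<double> fwd, rev;
    flatten_lo(lo, fwd, rev);
    const int *s = INTEGER(seq);
    std::vector<int> offsets, strands;  // strand 0 = plus, 1 = minus
    std::vector<double> scores;
    for (int i = 0; i + L <= n; ++i) {
        bool has_n = false;
        double sp = 0.0, sm = 0.0;
        for (int j = 0; j < L; ++j) {
            const int b = s[i + j];
            if (b < 0) { has_n = true; break; }
            sp += fwd[4 * j + b];
            sm += rev[4 * j + b];
        }
        if (has_n) continue;
        if (sp >= threshold) {
            offsets.push_back(i); strands.push_back(0); scores.push_back(sp);
        }
        if (sm >= threshold) {
            offsets.push_back(i); strands.push_back(1); scores.push_back(sm);
        }
    }
    return DataFrame::create(_["offset"] = offsets,
                             _["strand"] = strands,
                             _["score"]  = scores);
}

// Per-sequence presence indicator (the enrichment counting unit).  Early-exits
// on the first window of either strand reaching the threshold.

// [[Rcpp::export]]
LogicalVector any_hit_cpp(List seqs, NumericMatrix lo, double threshold) {
    const int ns = seqs.size();
    const int L = lo.nrow();
    std::vector<double> fwd, rev;
    flatten_lo(lo, fwd, rev);
    LogicalVector out(ns);
    for (int k = 0; k < ns; ++k) {
        IntegerVector seq = seqs[k];
        const int n = seq.size();
        const int *s = INTEGER(seq);
        bool hit = false;
        for (int i = 0; i + L <= n && !hit; ++i) {
            bool has_n = false;
            double sp = 0.0, sm = 0.0;
            for (int j = 0; j < L; ++j) {
                const int b = s[i + j];
                if (b < 0) { has_n = true; break; }
                sp += fwd[4 * j + b];
                sm += rev[4 * j + b];
            }
            if (!has_n && (sp >= threshold || sm >= threshold)) hit = true;
        }
        out[k] = hit;
    }
    return out;
}
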