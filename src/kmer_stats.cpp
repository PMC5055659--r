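#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average-tie ranks of v (1-based ranks, like R's rank()).
static std::vector<double> avg_ranks(const std::vector<double>& v) {
    int n = v.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    std::vector<double> r(n);
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
        double avg = (i + j) / 2.0 + 1.0;
        for (int t = i; t <= j; ++t) r[ord[t]] = avg;
        i = j + 1;
    }
    return r;
}

// Per-event, per-k-mer coverage statistics over region sequences.
//
// codes: events x L matrix of base codes (A=0, C=1, G=2, T=3; negative =
// invalid).  cons: events x L per-base conservation aligned with codes
// (NA = missing base).  Windows of width k define k-mer instances; for
// every (event, k-mer) pair with >= 1 instance this returns the instance
// count, the number and conservation sum of distinct covered bases with
// non-missing conservation, and the conservation-weighted count (each
// instance contributes the minimum conservation over its k bases;
// instances containing a missing base are dropped from the weighted
// count).
// [[Rcpp::export]]
List cpp_kmer_coverage(IntegerMatrix codes, NumericMatrix cons, int k) {
    int n = codes.nrow(), L = codes.ncol();
    int W = L - k + 1;
    std::vector<int> out_event, out_kmer, out_count, out_covn;
    std::vector<double> out_covsum, out_wcount;
    std::vector<std::pair<int,int> > wins;   // (kmer id, window start)
    for (int e = 0; e < n; ++e) {
        wins.clear();
        for (int w = 0; w < W; ++w) {
            int id = 0;
            bool ok = true;
            for (int t = 0; t < k; ++t) {
                int c = codes(e, w + t);
                if (c < 0 || c > 3) { ok = false; break; }
                id = id * 4 + c;
            }
            if (ok) wins.push_back(std::make_pair(id, w));
        }
        std::sort(wins.begin(), wins.end());
        size_t i = 0;
        while (i < wins.size()) {
            size_t j = i;
            int id = wins[i].first;
            while (j + 1 < wins.size() && wins[j + 1].first == id) ++j;
            int count = j - i + 1;
            double covsum = 0.0, wcount = 0.0;
            int covn = 0;
            int last = -1;                   // last base already counted
            for (size_t t = i; t <= j; ++t) {
                int p = wins[t].second;
                // union of covered bases (windows sorted by position)
                for (int b = std::max(p, last + 1); b < p + k; ++b) {
                    double cv = cons(e, b);
                    if (!NumericMatrix::is_na(cv)) { covsum += cv; ++covn; }
                }
                last = std::max(last, p + k - 1);
                // weighted count: min conservation over the instance
                double mn = R_PosInf;
                bool has_na = false;
                for (int b = p; b < p + k; ++b) {
                    double cv = cons(e, b);
                    if (NumericMatrix::is_na(cv)) { has_na = true; break; }
                    if (cv < mn) mn = cv;
                }
                if (!has_na) wcount += mn;
            }
            out_event.push_back(e + 1);
            out_kmer.push_back(id + 1);
            out_count.push_back(count);
            out_covn.push_back(covn);
            out_covsum.push_back(covsum);
            out_wcount.push_back(wcount);
            i = j + 1;
        }
    }
    return List::create(_["event"] = wrap(out_event),
                        _["kmer"] = wrap(out_kmer),
                        _["count"] = wrap(out_count),
                        _["cov_n"] = wrap(out_covn),
                        _["cov_sum"] = wrap(out_covsum),
                        _["wcount"] = wrap(out_wcount));
}

// Spearman correlations of a response against fixed per-k-mer rank
// vectors over per-k-mer event subsets.
//
// idx: list of 1-based integer vectors (containing events per k-mer).
// xranks: list of numeric vectors, the pre-computed average-tie ranks of
// the fixed variable (count or enrichment) over the same subsets.
// r: response vector (e.g. residual PSI) over all events.
// Returns one correlation per k-mer; NA when < 3 events or either side
// is constant.
// [[Rcpp::export]]
NumericVector cpp_subset_spearman(List idx, List xranks, NumericVector r) {
    int K = idx.size();
    NumericVector out(K);
    for (int k = 0; k < K; ++k) {
        IntegerVector ix = idx[k];
        NumericVector xr = xranks[k];
        int m = ix.size();
        if (m < 3) { out[k] = NA_REAL; continue; }
        std::vector<double> sub(m);
        for (int i = 0; i < m; ++i) sub[i] = r[ix[i] - 1];
        std::vector<double> yr = avg_ranks(sub);
        double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
        for (int i = 0; i < m; ++i) {
            sx += xr[i]; sy += yr[i];
            sxx += xr[i] * xr[i]; syy += yr[i] * yr[i];
            sxy += xr[i] * yr[i];
        }
        double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
        if (vx <= 1e-12 || vy <= 1e-12) { out[k] = NA_REAL; continue; }
        out[k] = (sxy - sx * sy / m) / std::sqrt(vx * vy);
    }
    return out;
}
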