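#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Two-row Levenshtein DP with an optional early-exit bound: once every cell in
// a row exceeds `bound` the final distance must too, so we can stop.  A bound
// of -1 disables the cutoff.
static int levenshtein(const std::string &a, const std::string &b, int bound) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n == 0) return m;
    if (m == 0) return n;
    if (bound >= 0 && std::abs(n - m) > bound) return bound + 1;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        int row_min = cur[0];
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
            if (cur[j] < row_min) row_min = cur[j];
        }
        if (bound >= 0 && row_min > bound) return bound + 1;
        prev.swap(cur);
    }
    return prev[m];
}

//' @noRd
// [[Rcpp::export(name = ".edit_distance_cpp")]]
IntegerVector edit_distance_cpp(CharacterVector a, CharacterVector b) {
    R_xlen_t n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string sa = as<std::string>(a[i % a.size()]);
        std::string sb = as<std::string>(b[i % b.size()]);
        out[i] = levenshtein(sa, sb, -1);
    }
    return out;
}

// For each raw barcode, find the whitelist entry at minimum Levenshtein
// distance.  Returns the 1-based index of the unique minimiser (NA when the
// minimum is tied or exceeds max_dist), the minimum distance itself, and a
// tie flag.
//' @noRd
// [[Rcpp::export(name = ".match_barcodes_cpp")]]
List match_barcodes_cpp(CharacterVector raw, CharacterVector whitelist,
                        int max_dist) {
    R_xlen_t n = raw.size(), w = whitelist.size();
    std::vector<std::string> wl(w);
    for (R_xlen_t j = 0; j < w; ++j) wl[j] = as<std::string>(whitelist[j]);
    IntegerVector idx(n), dist(n);
    LogicalVector tie(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (raw[i] == NA_STRING) {
            idx[i] = NA_INTEGER; dist[i] = NA_INTEGER; tie[i] = false;
            continue;
        }
        std::string r = as<std::string>(raw[i]);
        int best = INT_MAX, best_j = -1;
        bool tied = false;
        for (R_xlen_t j = 0; j < w; ++j) {
            // bound by current best: anything worse is irrelevant
            int d = levenshtein(r, wl[j], best == INT_MAX ? -1 : best);
            if (d < best) { best = d; best_j = (int)j; tied = false; }
            else if (d == best) { tied = true; }
        }
        dist[i] = best;
        tie[i] = tied;
        idx[i] = (!tied && best <= max_dist) ? best_j + 1 : NA_INTEGER;
    }
    return List::create(_["idx"] = idx, _["dist"] = dist, _["tie"] = tie);
}

// Semi-global alignment of a linker against a search window: the linker is
// consumed in full, the window start/end are free.  Returns the minimum edit
// distance, and the 1-based start/end of the best-matching window segment
// (ties on the end position resolved toward `expected_end`; traceback
// prefers diagonal moves for determinism).
//' @noRd
// [[Rcpp::export(name = ".linker_align_cpp")]]
List linker_align_cpp(std::string window, std::string linker,
                      int expected_end) {
    const int W = (int)window.size(), L = (int)linker.size();
    // dp[(i)*(W+1) + j]: linker[0..i) vs window[?..j)
    std::vector<int> dp((L + 1) * (W + 1));
    for (int j = 0; j <= W; ++j) dp[j] = 0;
    for (int i = 1; i <= L; ++i) {
        dp[i * (W + 1)] = i;
        for (int j = 1; j <= W; ++j) {
            int sub = dp[(i - 1) * (W + 1) + j - 1] +
                      (linker[i - 1] == window[j - 1] ? 0 : 1);
            int up = dp[(i - 1) * (W + 1) + j] + 1;
            int left = dp[i * (W + 1) + j - 1] + 1;
            dp[i * (W + 1) + j] = std::min(sub, std::min(up, left));
        }
    }
    int best = INT_MAX, jend = -1;
    for (int j = 1; j <= W; ++j) {
        int d = dp[L * (W + 1) + j];
        if (d < best ||
            (d == best && std::abs(j - expected_end) <
                              std::abs(jend - expected_end))) {
            best = d;
            jend = j;
        }
    }
    // traceback to the segment start
    int i = L, j = jend;
    while (i > 0 && j > 0) {
        int cur = dp[i * (W + 1) + j];
        int sub = dp[(i - 1) * (W + 1) + j - 1] +
                  (linker[i - 1] == window[j - 1] ? 0 : 1);
        if (cur == sub) { --i; --j; continue; }
        if (cur == dp[(i - 1) * (W + 1) + j] + 1) { --i; continue; }
        --j;
    }
    return List::create(_["dist"] = best, _["start"] = j + 1,
                        _["end"] = jend);
}
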