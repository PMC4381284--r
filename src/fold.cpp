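#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Bases are encoded A=0, C=1, G=2, U=3 on the R side.

static inline double pair_w(int a, int b, double wGC, double wAU, double wGU) {
    if ((a == 1 && b == 2) || (a == 2 && b == 1)) return wGC;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
    return -1.0;   // illegal pair
}

struct DP {
    int n;
    std::vector<double> M;                       // n*n, row-major
    std::vector<std::vector<int> > partners;     // legal k >= i+h+1 per i
    std::vector<double> W;                       // n*n pair weights (<0 illegal)
    double at(int i, int j) const { return (i > j) ? 0.0 : M[i * n + j]; }
};

static void fill_dp(const std::vector<int>& s, double wGC, double wAU, double wGU,
                    int h, const std::vector<bool>& mask, DP& dp) {
    int n = (int)s.size();
    dp.n = n;
    dp.M.assign((size_t)n * n, 0.0);
    dp.W.assign((size_t)n * n, -1.0);
    dp.partners.assign(n, std::vector<int>());
    for (int i = 0; i < n; ++i) {
        if (mask[i]) continue;
        for (int k = i + h + 1; k < n; ++k) {
            if (mask[k]) continue;
            double w = pair_w(s[i], s[k], wGC, wAU, wGU);
            if (w > 0) {
                dp.partners[i].push_back(k);
                dp.W[(size_t)i * n + k] = w;
            }
        }
    }
    double* M = dp.M.data();
    for (int i = n - 2; i >= 0; --i) {
        const double* rowW = dp.W.data() + (size_t)i * n;
        const double* rowN = M + (size_t)(i + 1) * n;   // row i+1
        double* row = M + (size_t)i * n;
        const std::vector<int>& ps = dp.partners[i];
        for (int j = i + 1; j < n; ++j) {
            double best = rowN[j];                       // i unpaired
            for (size_t t = 0; t < ps.size(); ++t) {
                int k = ps[t];
                if (k > j) break;
                double cand = rowW[k];
                if (k - 1 >= i + 1) cand += rowN[k - 1];
                if (k + 1 <= j)     cand += M[(size_t)(k + 1) * n + j];
                if (cand > best) best = cand;
            }
            row[j] = best;
        }
    }
}

// Deterministic traceback: at [i,j] prefer pairing i (outermost partner
// first) over leaving i unpaired.
static void traceback(const DP& dp, std::vector<int>& p) {
    const double eps = 1e-9;
    int n = dp.n;
    std::vector<std::pair<int, int> > todo;
    todo.push_back(std::make_pair(0, n - 1));
    while (!todo.empty()) {
        int i = todo.back().first, j = todo.back().second;
        todo.pop_back();
        while (i < j) {
            bool paired = false;
            const std::vector<int>& ps = dp.partners[i];
            for (int t = (int)ps.size() - 1; t >= 0; --t) {
                int k = ps[t];
                if (k > j) continue;
                double cand = dp.W[(size_t)i * n + k] + dp.at(i + 1, k - 1)
                            + dp.at(k + 1, j);
                if (cand > dp.at(i, j) - eps) {
                    p[i] = k + 1;       // 1-based
                    p[k] = i + 1;
                    if (k + 1 <= j) todo.push_back(std::make_pair(k + 1, j));
                    j = k - 1;
                    ++i;
                    paired = true;
                    break;
                }
            }
            if (!paired) ++i;
        }
    }
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector seq_codes, double wGC, double wAU, double wGU,
             int min_hairpin, LogicalVector mask) {
    int n = seq_codes.size();
    std::vector<int> s(seq_codes.begin(), seq_codes.end());
    std::vector<bool> mk(n);
    for (int i = 0; i < n; ++i) mk[i] = mask[i];
    DP dp;
    std::vector<int> p(n, 0);
    double w = 0.0;
    if (n > 1) {
        fill_dp(s, wGC, wAU, wGU, min_hairpin, mk, dp);
        traceback(dp, p);
        w = dp.at(0, n - 1);
    }
    return List::create(_["pairs"] = IntegerVector(p.begin(), p.end()),
                        _["weight"] = w);
}

// ---- bounded suboptimal enumeration (Wuchty-style, no duplicates) ----------

struct Str {
    std::vector<std::pair<int, int> > pairs;  // 0-based (i,k)
    double w;
};

struct EnumCtx {
    const DP* dp;
    long node_cap;   // max structures materialized per subinterval
    long budget;     // global safety bound across the whole recursion
    bool incomplete;
};

// All structures on [i,j] with weight >= M(i,j) - deficit.  The fate of
// base i (unpaired, or paired with each k) partitions the space, so each
// structure is produced exactly once.
static std::vector<Str> enum_rec(EnumCtx& C, int i, int j, double deficit) {
    std::vector<Str> out;
    if (i > j) {
        Str e; e.w = 0.0;
        out.push_back(e);
        return out;
    }
    const DP& dp = *C.dp;
    double Mij = dp.at(i, j);
    const double eps = 1e-9;

    bool full = false;   // this node reached its output cap
    double d1 = deficit - (Mij - dp.at(i + 1, j));
    if (d1 > -eps) {
        std::vector<Str> subs = enum_rec(C, i + 1, j, d1);
        for (size_t t = 0; t < subs.size() && !full; ++t) {
            if ((long)out.size() >= C.node_cap || C.budget-- <= 0) {
                C.incomplete = true; full = true; break;
            }
            out.push_back(subs[t]);
        }
    }
    const std::vector<int>& ps = dp.partners[i];
    for (size_t t = 0; t < ps.size() && !full; ++t) {
        int k = ps[t];
        if (k > j) break;
        double w = dp.W[(size_t)i * dp.n + k];
        double Ml = dp.at(i + 1, k - 1);
        double Mr = dp.at(k + 1, j);
        double d2 = deficit - (Mij - (w + Ml + Mr));
        if (d2 < -eps) continue;
        std::vector<Str> L = enum_rec(C, i + 1, k - 1, d2);
        std::vector<Str> R = enum_rec(C, k + 1, j, d2);
        for (size_t a = 0; a < L.size() && !full; ++a) {
            double shortL = Ml - L[a].w;
            for (size_t b = 0; b < R.size(); ++b) {
                double shortfall = shortL + (Mr - R[b].w);
                if (shortfall > d2 + eps) continue;
                if ((long)out.size() >= C.node_cap || C.budget-- <= 0) {
                    C.incomplete = true; full = true; break;
                }
                Str sNew;
                sNew.pairs.reserve(L[a].pairs.size() + R[b].pairs.size() + 1);
                sNew.pairs.push_back(std::make_pair(i, k));
                sNew.pairs.insert(sNew.pairs.end(), L[a].pairs.begin(),
                                  L[a].pairs.end());
                sNew.pairs.insert(sNew.pairs.end(), R[b].pairs.begin(),
                                  R[b].pairs.end());
                sNew.w = w + L[a].w + R[b].w;
                out.push_back(sNew);
            }
        }
    }
    return out;
}

// [[Rcpp::export(name = ".enum_dp")]]
List enum_dp(IntegerVector seq_codes, double wGC, double wAU, double wGU,
             int min_hairpin, LogicalVector mask, double deficit,
             double max_structures) {
    int n = seq_codes.size();
    std::vector<int> s(seq_codes.begin(), seq_codes.end());
    std::vector<bool> mk(n);
    for (int i = 0; i < n; ++i) mk[i] = mask[i];

    std::vector<Str> res;
    double optw = 0.0;
    bool complete = true;
    if (n > 1) {
        DP dp;
        fill_dp(s, wGC, wAU, wGU, min_hairpin, mk, dp);
        EnumCtx C;
        C.dp = &dp;
        C.node_cap = (long)max_structures;
        C.budget = 200L * (long)max_structures;
        C.incomplete = false;
        res = enum_rec(C, 0, n - 1, deficit);
        optw = dp.at(0, n - 1);
        complete = !C.incomplete;
    } else {
        Str e; e.w = 0.0; res.push_back(e);
    }

    List tables(res.size());
    NumericVector wts(res.size());
    for (size_t t = 0; t < res.size(); ++t) {
        IntegerVector p(n, 0);
        for (size_t q = 0; q < res[t].pairs.size(); ++q) {
            p[res[t].pairs[q].first]  = res[t].pairs[q].second + 1;
            p[res[t].pairs[q].second] = res[t].pairs[q].first + 1;
        }
        tables[t] = p;
        wts[t] = res[t].w;
    }
    return List::create(_["pairs"] = tables, _["weights"] = wts,
                        _["complete"] = complete,
                        _["optimal_weight"] = optw);
}
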