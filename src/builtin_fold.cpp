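#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact minimum-energy folding of short RNA under the constraints used
// throughout the package: canonical pairs only (AU, GC, GU), hairpin loops
// of at least 3 unpaired nt, and -- when noLP is set -- no helix of length 1.
//
// Scoring is a documented "nearest-neighbor-lite" model: each base pair
// contributes a fixed stability (GC -3.0, AU -2.0, GU -1.0 kcal/mol) and
// each helix (maximal stack of consecutive pairs) pays a fixed initiation
// penalty of +4.0 kcal/mol, a coarse stand-in for loop entropy.  The
// structure energy is the sum.  This keeps the dynamic program exact and
// exhaustively checkable while still penalizing fragmented structures the
// way nearest-neighbor models do.
//
// DP decomposition (i..j inclusive, 0-based):
//   W(i,j)  best energy of any admissible structure on i..j
//   Q(i,j)  best energy with (i,j) paired, assuming the caller already
//           guarantees the pair sits under an outer stacked pair, so the
//           helix may legally terminate here
//   P(i,j)  best energy with (i,j) paired as the OUTERMOST pair of a helix;
//           with noLP this forces (i+1,j-1) to pair as well
// Tie-breaks in the traceback are fixed (leave j unpaired first, then
// smallest k; inside a helix prefer to keep stacking) so results are
// deterministic.

static const double INF = 1e9;
static const double HELIX_OPEN = 4.0;

static inline double pair_energy(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
    return INF;
}

struct FoldDP {
    int n;
    bool noLP;
    std::string s;
    std::vector<double> W, P, Q;
    int idx(int i, int j) const { return i * n + j; }

    bool can_pair(int i, int j) const {
        if (j - i - 1 < 3) return false;
        return pair_energy(s[i], s[j]) < INF / 2;
    }

    double getW(int i, int j) const { return (i > j) ? 0.0 : W[idx(i, j)]; }

    void run() {
        W.assign(n * n, 0.0);
        P.assign(n * n, INF);
        Q.assign(n * n, INF);
        for (int span = 4; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                if (can_pair(i, j)) {
                    double e = pair_energy(s[i], s[j]);
                    // helix may end here (interior is any structure) ...
                    double q = e + getW(i + 1, j - 1);
                    // ... or continue stacking inward
                    if (can_pair(i + 1, j - 1) && Q[idx(i + 1, j - 1)] < INF / 2)
                        q = std::min(q, e + Q[idx(i + 1, j - 1)]);
                    Q[idx(i, j)] = q;
                    if (!noLP) {
                        P[idx(i, j)] = HELIX_OPEN + q;
                    } else if (can_pair(i + 1, j - 1) &&
                               Q[idx(i + 1, j - 1)] < INF / 2) {
                        P[idx(i, j)] = HELIX_OPEN + e + Q[idx(i + 1, j - 1)];
                    }
                }
                double best = getW(i, j - 1); // j unpaired
                for (int k = i; k + 4 <= j; ++k) {
                    if (P[idx(k, j)] < INF / 2) {
                        double cand = (k > i ? getW(i, k - 1) : 0.0) + P[idx(k, j)];
                        if (cand < best) best = cand;
                    }
                }
                W[idx(i, j)] = best;
            }
        }
    }

    std::string db;

    void traceW(int i, int j) {
        if (i > j || j - i < 4) return;
        double w = getW(i, j);
        if (w == getW(i, j - 1)) { traceW(i, j - 1); return; }
        for (int k = i; k + 4 <= j; ++k) {
            if (P[idx(k, j)] < INF / 2) {
                double cand = (k > i ? getW(i, k - 1) : 0.0) + P[idx(k, j)];
                if (cand == w) {
                    if (k > i) traceW(i, k - 1);
                    traceP(k, j);
                    return;
                }
            }
        }
        traceW(i, j - 1); // numeric safety net; should not be reached
    }

    void traceP(int i, int j) {
        db[i] = '(';
        db[j] = ')';
        double e = pair_energy(s[i], s[j]);
        if (noLP) {
            traceQ(i + 1, j - 1);
        } else {
            // P == HELIX_OPEN + Q here
            if (can_pair(i + 1, j - 1) && Q[idx(i + 1, j - 1)] < INF / 2 &&
                P[idx(i, j)] == HELIX_OPEN + e + Q[idx(i + 1, j - 1)]) {
                traceQ(i + 1, j - 1);
            } else {
                traceW(i + 1, j - 1);
            }
        }
    }

    void traceQ(int i, int j) {
        db[i] = '(';
        db[j] = ')';
        double e = pair_energy(s[i], s[j]);
        // prefer to keep stacking at ties (documented tie-break)
        if (can_pair(i + 1, j - 1) && Q[idx(i + 1, j - 1)] < INF / 2 &&
            Q[idx(i, j)] == e + Q[idx(i + 1, j - 1)]) {
            traceQ(i + 1, j - 1);
        } else {
            traceW(i + 1, j - 1);
        }
    }
};

// [[Rcpp::export(name = ".builtin_fold_cpp")]]
List builtin_fold_cpp(std::string seq, bool noLP) {
    FoldDP dp;
    dp.s = seq;
    dp.n = (int)seq.size();
    dp.noLP = noLP;
    if (dp.n == 0)
        return List::create(_["db"] = "", _["mfe"] = 0.0);
    dp.run();
    dp.db.assign(dp.n, '.');
    dp.traceW(0, dp.n - 1);
    double mfe = dp.getW(0, dp.n - 1);
    return List::create(_["db"] = dp.db, _["mfe"] = mfe);
}
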