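#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Edit-operation codes shared with the R side:
// 0 = match, 1 = mismatch, 2 = insertion (base present only in B),
// 3 = deletion (base present only in A).

static const int NEG = std::numeric_limits<int>::min() / 4;

// Affine gap scoring: match +1, mismatch -1, first gap base -2 (open),
// each further gap base -1 (extend).
static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP_OPEN = -2;   // cost of the first base of a gap
static const int GAP_EXT = -1;

struct AlnResult {
    std::vector<int> ops;     // per-column op codes (expanded)
    int score;
    bool hit_edge;
};

// Banded global alignment of a (rows) vs b (columns).  The band allows
// j in [i + lo_shift, i + hi_shift]; callers pass a symmetric band that
// already accounts for the length difference.
static AlnResult banded_global(const char *a, int n, const char *b, int m,
                               int band) {
    int d = m - n;
    int loS = std::min(0, d) - band;
    int hiS = std::max(0, d) + band;
    int W = hiS - loS + 1;

    // three layers: M (diag), X (gap in b: consumes a, deletion),
    // Y (gap in a: consumes b, insertion)
    std::vector<int> M((size_t)(n + 1) * W, NEG), X = M, Y = M;
    // traceback: 2 bits per layer packed in a byte
    // for M: 0 = from M, 1 = from X, 2 = from Y
    std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0), tbX = tbM, tbY = tbM;

    auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - loS); };
    auto inband = [&](int i, int j) {
        return j >= 0 && j <= m && j - i >= loS && j - i <= hiS;
    };

    M[idx(0, 0)] = 0;
    for (int j = 1; j <= m && inband(0, j); ++j) {
        Y[idx(0, j)] = GAP_OPEN + GAP_EXT * (j - 1);
        tbY[idx(0, j)] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
        int jlo = std::max(0, i + loS), jhi = std::min(m, i + hiS);
        for (int j = jlo; j <= jhi; ++j) {
            size_t c = idx(i, j);
            if (j > 0 && inband(i - 1, j - 1)) {
                size_t p = idx(i - 1, j - 1);
                int s = (a[i - 1] == b[j - 1]) ? MATCH : MISMATCH;
                int best = M[p]; unsigned char t = 0;
                if (X[p] > best) { best = X[p]; t = 1; }
                if (Y[p] > best) { best = Y[p]; t = 2; }
                if (best > NEG) { M[c] = best + s; tbM[c] = t; }
            }
            if (inband(i - 1, j)) {  // X: consume a[i-1]
                size_t p = idx(i - 1, j);
                int fromM = (M[p] > NEG) ? M[p] + GAP_OPEN : NEG;
                int fromX = (X[p] > NEG) ? X[p] + GAP_EXT : NEG;
                if (fromM >= fromX) { if (fromM > NEG) { X[c] = fromM; tbX[c] = 0; } }
                else { X[c] = fromX; tbX[c] = 1; }
            }
            if (j > 0 && inband(i, j - 1)) {  // Y: consume b[j-1]
                size_t p = idx(i, j - 1);
                int fromM = (M[p] > NEG) ? M[p] + GAP_OPEN : NEG;
                int fromY = (Y[p] > NEG) ? Y[p] + GAP_EXT : NEG;
                if (fromM >= fromY) { if (fromM > NEG) { Y[c] = fromM; tbY[c] = 0; } }
                else { Y[c] = fromY; tbY[c] = 2; }
            }
        }
    }

    AlnResult res;
    size_t e = idx(n, m);
    int layer = 0, best = M[e];
    if (X[e] > best) { best = X[e]; layer = 1; }
    if (Y[e] > best) { best = Y[e]; layer = 2; }
    res.score = best;
    res.hit_edge = false;

    int i = n, j = m;
    std::vector<int> rev;
    while (i > 0 || j > 0) {
        // touching the band boundary (not forced by the matrix corner)
        if ((j - i == loS || j - i == hiS) && i > 0 && j > 0 && i < n)
            res.hit_edge = true;
        size_t c = idx(i, j);
        if (layer == 0) {
            int t = tbM[c];
            rev.push_back(a[i - 1] == b[j - 1] ? 0 : 1);
            --i; --j; layer = t;
        } else if (layer == 1) {
            int t = tbX[c];
            rev.push_back(3);
            --i; layer = (t == 0) ? 0 : 1;
        } else {
            int t = tbY[c];
            rev.push_back(2);
            --j; layer = (t == 0) ? 0 : 2;
        }
    }
    res.ops.assign(rev.rbegin(), rev.rend());
    return res;
}

static void rle_push(std::vector<int> &op, std::vector<int> &len, int o, int l) {
    if (l <= 0) return;
    if (!op.empty() && op.back() == o) len.back() += l;
    else { op.push_back(o); len.push_back(l); }
}

// [[Rcpp::export]]
List cpp_banded_global(std::string a, std::string b, int band,
                       int max_doublings = 4) {
    AlnResult r;
    int bw = band + (int)std::abs((long)a.size() - (long)b.size());
    int tries = 0;
    for (;;) {
        r = banded_global(a.c_str(), a.size(), b.c_str(), b.size(), bw);
        if (!r.hit_edge || tries >= max_doublings) break;
        bw *= 2; ++tries;
    }
    std::vector<int> op, len;
    for (int o : r.ops) rle_push(op, len, o, 1);
    return List::create(_["op"] = wrap(op), _["len"] = wrap(len),
                        _["score"] = r.score, _["hit_edge"] = r.hit_edge);
}

// Refine one colinear anchor chain into a full edit-op list.
// pa, pb: 0-based anchor start positions (already in forward/forward
// space), sorted, colinear, gaps bounded by the chaining step.
// Overlapping anchors on the same diagonal are merged into match runs;
// the regions between anchor ends are aligned by banded global DP.
// [[Rcpp::export]]
List cpp_refine_chain(std::string a, std::string b,
                      IntegerVector pa, IntegerVector pb,
                      int k, int band) {
    int na = pa.size();
    if (na == 0) stop("empty anchor chain");
    std::vector<int> op, len;
    long score = 0;

    // current end of the refined alignment in a and b
    int ea = pa[0], eb = pb[0];
    int start_a = pa[0], start_b = pb[0];
    rle_push(op, len, 0, k);
    score += MATCH * k;
    ea += k; eb += k;

    for (int t = 1; t < na; ++t) {
        int qa = pa[t], qb = pb[t];
        if (qa + k <= ea) continue;  // fully contained in refined run
        if (qa <= ea && qb <= eb && (qa - qb) == (ea - eb)) {
            // same diagonal, overlapping/contiguous: extend the match run
            int ext = qa + k - ea;
            rle_push(op, len, 0, ext);
            score += MATCH * ext;
            ea += ext; eb += ext;
            continue;
        }
        if (qa < ea || qb < eb) continue;  // off-diagonal overlap: skip anchor
        // gap region between anchor ends
        int ga = qa - ea, gb = qb - eb;
        if (ga > 0 || gb > 0) {
            std::string sa = a.substr(ea, ga), sb = b.substr(eb, gb);
            int bw = band + std::abs(ga - gb);
            AlnResult r;
            int tries = 0;
            for (;;) {
                r = banded_global(sa.c_str(), ga, sb.c_str(), gb, bw);
                if (!r.hit_edge || tries >= 4) break;
                bw *= 2; ++tries;
            }
            for (int o : r.ops) rle_push(op, len, o, 1);
            score += r.score;
        }
        rle_push(op, len, 0, k);
        score += MATCH * k;
        ea = qa + k; eb = qb + k;
    }
    return List::create(_["start_a"] = start_a, _["end_a"] = ea,
                        _["start_b"] = start_b, _["end_b"] = eb,
                        _["op"] = wrap(op), _["len"] = wrap(len),
                        _["score"] = (double)score);
}

// Score-only Smith-Waterman (rolling rows): exact best local score,
// no traceback.  Used as a sound screen before the full alignment.
static int local_score_only(const std::string &a, const std::string &b) {
    int n = a.size(), m = b.size();
    std::vector<int> Mp(m + 1, 0), Xp(m + 1, 0), Yp(m + 1, 0),
        Mc(m + 1, 0), Xc(m + 1, 0), Yc(m + 1, 0);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
        Mc[0] = Xc[0] = Yc[0] = 0;
        for (int j = 1; j <= m; ++j) {
            int s = (a[i - 1] == b[j - 1]) ? MATCH : MISMATCH;
            int v = std::max(0, s + std::max(Mp[j - 1],
                                             std::max(Xp[j - 1], Yp[j - 1])));
            int x = std::max(0, std::max(Mp[j] + GAP_OPEN, Xp[j] + GAP_EXT));
            int y = std::max(0, std::max(Mc[j - 1] + GAP_OPEN,
                                         Yc[j - 1] + GAP_EXT));
            Mc[j] = v; Xc[j] = x; Yc[j] = y;
            if (v > best) best = v;
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    return best;
}

struct LocalAln {
    int score, matches, columns, a_start, a_end, b_start, b_end;
};

static LocalAln local_align_full(const std::string &a, const std::string &b) {
    int n = a.size(), m = b.size();
    std::vector<int> M((size_t)(n + 1) * (m + 1), 0), X = M, Y = M;
    std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
    // tb for M layer: 0 stop, 1 diag-from-M, 2 diag-from-X, 3 diag-from-Y
    std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1), 0), tbY = tbX;

    auto id = [&](int i, int j) { return (size_t)i * (m + 1) + j; };
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            size_t c = id(i, j), pd = id(i - 1, j - 1),
                   pu = id(i - 1, j), pl = id(i, j - 1);
            int s = (a[i - 1] == b[j - 1]) ? MATCH : MISMATCH;
            int v = 0; unsigned char t = 0;
            if (M[pd] + s > v) { v = M[pd] + s; t = 1; }
            if (X[pd] + s > v) { v = X[pd] + s; t = 2; }
            if (Y[pd] + s > v) { v = Y[pd] + s; t = 3; }
            M[c] = v; tb[c] = t;
            int x = 0; unsigned char tx = 0;
            if (M[pu] + GAP_OPEN > x) { x = M[pu] + GAP_OPEN; tx = 1; }
            if (X[pu] + GAP_EXT > x) { x = X[pu] + GAP_EXT; tx = 2; }
            X[c] = x; tbX[c] = tx;
            int y = 0; unsigned char ty = 0;
            if (M[pl] + GAP_OPEN > y) { y = M[pl] + GAP_OPEN; ty = 1; }
            if (Y[pl] + GAP_EXT > y) { y = Y[pl] + GAP_EXT; ty = 3; }
            Y[c] = y; tbY[c] = ty;
            if (M[c] > best) { best = M[c]; bi = i; bj = j; }
        }
    }
    int matches = 0, cols = 0;
    int i = bi, j = bj, layer = 1;  // 1 = M, 2 = X, 3 = Y
    while (i > 0 && j > 0) {
        size_t c = id(i, j);
        if (layer == 1) {
            unsigned char t = tb[c];
            if (t == 0) break;
            if (a[i - 1] == b[j - 1]) ++matches;
            ++cols; --i; --j; layer = t;
        } else if (layer == 2) {
            unsigned char t = tbX[c];
            if (t == 0) break;
            ++cols; --i; layer = t;
        } else {
            unsigned char t = tbY[c];
            if (t == 0) break;
            ++cols; --j; layer = t;
        }
    }
    return LocalAln{best, matches, cols, i, bi, j, bj};
}

// Smith-Waterman local alignment (affine gaps, same scoring as above).
// Returns the best score and the match/column composition of the best
// local alignment, plus its coordinates (0-based half-open).
// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b) {
    LocalAln r = local_align_full(a, b);
    return List::create(_["score"] = r.score, _["matches"] = r.matches,
                        _["columns"] = r.columns,
                        _["a_start"] = r.a_start, _["a_end"] = r.a_end,
                        _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

// Greedy incremental clustering of tags by local-alignment identity.
// Tags are processed in input order; each is compared against existing
// clusters in creation order (all members, or the founding member only)
// and joins the first / best cluster whose best local alignment reaches
// `threshold` identity over at least `min_overlap` columns.  A
// score-only pass screens candidates first: any alignment with
// identity >= t over >= m columns scores at least (3t-2)*m, so lower
// best scores cannot qualify and the traceback alignment is skipped.
// Returns 1-based cluster ids per tag.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 int min_overlap, bool all_members,
                                 bool join_best) {
    int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    double bd = (3.0 * threshold - 2.0) * min_overlap;
    int sbound = bd > 0 ? (int)std::ceil(bd) : 0;

    std::vector<std::vector<int> > members;
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        int hit = -1;
        double hit_ident = -1.0;
        for (size_t ci = 0; ci < members.size(); ++ci) {
            double best_ident = -1.0;
            bool qualified = false;
            size_t ncand = all_members ? members[ci].size() : 1;
            for (size_t mi = 0; mi < ncand; ++mi) {
                const std::string &t = s[members[ci][mi]];
                if (local_score_only(s[i], t) < sbound) continue;
                LocalAln al = local_align_full(s[i], t);
                if (al.columns < min_overlap) continue;
                double ident = (double)al.matches / al.columns;
                if (ident > best_ident) best_ident = ident;
                if (ident >= threshold) {
                    qualified = true;
                    if (!join_best) break;
                }
            }
            if (qualified) {
                if (!join_best) { hit = (int)ci; break; }
                if (best_ident > hit_ident) {
                    hit = (int)ci; hit_ident = best_ident;
                }
            }
        }
        if (hit < 0) {
            members.push_back(std::vector<int>(1, i));
            out[i] = (int)members.size();
        } else {
            members[hit].push_back(i);
            out[i] = hit + 1;
        }
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Codon-unit global alignment.  Each codon is one DP unit; the
// diagonal score of a codon pair is (+1 per identical base, -1 per
// differing base); codon gaps are affine (-4 first codon, -1 each
// further codon).  Deterministic tie-breaking prefers the diagonal,
// then a gap in A (consuming a B codon).
// [[Rcpp::export]]
List cpp_codon_align(std::string a, std::string b) {
    if (a.size() % 3 || b.size() % 3) stop("sequence length not a multiple of 3");
    int n = a.size() / 3, m = b.size() / 3;
    const int CGO = -4, CGE = -1;
    std::vector<int> M((size_t)(n + 1) * (m + 1), NEG), X = M, Y = M;
    std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0), tbX = tbM, tbY = tbM;
    auto id = [&](int i, int j) { return (size_t)i * (m + 1) + j; };
    auto cscore = [&](int i, int j) {
        int s = 0;
        for (int t = 0; t < 3; ++t)
            s += (a[3 * (i - 1) + t] == b[3 * (j - 1) + t]) ? 1 : -1;
        return s;
    };
    M[id(0, 0)] = 0;
    for (int j = 1; j <= m; ++j) {
        Y[id(0, j)] = CGO + CGE * (j - 1);
        tbY[id(0, j)] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
        X[id(i, 0)] = CGO + CGE * (i - 1);
        tbX[id(i, 0)] = (i == 1) ? 0 : 1;
        for (int j = 1; j <= m; ++j) {
            size_t c = id(i, j), pd = id(i - 1, j - 1),
                   pu = id(i - 1, j), pl = id(i, j - 1);
            int s = cscore(i, j);
            int v = M[pd]; unsigned char t = 0;
            if (Y[pd] > v) { v = Y[pd]; t = 2; }
            if (X[pd] > v) { v = X[pd]; t = 1; }
            if (v > NEG) { M[c] = v + s; tbM[c] = t; }
            int fromM = (M[pu] > NEG) ? M[pu] + CGO : NEG;
            int fromX = (X[pu] > NEG) ? X[pu] + CGE : NEG;
            if (fromM >= fromX) { if (fromM > NEG) { X[c] = fromM; tbX[c] = 0; } }
            else { X[c] = fromX; tbX[c] = 1; }
            fromM = (M[pl] > NEG) ? M[pl] + CGO : NEG;
            int fromY = (Y[pl] > NEG) ? Y[pl] + CGE : NEG;
            if (fromM >= fromY) { if (fromM > NEG) { Y[c] = fromM; tbY[c] = 0; } }
            else { Y[c] = fromY; tbY[c] = 2; }
        }
    }
    size_t e = id(n, m);
    // tie preference at the end point: M, then Y (gap in A), then X
    int layer, best;
    if (M[e] >= Y[e] && M[e] >= X[e]) { layer = 0; best = M[e]; }
    else if (Y[e] >= X[e]) { layer = 2; best = Y[e]; }
    else { layer = 1; best = X[e]; }
    std::string ga, gb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        size_t c = id(i, j);
        if (layer == 0) {
            int t = tbM[c];
            ga.insert(0, a.substr(3 * (i - 1), 3));
            gb.insert(0, b.substr(3 * (j - 1), 3));
            --i; --j; layer = (t == 0) ? 0 : (t == 1 ? 1 : 2);
        } else if (layer == 1) {
            int t = tbX[c];
            ga.insert(0, a.substr(3 * (i - 1), 3));
            gb.insert(0, "---");
            --i; layer = (t == 0) ? 0 : 1;
        } else {
            int t = tbY[c];
            ga.insert(0, "---");
            gb.insert(0, b.substr(3 * (j - 1), 3));
            --j; layer = (t == 0) ? 0 : 2;
        }
    }
    return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                        _["score"] = best);
}
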