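#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base2bits(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't': return 3;
        default: return -1;
    }
}

// Enumerate canonical k-mers of a string; cb(pos, canonical_key, strand)
// strand = 0 if the forward k-mer is canonical, 1 if its revcomp is.
// Positions whose window contains a non-ACGT base are skipped.
template <typename F>
static void scan_kmers(const char *s, int len, int k, F cb) {
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { valid = 0; fwd = rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
        if (++valid >= k) {
            int pos = i - k + 1;
            if (fwd <= rev) cb(pos, fwd, 0);
            else cb(pos, rev, 1);
        }
    }
}

struct Occ { int seq; int pos; unsigned char strand; };

// All-vs-all exact k-mer anchor map over a set of scaffolds.  Every
// canonical k-mer occurring at <= max_mult positions (over the whole
// input) contributes one anchor per pair of distinct occurrences.
// Returned positions are 0-based; orient 0 = forward, 1 = reverse.
// [[Rcpp::export]]
DataFrame cpp_seed_anchors(CharacterVector seqs, int k, int max_mult) {
    std::unordered_map<uint64_t, std::vector<Occ> > occ;
    occ.reserve(1 << 20);
    int nseq = seqs.size();
    for (int si = 0; si < nseq; ++si) {
        const char *s = CHAR(STRING_ELT(seqs, si));
        int len = LENGTH(STRING_ELT(seqs, si));
        scan_kmers(s, len, k, [&](int pos, uint64_t key, int strand) {
            std::vector<Occ> &v = occ[key];
            if ((int)v.size() <= max_mult)  // keep one extra to detect overflow
                v.push_back({si, pos, (unsigned char)strand});
            else if ((int)v.size() == max_mult + 1)
                v.push_back({-1, 0, 0});    // poison marker: too repetitive
        });
    }
    std::vector<int> ai, bi, pa, pb, orient;
    for (auto &kv : occ) {
        std::vector<Occ> &v = kv.second;
        if ((int)v.size() > max_mult) continue;
        if (v.size() < 2) continue;
        for (size_t x = 0; x + 1 < v.size(); ++x) {
            for (size_t y = x + 1; y < v.size(); ++y) {
                const Occ *p = &v[x], *q = &v[y];
                // canonical pair order: lower sequence index first,
                // then lower position
                if (q->seq < p->seq || (q->seq == p->seq && q->pos < p->pos))
                    std::swap(p, q);
                ai.push_back(p->seq + 1);
                bi.push_back(q->seq + 1);
                pa.push_back(p->pos);
                pb.push_back(q->pos);
                orient.push_back(p->strand == q->strand ? 0 : 1);
            }
        }
    }
    return DataFrame::create(_["seq_a"] = wrap(ai), _["seq_b"] = wrap(bi),
                             _["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb),
                             _["orient"] = wrap(orient));
}

// Greedy colinear chaining of anchors from one (scaffold pair,
// orientation) group, already transformed to forward/forward space and
// sorted by (pos_a, pos_b).  An anchor joins the active chain with the
// closest diagonal whose last anchor it can follow: monotone in both
// coordinates, end-to-start gap <= max_gap on both sequences, and, if
// overlapping the previous anchor, on the same diagonal.
// Returns a chain id per anchor (1-based).
// [[Rcpp::export]]
IntegerVector cpp_chain_anchors(IntegerVector pa, IntegerVector pb,
                                int k, int max_gap) {
    int n = pa.size();
    IntegerVector out(n);
    struct Chain { int la, lb, id; };
    std::vector<Chain> active;
    int next_id = 1;
    for (int i = 0; i < n; ++i) {
        int a = pa[i], b = pb[i];
        // expire chains that can no longer be extended
        size_t w = 0;
        for (size_t c = 0; c < active.size(); ++c)
            if (a - (active[c].la + k) <= max_gap) active[w++] = active[c];
        active.resize(w);
        int best = -1; long bestshift = 0;
        for (size_t c = 0; c < active.size(); ++c) {
            int la = active[c].la, lb = active[c].lb;
            if (a <= la || b <= lb) continue;
            if (b - (lb + k) > max_gap) continue;
            // overlapping anchors may sit on a nearby diagonal (an
            // indel shift); refinement skips conflicting overlaps
            long shift = std::labs((long)(a - b) - (long)(la - lb));
            bool overlap = (a < la + k) || (b < lb + k);
            if (overlap && shift > max_gap) continue;
            if (best < 0 || shift < bestshift) { best = (int)c; bestshift = shift; }
        }
        if (best >= 0) {
            active[best].la = a; active[best].lb = b;
            out[i] = active[best].id;
        } else {
            active.push_back({a, b, next_id});
            out[i] = next_id++;
        }
    }
    return out;
}

// Canonical k-mer frequency spectrum over a set of reads.
// Returns the histogram (frequency -> number of distinct canonical
// k-mers) and the total number of counted k-mer instances.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
    std::unordered_map<uint64_t, int> counts;
    counts.reserve(1 << 20);
    double total = 0;
    int nr = reads.size();
    for (int ri = 0; ri < nr; ++ri) {
        const char *s = CHAR(STRING_ELT(reads, ri));
        int len = LENGTH(STRING_ELT(reads, ri));
        scan_kmers(s, len, k, [&](int, uint64_t key, int) {
            ++counts[key];
            total += 1;
        });
    }
    std::unordered_map<int, double> hist;
    for (auto &kv : counts) hist[kv.second] += 1;
    std::vector<int> freq;
    std::vector<double> nk;
    freq.reserve(hist.size()); nk.reserve(hist.size());
    for (auto &kv : hist) { freq.push_back(kv.first); nk.push_back(kv.second); }
    return List::create(_["frequency"] = wrap(freq), _["n_kmers"] = wrap(nk),
                        _["total_instances"] = total);
}
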