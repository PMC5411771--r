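#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

#include "kmer_hash.h"

using namespace Rcpp;
using namespace bdbg;

// ---------------------------------------------------------------------
// Exact (non-probabilistic) reference assembler.
//
// Same algorithm semantics as the Bloom filter pipeline — solid reads,
// branch splitting, depth-bounded look-ahead, visited-set deduplication —
// but implemented over exact hash tables keyed by k-mer strings, with a
// breadth-first survival search.  Deliberately brute force: this is the
// verification oracle, kept free of the rolling-hash/Bloom machinery.
// ---------------------------------------------------------------------

namespace {

typedef std::unordered_set<std::string> StrSet;

std::string canon(const std::string& s) {
    std::string r = revcomp_str(s);
    return s <= r ? s : r;
}

std::vector<std::string> segments_of(const std::string& read) {
    std::vector<std::string> out;
    std::string cur;
    for (char ch : read) {
        int c = base_code(ch);
        if (c < 0) {
            if (!cur.empty()) out.push_back(cur);
            cur.clear();
        } else {
            cur.push_back(code_base(c));
        }
    }
    if (!cur.empty()) out.push_back(cur);
    return out;
}

void count_kmers(CharacterVector reads, int k,
                 std::unordered_map<std::string, double>& counts) {
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        for (const std::string& seg : segments_of(s)) {
            if ((int)seg.size() < k) continue;
            for (int i = 0; i + k <= (int)seg.size(); ++i)
                counts[canon(seg.substr(i, k))] += 1;
        }
    }
}

struct ExactGraph {
    const StrSet* solid;
    int k;
    int depth;

    bool has(const std::string& kmer) const {
        return solid->count(canon(kmer)) != 0;
    }

    std::vector<std::string> raw_succ(const std::string& kmer) const {
        std::vector<std::string> out;
        static const char B[4] = {'A', 'C', 'G', 'T'};
        for (char b : B) {
            std::string s = kmer.substr(1) + b;
            if (has(s)) out.push_back(s);
        }
        return out;
    }

    // Breadth-first survival: does a walk of more than `depth` nodes exist
    // starting at `from` (which counts as the first node)?
    bool survives(const std::string& from) const {
        StrSet frontier{from};
        for (int step = 0; step < depth; ++step) {
            StrSet next;
            for (const std::string& x : frontier)
                for (const std::string& s : raw_succ(x)) next.insert(s);
            if (next.empty()) return false;
            frontier.swap(next);
        }
        return true;
    }

    std::vector<std::string> surv_succ(const std::string& kmer) const {
        std::vector<std::string> cands = raw_succ(kmer);
        if (cands.size() <= 1) return cands;
        std::vector<std::string> out;
        for (const std::string& s : cands)
            if (survives(s)) out.push_back(s);
        return out;
    }

    bool edge_unique(const std::string& x, const std::string& y) const {
        std::vector<std::string> sx = surv_succ(x);
        if (sx.size() != 1 || sx[0] != y) return false;
        std::vector<std::string> sy = surv_succ(revcomp_str(y));
        return sy.size() == 1 && sy[0] == revcomp_str(x);
    }
};

void oracle_extend_right(const ExactGraph& g, std::string& seq,
                         StrSet& visited) {
    for (;;) {
        std::string x = seq.substr(seq.size() - g.k);
        std::vector<std::string> sx = g.surv_succ(x);
        if (sx.size() != 1) break;
        const std::string& y = sx[0];
        std::vector<std::string> sy = g.surv_succ(revcomp_str(y));
        if (sy.size() != 1 || sy[0] != revcomp_str(x)) break;
        std::string cy = canon(y);
        if (visited.count(cy)) break;
        visited.insert(cy);
        seq.push_back(y.back());
    }
}

} // namespace

// Canonical k-mer occurrence counts (small inputs; used by tests).
// [[Rcpp::export]]
List cpp_exact_kmer_counts(CharacterVector reads, int k) {
    std::unordered_map<std::string, double> counts;
    count_kmers(reads, k, counts);
    std::vector<std::string> kmers;
    kmers.reserve(counts.size());
    for (const auto& kv : counts) kmers.push_back(kv.first);
    std::sort(kmers.begin(), kmers.end());
    NumericVector n(kmers.size());
    for (size_t i = 0; i < kmers.size(); ++i) n[i] = counts[kmers[i]];
    return List::create(_["kmer"] = wrap(kmers), _["count"] = n);
}

// Exact reference assembly: canonical unitig sequences, sorted.
// [[Rcpp::export]]
CharacterVector cpp_exact_unitigs(CharacterVector reads, int k, int c,
                                  int depth, int min_len) {
    if (k < 3) stop("k must be >= 3");
    if (c < 1) stop("c must be >= 1");
    std::unordered_map<std::string, double> counts;
    count_kmers(reads, k, counts);
    StrSet solid;
    for (const auto& kv : counts)
        if (kv.second >= c) solid.insert(kv.first);
    counts.clear();
    ExactGraph g{&solid, k, depth};
    StrSet tracked;
    StrSet out;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        std::vector<std::string> segs;
        bool any = false, all_ok = true;
        for (const std::string& seg : segments_of(s)) {
            if ((int)seg.size() < k) continue;
            any = true;
            segs.push_back(seg);
        }
        if (!any) continue;
        for (const std::string& seg : segs) {
            for (int i = 0; all_ok && i + k <= (int)seg.size(); ++i)
                if (!g.has(seg.substr(i, k))) all_ok = false;
            if (!all_ok) break;
        }
        if (!all_ok) continue;
        for (const std::string& seg : segs) {
            int nk = (int)seg.size() - k + 1;
            int a = 0;
            for (int p = 0; p < nk; ++p) {
                bool boundary =
                    (p + 1 == nk) ||
                    !g.edge_unique(seg.substr(p, k), seg.substr(p + 1, k));
                if (!boundary) continue;
                std::string sub = seg.substr(a, p + k - a);
                // skip if fully tracked
                bool novel = false;
                for (int i = 0; i + k <= (int)sub.size(); ++i)
                    if (!tracked.count(canon(sub.substr(i, k)))) {
                        novel = true;
                        break;
                    }
                if (novel) {
                    StrSet visited;
                    for (int i = 0; i + k <= (int)sub.size(); ++i)
                        visited.insert(canon(sub.substr(i, k)));
                    std::string seq = sub;
                    oracle_extend_right(g, seq, visited);
                    std::string rseq = revcomp_str(seq);
                    oracle_extend_right(g, rseq, visited);
                    seq = revcomp_str(rseq);
                    for (const std::string& v : visited) tracked.insert(v);
                    if ((int)seq.size() >= min_len) out.insert(canon(seq));
                }
                a = p + 1;
            }
        }
    }
    std::vector<std::string> v(out.begin(), out.end());
    std::sort(v.begin(), v.end());
    return wrap(v);
}
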