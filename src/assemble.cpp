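#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>

#include "bloom.h"
#include "r_util.h"
#include "u64set.h"

using namespace Rcpp;
using namespace bdbg;

// ---------------------------------------------------------------------
// Probabilistic de Bruijn graph traversal over the solid-k-mer filter.
//
// Edges are discovered by querying the four single-base extensions of the
// current k-mer.  At a branching point a depth-bounded look-ahead decides
// which extensions are real: an extension survives iff some walk of more
// than `depth` nodes exists below it (exact bounded search, memoised).
// Unitig extension steps across an edge x->y only when y is the unique
// surviving successor of x and x is the unique surviving predecessor of y.
// ---------------------------------------------------------------------

namespace {

// Cache of look-ahead outcomes per oriented k-mer (keyed by its forward
// hash).  Reads overlap many-fold, so the same branch decisions recur for
// every read crossing a position; caching them makes the second pass
// scale with distinct solid k-mers rather than k-mer occurrences.
// Open addressing, linear probing; key 0 is the empty sentinel (the
// astronomically rare k-mer hashing to 0 is simply not cached).
struct SurvCache {
    struct Entry {
        uint64_t key;
        uint8_t raw;   // bitmask of solid extensions (bit b = base b)
        uint8_t surv;  // bitmask of surviving extensions
    };
    std::vector<Entry> tab;
    uint64_t mask;
    size_t n = 0;

    SurvCache() : tab((size_t)1 << 12, Entry{0, 0, 0}),
                  mask(((uint64_t)1 << 12) - 1) {}

    Entry* find(uint64_t key) {
        if (!key) return nullptr;
        uint64_t i = mix64(key) & mask;
        while (tab[i].key) {
            if (tab[i].key == key) return &tab[i];
            i = (i + 1) & mask;
        }
        return nullptr;
    }

    void put(uint64_t key, uint8_t raw, uint8_t surv) {
        if (!key) return;
        uint64_t i = mix64(key) & mask;
        while (tab[i].key) {
            if (tab[i].key == key) return;
            i = (i + 1) & mask;
        }
        tab[i] = Entry{key, raw, surv};
        if (10 * ++n > 7 * (mask + 1)) grow();
    }

    void grow() {
        std::vector<Entry> old;
        old.swap(tab);
        tab.assign((size_t)(mask + 1) * 2, Entry{0, 0, 0});
        mask = mask * 2 + 1;
        for (const Entry& e : old) {
            if (!e.key) continue;
            uint64_t i = mix64(e.key) & mask;
            while (tab[i].key) i = (i + 1) & mask;
            tab[i] = e;
        }
    }
};

struct Ctx {
    Bloom* bf;     // solid-k-mer filter (last cascade level)
    int k;
    int depth;     // look-ahead depth in nodes
    double steps;  // k-mer membership probes issued during traversal
    SurvCache* cache = nullptr;
};

Bloom* resolve_filter(SEXP handle, bool is_cascade) {
    if (is_cascade) {
        XPtr<Cascade> p(handle);
        Bloom* b = p->last();
        if (!b) stop("cascade last level is missing");
        return b;
    }
    XPtr<Bloom> p(handle);
    return p;
}

// Solid single-base extensions of w.  Hashes of all four candidates are
// derived in O(1) from w; candidate strings are only materialised for
// extensions present in the filter.
int raw_successors(Ctx& ctx, const Walker& w, Walker* cand, int* codes) {
    int out = base_code(w.b[0]);
    uint64_t f1 = rol64(w.fh, 1) ^ rol64(KSEED[out], (unsigned)ctx.k);
    uint64_t r1 = ror64(w.rh ^ KSEED[comp_code(out)], 1);
    int n = 0;
    for (int b = 0; b < 4; ++b) {
        uint64_t fh = f1 ^ KSEED[b];
        uint64_t rh = r1 ^ rol64(KSEED[comp_code(b)], (unsigned)(ctx.k - 1));
        ctx.steps += 1;
        if (ctx.bf->contains(fh < rh ? fh : rh)) {
            cand[n].b.assign(w.b, 1, std::string::npos);
            cand[n].b.push_back(code_base(b));
            cand[n].fh = fh;
            cand[n].rh = rh;
            codes[n] = b;
            ++n;
        }
    }
    return n;
}

// Depth-bounded survival search.  The DFS walks one shared path buffer
// (the candidate window plus the bases pushed so far), so a node at
// recursion offset `pos` has window buf[pos, pos+k); hashes roll in O(1)
// and no per-node memory is allocated.
struct Dfs {
    Ctx* ctx;
    std::string buf; // candidate window + path bases
    std::unordered_map<uint64_t, int> failed; // fwd hash -> budget failed
    bool use_memo = false;

    // 1 = survives, 0 = dies, -1 = node budget exhausted
    int run(int pos, uint64_t fh, uint64_t rh, int left, int& budget) {
        if (left <= 0) return 1;
        if (!use_memo) {
            if (--budget < 0) return -1;
        } else {
            auto it = failed.find(fh);
            if (it != failed.end() && it->second >= left) return 0;
        }
        int k = ctx->k;
        int out = base_code(buf[pos]);
        uint64_t f1 = rol64(fh, 1) ^ rol64(KSEED[out], (unsigned)k);
        uint64_t r1 = ror64(rh ^ KSEED[comp_code(out)], 1);
        bool exhausted = false;
        for (int b = 0; b < 4; ++b) {
            uint64_t fh2 = f1 ^ KSEED[b];
            uint64_t rh2 = r1 ^ rol64(KSEED[comp_code(b)],
                                      (unsigned)(k - 1));
            ctx->steps += 1;
            if (!ctx->bf->contains(fh2 < rh2 ? fh2 : rh2)) continue;
            buf.push_back(code_base(b));
            int r = run(pos + 1, fh2, rh2, left - 1, budget);
            buf.pop_back();
            if (r == 1) return 1;
            if (r == -1) exhausted = true;
        }
        if (exhausted) return -1;
        if (use_memo) {
            auto& slot = failed[fh];
            if (slot < left) slot = left;
        }
        return 0;
    }
};

// A candidate extension survives iff a walk of more than `depth` nodes
// (the candidate counting as the first) hangs below it.  Small search
// trees (the overwhelmingly common case) are handled without the memo
// table; pathological ones fall back to the memoised exact search.
bool survives(Ctx& ctx, const Walker& cand) {
    Dfs dfs;
    dfs.ctx = &ctx;
    dfs.buf = cand.b;
    int budget = 16 * ctx.depth;
    int r = dfs.run(0, cand.fh, cand.rh, ctx.depth, budget);
    if (r >= 0) return r == 1;
    dfs.use_memo = true;
    dfs.buf = cand.b;
    budget = 0;
    return dfs.run(0, cand.fh, cand.rh, ctx.depth, budget) == 1;
}

// Rebuild the candidate walkers selected by `mask` without any filter
// probes (hashes roll in O(1) from w).
int candidates_from_mask(Ctx& ctx, const Walker& w, uint8_t mask,
                         Walker* cand, int* codes) {
    int out = base_code(w.b[0]);
    uint64_t f1 = rol64(w.fh, 1) ^ rol64(KSEED[out], (unsigned)ctx.k);
    uint64_t r1 = ror64(w.rh ^ KSEED[comp_code(out)], 1);
    int n = 0;
    for (int b = 0; b < 4; ++b) {
        if (!((mask >> b) & 1)) continue;
        cand[n].b.assign(w.b, 1, std::string::npos);
        cand[n].b.push_back(code_base(b));
        cand[n].fh = f1 ^ KSEED[b];
        cand[n].rh = r1 ^ rol64(KSEED[comp_code(b)], (unsigned)(ctx.k - 1));
        codes[n] = b;
        ++n;
    }
    return n;
}

// Surviving extensions.  The look-ahead is only invoked at branching
// points: with zero or one raw candidate the raw set is returned as is.
// Outcomes are cached per oriented k-mer when a cache is attached.
int surviving_successors(Ctx& ctx, const Walker& w, Walker* cand, int* codes,
                         int* n_raw = nullptr) {
    if (ctx.cache) {
        SurvCache::Entry* e = ctx.cache->find(w.fh);
        if (e) {
            if (n_raw) *n_raw = __builtin_popcount(e->raw);
            return candidates_from_mask(ctx, w, e->surv, cand, codes);
        }
    }
    int n = raw_successors(ctx, w, cand, codes);
    uint8_t raw_mask = 0;
    for (int i = 0; i < n; ++i) raw_mask |= (uint8_t)(1u << codes[i]);
    if (n_raw) *n_raw = n;
    int m = n;
    if (n > 1) {
        m = 0;
        for (int i = 0; i < n; ++i) {
            if (survives(ctx, cand[i])) {
                cand[m] = cand[i];
                codes[m] = codes[i];
                ++m;
            }
        }
    }
    if (ctx.cache) {
        uint8_t surv_mask = 0;
        for (int i = 0; i < m; ++i) surv_mask |= (uint8_t)(1u << codes[i]);
        ctx.cache->put(w.fh, raw_mask, surv_mask);
    }
    return m;
}

// Is the edge x->y (y = x shifted by appended base) a unitig-interior edge?
// Requires y to be x's unique surviving successor and x to be y's unique
// surviving predecessor (queried on the reverse strand).
bool edge_unique(Ctx& ctx, const Walker& x, const Walker& y) {
    Walker cand[4];
    int codes[4];
    int ns = surviving_successors(ctx, x, cand, codes);
    if (ns != 1 || cand[0].fh != y.fh) return false;
    Walker yr = rc_walker(y);
    int np = surviving_successors(ctx, yr, cand, codes);
    return np == 1 && codes[0] == comp_code(base_code(x.b[0]));
}

// Append bases rightward from the walker of the current last k-mer.
// `visited` holds canonical hashes of all k-mers of the growing unitig and
// doubles as the cycle guard.
void extend_right(Ctx& ctx, std::string& seq, Walker cur,
                  std::unordered_set<uint64_t>& visited) {
    for (;;) {
        Walker cand[4];
        int codes[4];
        int ns = surviving_successors(ctx, cur, cand, codes);
        if (ns != 1) break;
        Walker y = cand[0];
        Walker yr = rc_walker(y);
        int np = surviving_successors(ctx, yr, cand, codes);
        if (np != 1 || codes[0] != comp_code(base_code(cur.b[0]))) break;
        if (visited.count(y.canonical())) break; // circular structure
        visited.insert(y.canonical());
        seq.push_back(y.b.back());
        cur = y;
    }
}

// ACGT segments of a read, uppercased.
std::vector<std::string> acgt_segments(const std::string& read) {
    std::vector<std::string> segs;
    std::string cur;
    for (char ch : read) {
        int c = base_code(ch);
        if (c < 0) {
            if (!cur.empty()) segs.push_back(cur);
            cur.clear();
        } else {
            cur.push_back(code_base(c));
        }
    }
    if (!cur.empty()) segs.push_back(cur);
    return segs;
}

std::vector<Walker> segment_walkers(const std::string& seg, int k) {
    std::vector<Walker> ws;
    if ((int)seg.size() < k) return ws;
    ws.reserve(seg.size() - k + 1);
    Walker w;
    make_walker(seg.c_str(), k, w);
    ws.push_back(w);
    for (int i = 1; i + k <= (int)seg.size(); ++i)
        ws.push_back(succ_walker(ws.back(), base_code(seg[i + k - 1])));
    return ws;
}

// Rolling canonical-hash scan of a clean ACGT segment; calls fn(canon)
// for every window.  Returns false early if fn returns false.
template <class F>
bool scan_segment(const std::string& seg, int k, F fn) {
    int n = (int)seg.size();
    if (n < k) return true;
    std::vector<int> codes(n);
    for (int i = 0; i < n; ++i) codes[i] = base_code(seg[i]);
    uint64_t fh = hash_fwd(codes.data(), k);
    uint64_t rh = hash_rc(codes.data(), k);
    for (int i = 0;; ++i) {
        if (!fn(fh < rh ? fh : rh)) return false;
        if (i + k >= n) return true;
        int out = codes[i], in = codes[i + k];
        fh = rol64(fh, 1) ^ rol64(KSEED[out], (unsigned)k) ^ KSEED[in];
        rh = ror64(rh ^ KSEED[comp_code(out)], 1) ^
             rol64(KSEED[comp_code(in)], (unsigned)(k - 1));
    }
}

bool segment_all_solid(Ctx& ctx, const std::string& seg) {
    return scan_segment(seg, ctx.k, [&](uint64_t canon) {
        return ctx.bf->contains(canon);
    });
}

// 2-bit packed canonical scan for exact distinct counting (k <= 64);
// falls back to the canonical hash as identity for larger k.
template <class F>
void scan_packed(const std::string& seg, int k, F fn) {
    int n = (int)seg.size();
    if (n < k) return;
    bool packed = k <= 64;
    u128 mask = (k >= 64) ? ~(u128)0 : (((u128)1 << (2 * k)) - 1);
    std::vector<int> codes(n);
    for (int i = 0; i < n; ++i) codes[i] = base_code(seg[i]);
    uint64_t fh = hash_fwd(codes.data(), k);
    uint64_t rh = hash_rc(codes.data(), k);
    u128 pf = 0, pr = 0;
    if (packed) {
        for (int i = 0; i < k; ++i) {
            pf = ((pf << 2) | (u128)codes[i]) & mask;
            pr = (pr >> 2) |
                 ((u128)comp_code(codes[i]) << (2 * (k - 1)));
        }
    }
    for (int i = 0;; ++i) {
        uint64_t canon_hash = fh < rh ? fh : rh;
        u128 ident = packed ? (pf < pr ? pf : pr) : (u128)canon_hash;
        fn(canon_hash, ident);
        if (i + k >= n) return;
        int out = codes[i], in = codes[i + k];
        fh = rol64(fh, 1) ^ rol64(KSEED[out], (unsigned)k) ^ KSEED[in];
        rh = ror64(rh ^ KSEED[comp_code(out)], 1) ^
             rol64(KSEED[comp_code(in)], (unsigned)(k - 1));
        if (packed) {
            pf = ((pf << 2) | (u128)in) & mask;
            pr = (pr >> 2) | ((u128)comp_code(in) << (2 * (k - 1)));
        }
    }
}

} // namespace

// ---- first pass: k-mer loading ---------------------------------------

// Inserts every canonical k-mer occurrence into the cascade; optionally
// counts distinct canonical k-mers exactly (2-bit packing for k <= 32,
// canonical 64-bit hash set beyond).
// [[Rcpp::export]]
List cpp_load_pass(SEXP cascade, CharacterVector reads, int k,
                   bool count_distinct) {
    XPtr<Cascade> cf(cascade);
    U128Set seen;
    double n_kmers = 0;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        for (const std::string& seg : acgt_segments(s)) {
            if ((int)seg.size() < k) continue;
            scan_packed(seg, k, [&](uint64_t canon, u128 ident) {
                cf->insert(canon);
                n_kmers += 1;
                if (count_distinct) seen.insert(ident);
            });
        }
    }
    return List::create(_["kmers"] = n_kmers,
                        _["distinct"] = count_distinct
                            ? (double)seen.size() : NA_REAL);
}

// Exact distinct canonical k-mer count without touching any filter
// (presampling pass for FPR-targeted sizing).
// [[Rcpp::export]]
double cpp_distinct_kmers(CharacterVector reads, int k) {
    U128Set seen;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        for (const std::string& seg : acgt_segments(s)) {
            if ((int)seg.size() < k) continue;
            scan_packed(seg, k, [&](uint64_t, u128 ident) {
                seen.insert(ident);
            });
        }
    }
    return (double)seen.size();
}

// ---- graph queries ----------------------------------------------------

// [[Rcpp::export]]
List cpp_successors(SEXP filter, bool is_cascade, std::string kmer) {
    Ctx ctx{resolve_filter(filter, is_cascade), (int)kmer.size(),
            (int)kmer.size(), 0};
    Walker w;
    if (!make_walker(kmer.c_str(), ctx.k, w))
        stop("k-mer contains a non-ACGT character");
    Walker cand[4];
    int codes[4];
    int n = raw_successors(ctx, w, cand, codes);
    CharacterVector bases(n), kmers(n);
    for (int i = 0; i < n; ++i) {
        bases[i] = std::string(1, code_base(codes[i]));
        kmers[i] = cand[i].b;
    }
    return List::create(_["base"] = bases, _["kmer"] = kmers);
}

// [[Rcpp::export]]
List cpp_lookahead_classify(SEXP filter, bool is_cascade, std::string kmer,
                            int depth) {
    Ctx ctx{resolve_filter(filter, is_cascade), (int)kmer.size(), depth, 0};
    if (depth < 1) stop("depth must be >= 1");
    Walker w;
    if (!make_walker(kmer.c_str(), ctx.k, w))
        stop("k-mer contains a non-ACGT character");
    Walker cand[4];
    int codes[4];
    int n_raw = 0;
    int ns = surviving_successors(ctx, w, cand, codes, &n_raw);
    CharacterVector surv(ns);
    for (int i = 0; i < ns; ++i) surv[i] = std::string(1, code_base(codes[i]));
    std::string kind;
    if (ns == 0) kind = "dead_end";
    else if (ns >= 2) kind = "true_branch";
    else kind = (n_raw > 1) ? "false_branch_pruned" : "unique";
    return List::create(_["kind"] = kind, _["surviving"] = surv,
                        _["n_raw"] = n_raw, _["steps"] = ctx.steps);
}

// ---- second pass building blocks --------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_is_solid_read(SEXP filter, bool is_cascade,
                                CharacterVector reads, int k) {
    Ctx ctx{resolve_filter(filter, is_cascade), k, k, 0};
    LogicalVector out(reads.size());
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        bool any = false, ok = true;
        for (const std::string& seg : acgt_segments(s)) {
            if ((int)seg.size() < k) continue;
            any = true;
            if (!segment_all_solid(ctx, seg)) { ok = false; break; }
        }
        out[r] = any && ok;
    }
    return out;
}

// Branch-free sub-segments of a solid read: 1-based [start, end] base
// coordinates within the read, split wherever consecutive k-mers are not
// joined by a unitig-interior edge.
// [[Rcpp::export]]
List cpp_split_at_branches(SEXP filter, bool is_cascade, std::string read,
                           int k, int depth) {
    Ctx ctx{resolve_filter(filter, is_cascade), k, depth, 0};
    SurvCache cache;
    ctx.cache = &cache;
    std::vector<int> starts, ends;
    std::vector<std::string> seqs;
    // offsets of ACGT segments within the read
    int n = (int)read.size();
    int i = 0;
    while (i < n) {
        while (i < n && base_code(read[i]) < 0) ++i;
        int j = i;
        while (j < n && base_code(read[j]) >= 0) ++j;
        if (j - i >= k) {
            std::string seg;
            for (int t = i; t < j; ++t)
                seg.push_back(code_base(base_code(read[t])));
            std::vector<Walker> ws = segment_walkers(seg, k);
            int a = 0; // first k-mer index of current sub-segment
            for (size_t p = 0; p + 1 < ws.size(); ++p) {
                if (!edge_unique(ctx, ws[p], ws[p + 1])) {
                    starts.push_back(i + a + 1);
                    ends.push_back(i + (int)p + k);
                    seqs.push_back(seg.substr(a, (int)p + k - a));
                    a = (int)p + 1;
                }
            }
            starts.push_back(i + a + 1);
            ends.push_back(i + (int)ws.size() - 1 + k);
            seqs.push_back(seg.substr(a, (int)ws.size() - 1 + k - a));
        }
        i = j;
    }
    return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                        _["sequence"] = wrap(seqs));
}

static List extend_segment(Ctx& ctx, Bloom* tracking,
                           const std::string& segment, int min_len) {
    std::vector<Walker> ws = segment_walkers(segment, ctx.k);
    if (ws.empty()) stop("segment shorter than k");
    // skip if every k-mer is already tracked
    bool novel = false;
    for (const auto& w : ws)
        if (!tracking->contains(w.canonical())) { novel = true; break; }
    if (!novel)
        return List::create(_["skipped"] = true, _["sequence"] = "",
                            _["emit"] = false, _["steps"] = ctx.steps);
    std::unordered_set<uint64_t> visited;
    for (const auto& w : ws) visited.insert(w.canonical());
    std::string seq = segment;
    extend_right(ctx, seq, ws.back(), visited);
    // left extension: extend the reverse complement rightward
    std::string rseq = revcomp_str(seq);
    Walker last;
    make_walker(rseq.c_str() + (rseq.size() - ctx.k), ctx.k, last);
    extend_right(ctx, rseq, last, visited);
    seq = revcomp_str(rseq);
    for (uint64_t cy : visited) tracking->insert(cy);
    bool emit = (int)seq.size() >= min_len;
    return List::create(_["skipped"] = false, _["sequence"] = seq,
                        _["emit"] = emit, _["steps"] = ctx.steps);
}

// [[Rcpp::export]]
List cpp_extend_seed(SEXP filter, bool is_cascade, SEXP tracking,
                     std::string segment, int depth, int min_len, int k) {
    Ctx ctx{resolve_filter(filter, is_cascade), k, depth, 0};
    SurvCache cache;
    ctx.cache = &cache;
    XPtr<Bloom> tr(tracking);
    return extend_segment(ctx, tr, segment, min_len);
}

// Full second pass: solid-read identification, branch splitting, seed
// extension and tracking-filter deduplication, in input order.
// [[Rcpp::export]]
List cpp_pass2(SEXP filter, bool is_cascade, SEXP tracking,
               CharacterVector reads, int k, int depth, int min_len) {
    Ctx ctx{resolve_filter(filter, is_cascade), k, depth, 0};
    SurvCache cache;
    ctx.cache = &cache;
    XPtr<Bloom> tr(tracking);
    std::vector<std::string> unitigs;
    std::vector<int> seed_read;
    double n_solid = 0, n_with_kmer = 0;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        std::vector<std::string> segs;
        bool any = false, solid = true;
        for (const std::string& seg : acgt_segments(s)) {
            if ((int)seg.size() < k) continue;
            any = true;
            segs.push_back(seg);
        }
        if (!any) continue;
        n_with_kmer += 1;
        for (const std::string& seg : segs) {
            if (!segment_all_solid(ctx, seg)) { solid = false; break; }
        }
        if (!solid) continue;
        n_solid += 1;
        for (const std::string& seg : segs) {
            // split at branch points, then extend each sub-segment
            std::vector<Walker> ws = segment_walkers(seg, k);
            size_t a = 0;
            for (size_t p = 0; p <= ws.size() - 1; ++p) {
                bool boundary = (p + 1 == ws.size()) ||
                                !edge_unique(ctx, ws[p], ws[p + 1]);
                if (!boundary) continue;
                std::string sub = seg.substr(a, p + k - a);
                List res = extend_segment(ctx, tr, sub, min_len);
                if (as<bool>(res["emit"])) {
                    unitigs.push_back(as<std::string>(res["sequence"]));
                    seed_read.push_back((int)r + 1);
                }
                a = p + 1;
            }
        }
    }
    return List::create(_["unitigs"] = wrap(unitigs),
                        _["seed_read"] = wrap(seed_read),
                        _["n_reads"] = (double)reads.size(),
                        _["n_reads_with_kmer"] = n_with_kmer,
                        _["n_solid_reads"] = n_solid,
                        _["steps"] = ctx.steps);
}
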