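#include <Rcpp.h>
#include "kmer_hash.h"
#include "r_util.h"

using namespace Rcpp;
using namespace bdbg;

// Direct (from-scratch) hashes of whole k-mers.  Stops at the first
// non-ACGT character, reporting its 1-based position.
// [[Rcpp::export]]
List cpp_hash_kmer(CharacterVector kmers) {
    R_xlen_t n = kmers.size();
    CharacterVector fwd(n), rc(n), canon(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        Walker w;
        if (!make_walker(s.c_str(), (int)s.size(), w)) {
            for (size_t j = 0; j < s.size(); ++j)
                if (base_code(s[j]) < 0)
                    stop("non-ACGT character '%c' at position %d of k-mer %d",
                         s[j], (int)(j + 1), (int)(i + 1));
        }
        fwd[i] = to_hex(w.fh);
        rc[i] = to_hex(w.rh);
        canon[i] = to_hex(w.canonical());
    }
    return List::create(_["fwd"] = fwd, _["rc"] = rc, _["canonical"] = canon);
}

// Rolling hashes of all k-mer windows of one sequence.  Windows containing
// non-ACGT characters are skipped (their pos is absent from the output).
// [[Rcpp::export]]
List cpp_hash_kmers(std::string seq, int k) {
    if (k < 1) stop("k must be >= 1");
    std::vector<int> pos;
    std::vector<std::string> fwd, rc, canon;
    int n = (int)seq.size();
    int i = 0;
    while (i + k <= n) {
        Walker w;
        if (!make_walker(seq.c_str() + i, k, w)) {
            // jump past the offending character
            int bad = i;
            for (int j = i; j < i + k; ++j)
                if (base_code(seq[j]) < 0) { bad = j; break; }
            i = bad + 1;
            continue;
        }
        for (;;) {
            pos.push_back(i + 1);
            fwd.push_back(to_hex(w.fh));
            rc.push_back(to_hex(w.rh));
            canon.push_back(to_hex(w.canonical()));
            if (i + k >= n) { i = n; break; }
            int code = base_code(seq[i + k]);
            if (code < 0) { i = i + k + 1; break; }
            w = succ_walker(w, code);
            ++i;
        }
    }
    return List::create(_["pos"] = wrap(pos), _["fwd"] = wrap(fwd),
                        _["rc"] = wrap(rc), _["canonical"] = wrap(canon));
}

// Multi-hash schedule: h derived 64-bit values per base key.
// [[Rcpp::export]]
CharacterMatrix cpp_multi_hash(SEXP keys, int h, double seed) {
    if (h < 1) stop("h must be >= 1");
    if (h > 64) stop("h must be <= 64");
    std::vector<uint64_t> ks = parse_keys(keys);
    CharacterMatrix out((int)ks.size(), h);
    uint64_t v[64];
    for (size_t i = 0; i < ks.size(); ++i) {
        multi_hash(ks[i], h, (uint64_t)seed, v);
        for (int j = 0; j < h; ++j) out((int)i, j) = to_hex(v[j]);
    }
    return out;
}

// Per-bit occupancy of each derived hash stream over n random base keys
// (keys drawn from R's RNG).  Returns a 64 x h matrix of set-bit counts.
// [[Rcpp::export]]
NumericMatrix cpp_multi_hash_bit_counts(double n, int h, double seed) {
    if (h < 1 || h > 64) stop("h must be in 1..64");
    NumericMatrix counts(64, h);
    uint64_t v[64];
    RNGScope scope;
    for (double i = 0; i < n; ++i) {
        uint64_t base = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                        (uint64_t)(unif_rand() * 4294967296.0);
        multi_hash(base, h, (uint64_t)seed, v);
        for (int j = 0; j < h; ++j)
            for (int b = 0; b < 64; ++b)
                if ((v[j] >> b) & 1ULL) counts(b, j) += 1;
    }
    return counts;
}

// Mean number of output bits changed by a single random base substitution,
// over n random k-mers (avalanche diagnostic).
// [[Rcpp::export]]
double cpp_avalanche(int n, int k) {
    RNGScope scope;
    double total = 0;
    for (int i = 0; i < n; ++i) {
        std::string s(k, 'A');
        for (int j = 0; j < k; ++j)
            s[j] = code_base((int)(unif_rand() * 4.0) & 3);
        Walker w;
        make_walker(s.c_str(), k, w);
        int pos = (int)(unif_rand() * k);
        if (pos >= k) pos = k - 1;
        int old = base_code(s[pos]);
        int sub = (old + 1 + (int)(unif_rand() * 3.0)) & 3;
        if (sub == old) sub = (old + 1) & 3;
        std::string t = s;
        t[pos] = code_base(sub);
        Walker wm;
        make_walker(t.c_str(), k, wm);
        total += __builtin_popcountll(w.fh ^ wm.fh);
    }
    return total / n;
}

// Byte-wise canonical form: lexicographic min of a sequence and its
// reverse complement (locale-independent).
// [[Rcpp::export]]
CharacterVector cpp_canonical_sequence(CharacterVector x) {
    CharacterVector out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) {
        std::string s = as<std::string>(x[i]);
        for (auto& c : s) c = (char)toupper((unsigned char)c);
        std::string r = revcomp_str(s);
        out[i] = s <= r ? s : r;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
    CharacterVector out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i)
        out[i] = revcomp_str(as<std::string>(x[i]));
    return out;
}
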