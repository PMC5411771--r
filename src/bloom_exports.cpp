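#include <Rcpp.h>
#include "bloom.h"
#include "r_util.h"

using namespace Rcpp;
using namespace bdbg;

// [[Rcpp::export]]
SEXP cpp_bf_new(double m_bits, int h, double seed) {
    XPtr<Bloom> p(new Bloom((uint64_t)m_bits, h, (uint64_t)seed), true);
    return p;
}

// [[Rcpp::export]]
void cpp_bf_insert(SEXP ptr, SEXP keys) {
    XPtr<Bloom> p(ptr);
    for (uint64_t k : parse_keys(keys)) p->insert(k);
}

// [[Rcpp::export]]
LogicalVector cpp_bf_contains(SEXP ptr, SEXP keys) {
    XPtr<Bloom> p(ptr);
    std::vector<uint64_t> ks = parse_keys(keys);
    LogicalVector out(ks.size());
    for (size_t i = 0; i < ks.size(); ++i) out[i] = p->contains(ks[i]);
    return out;
}

// [[Rcpp::export]]
List cpp_bf_info(SEXP ptr) {
    XPtr<Bloom> p(ptr);
    return List::create(_["m"] = (double)p->m, _["h"] = p->h,
                        _["seed"] = (double)p->seed,
                        _["inserts"] = (double)p->n_insert,
                        _["popcount"] = (double)p->popcount());
}

// Insert every canonical k-mer of the given sequences (ACGT segments only).
// [[Rcpp::export]]
double cpp_bf_insert_kmers(SEXP ptr, CharacterVector seqs, int k) {
    XPtr<Bloom> p(ptr);
    double n = 0;
    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
        std::string s = as<std::string>(seqs[r]);
        int len = (int)s.size(), i = 0;
        while (i + k <= len) {
            Walker w;
            if (!make_walker(s.c_str() + i, k, w)) {
                int bad = i;
                for (int j = i; j < i + k; ++j)
                    if (base_code(s[j]) < 0) { bad = j; break; }
                i = bad + 1;
                continue;
            }
            for (;;) {
                p->insert(w.canonical());
                n += 1;
                if (i + k >= len) { i = len; break; }
                int code = base_code(s[i + k]);
                if (code < 0) { i = i + k + 1; break; }
                w = succ_walker(w, code);
                ++i;
            }
        }
    }
    return n;
}

// Raw little-endian dump of the bit vector (for save_bloom).
// [[Rcpp::export]]
RawVector cpp_bf_dump(SEXP ptr) {
    XPtr<Bloom> p(ptr);
    size_t nbytes = (size_t)(p->m / 8);
    RawVector out((R_xlen_t)nbytes);
    for (size_t i = 0; i < nbytes; ++i)
        out[(R_xlen_t)i] = (Rbyte)((p->w[i >> 3] >> ((i & 7u) * 8u)) & 0xffu);
    return out;
}

// [[Rcpp::export]]
SEXP cpp_bf_restore(double m_bits, int h, double seed, double inserts,
                    RawVector bytes) {
    XPtr<Bloom> p(new Bloom((uint64_t)m_bits, h, (uint64_t)seed), true);
    if ((uint64_t)bytes.size() != p->m / 8)
        stop("bit-vector length does not match m");
    p->n_insert = (uint64_t)inserts;
    for (R_xlen_t i = 0; i < bytes.size(); ++i)
        p->w[(size_t)i >> 3] |= ((uint64_t)(unsigned char)bytes[i])
                                << (((size_t)i & 7u) * 8u);
    return p;
}

// ---- cascading Bloom filter -------------------------------------------

// [[Rcpp::export]]
SEXP cpp_cbf_new(double m_bits, int h, double seed, int c) {
    XPtr<Cascade> p(new Cascade((uint64_t)m_bits, h, (uint64_t)seed, c), true);
    return p;
}

// [[Rcpp::export]]
void cpp_cbf_insert(SEXP ptr, SEXP keys) {
    XPtr<Cascade> p(ptr);
    for (uint64_t k : parse_keys(keys)) p->insert(k);
}

// [[Rcpp::export]]
LogicalVector cpp_cbf_contains(SEXP ptr, SEXP keys, int level) {
    XPtr<Cascade> p(ptr);
    if (level < 1 || level > p->c) stop("level must be in 1..c");
    if (!p->levels[level - 1]) stop("cascade level %d has been dropped", level);
    std::vector<uint64_t> ks = parse_keys(keys);
    LogicalVector out(ks.size());
    for (size_t i = 0; i < ks.size(); ++i)
        out[i] = p->levels[level - 1]->contains(ks[i]);
    return out;
}

// [[Rcpp::export]]
List cpp_cbf_info(SEXP ptr) {
    XPtr<Cascade> p(ptr);
    NumericVector ins(p->c), bits(p->c);
    for (int i = 0; i < p->c; ++i) {
        ins[i] = p->levels[i] ? (double)p->levels[i]->n_insert : NA_REAL;
        bits[i] = (double)p->m; // equal-size levels by construction
    }
    return List::create(_["m"] = (double)p->m, _["h"] = p->h,
                        _["seed"] = (double)p->seed, _["c"] = p->c,
                        _["level_inserts"] = ins, _["level_bits"] = bits);
}

// [[Rcpp::export]]
void cpp_cbf_drop_early(SEXP ptr) {
    XPtr<Cascade> p(ptr);
    p->drop_early();
}
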