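#ifndef BLOOMDBG_KMER_HASH_H
#define BLOOMDBG_KMER_HASH_H

#include <cstdint>
#include <string>
#include <stdexcept>
#include <vector>

// Rolling canonical multi-hash for DNA k-mers.
//
// The forward hash of a k-mer s[0..k-1] is
//   fh = XOR_i rol(SEED[s[i]], (k-1-i) mod 64)
// i.e. a cyclic-polynomial (rotate/xor) combination of one fixed 64-bit
// constant per nucleotide, position-encoded by bit rotation.  Shifting the
// window one base updates fh in O(1).  The reverse-complement hash is
// maintained alongside so the canonical value min(fh, rh) is available in
// O(1) on both strands.

namespace bdbg {

// Fixed per-base seed constants, frozen by golden-value tests.
static const uint64_t KSEED[4] = {
    0x6c5d2f7a913be84fULL, // A
    0x28b1d6f39a07c45eULL, // C
    0xd94ae17f52c8b063ULL, // G
    0x83f6b92c04e7d5a1ULL  // T
};

inline uint64_t rol64(uint64_t x, unsigned r) {
    r &= 63u;
    return r ? (x << r) | (x >> (64u - r)) : x;
}

inline uint64_t ror64(uint64_t x, unsigned r) {
    r &= 63u;
    return r ? (x >> r) | (x << (64u - r)) : x;
}

// A, C, G, T -> 0..3 (lower case accepted); anything else -> -1.
inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

inline char code_base(int code) {
    static const char b[4] = {'A', 'C', 'G', 'T'};
    return b[code];
}

inline int comp_code(int code) { return 3 - code; }

// From-scratch forward hash; caller guarantees codes are valid.
inline uint64_t hash_fwd(const int* codes, int k) {
    uint64_t h = 0;
    for (int i = 0; i < k; ++i)
        h ^= rol64(KSEED[codes[i]], (unsigned)(k - 1 - i));
    return h;
}

// From-scratch hash of the reverse complement of the same window.
inline uint64_t hash_rc(const int* codes, int k) {
    uint64_t h = 0;
    for (int i = 0; i < k; ++i)
        h ^= rol64(KSEED[comp_code(codes[i])], (unsigned)i);
    return h;
}

// splitmix64 finalizer, used to derive the multi-hash stride.
inline uint64_t mix64(uint64_t z) {
    z += 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
}

// h derived values: value_i = base + i * g(base, seed), g odd so the
// schedule never degenerates.  value_0 == base.
inline void multi_hash(uint64_t base, int h, uint64_t seed, uint64_t* out) {
    uint64_t g = mix64(base ^ (seed * 0x9e3779b97f4a7c15ULL)) | 1ULL;
    uint64_t v = base;
    for (int i = 0; i < h; ++i) {
        out[i] = v;
        v += g;
    }
}

// An oriented k-mer window with its forward and reverse-complement hashes
// maintained under O(1) single-base shifts.
struct Walker {
    std::string b;  // bases as traversed (upper case A/C/G/T)
    uint64_t fh = 0, rh = 0;

    int k() const { return (int)b.size(); }
    uint64_t canonical() const { return fh < rh ? fh : rh; }
};

// Build a walker from scratch; returns false on a non-ACGT character.
inline bool make_walker(const char* s, int k, Walker& w) {
    std::vector<int> codes(k);
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[i]);
        if (c < 0) return false;
        codes[i] = c;
    }
    w.b.assign(s, s + k);
    for (auto& ch : w.b) ch = (char)toupper((unsigned char)ch);
    w.fh = hash_fwd(codes.data(), k);
    w.rh = hash_rc(codes.data(), k);
    return true;
}

// Successor window: drop the first base, append `code`.
inline Walker succ_walker(const Walker& w, int code) {
    int k = w.k();
    int out = base_code(w.b[0]);
    Walker s;
    s.b = w.b.substr(1);
    s.b.push_back(code_base(code));
    s.fh = rol64(w.fh, 1) ^ rol64(KSEED[out], (unsigned)k) ^ KSEED[code];
    s.rh = ror64(w.rh ^ KSEED[comp_code(out)], 1) ^
           rol64(KSEED[comp_code(code)], (unsigned)(k - 1));
    return s;
}

// Same window viewed from the opposite strand.
inline Walker rc_walker(const Walker& w) {
    Walker r;
    r.b.resize(w.b.size());
    for (size_t i = 0; i < w.b.size(); ++i)
        r.b[i] = code_base(comp_code(base_code(w.b[w.b.size() - 1 - i])));
    r.fh = w.rh;
    r.rh = w.fh;
    return r;
}

inline std::string revcomp_str(const std::string& s) {
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[s.size() - 1 - i]);
        r[i] = c < 0 ? 'N' : code_base(comp_code(c));
    }
    return r;
}

} // namespace bdbg

#endif
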