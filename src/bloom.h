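#ifndef BLOOMDBG_BLOOM_H
#define BLOOMDBG_BLOOM_H

#include <cstdint>
#include <memory>
#include <vector>
#include <stdexcept>

#include "kmer_hash.h"

namespace bdbg {

// Plain Bloom filter over 64-bit keys (canonical k-mer hashes).  Bit
// positions are value_i mod m with value_i from the multi-hash schedule;
// m is byte-granular so serialized filters are portable.
struct Bloom {
    uint64_t m;          // size in bits (multiple of 8, >= 8)
    int h;               // number of hash functions
    uint64_t seed;       // multi-hash seed
    uint64_t n_insert;   // distinct-key insert calls that set bits
    std::vector<uint64_t> w;

    Bloom(uint64_t m_bits, int h_, uint64_t seed_)
        : m(((m_bits + 7) / 8) * 8), h(h_), seed(seed_), n_insert(0) {
        if (m_bits < 8) m = 8;
        if (h < 1) throw std::invalid_argument("h must be >= 1");
        if (h > 64) throw std::invalid_argument("h must be <= 64");
        w.assign((size_t)((m + 63) / 64), 0ULL);
    }

    void positions(uint64_t key, uint64_t* pos) const {
        uint64_t v[64];
        multi_hash(key, h, seed, v);
        for (int i = 0; i < h; ++i) pos[i] = v[i] % m;
    }

    bool contains_pos(const uint64_t* pos) const {
        for (int i = 0; i < h; ++i)
            if (!((w[pos[i] >> 6] >> (pos[i] & 63u)) & 1ULL)) return false;
        return true;
    }

    void set_pos(const uint64_t* pos) {
        for (int i = 0; i < h; ++i)
            w[pos[i] >> 6] |= (1ULL << (pos[i] & 63u));
        ++n_insert;
    }

    void insert(uint64_t key) {
        uint64_t pos[64];
        positions(key, pos);
        set_pos(pos);
    }

    bool contains(uint64_t key) const {
        uint64_t pos[64];
        positions(key, pos);
        return contains_pos(pos);
    }

    uint64_t popcount() const {
        uint64_t n = 0;
        for (uint64_t x : w) n += (uint64_t)__builtin_popcountll(x);
        return n;
    }
};

// Chain of c equal-sized Bloom filters: a key is added to the first level
// where it is absent, so level i (1-based) holds keys seen >= i times
// (up to false positives).  The last level is the solid-k-mer set.
struct Cascade {
    uint64_t m;
    int h;
    uint64_t seed;
    int c;
    std::vector<std::unique_ptr<Bloom>> levels;

    Cascade(uint64_t m_bits, int h_, uint64_t seed_, int c_)
        : m(0), h(h_), seed(seed_), c(c_) {
        if (c < 1) throw std::invalid_argument("c must be >= 1");
        for (int i = 0; i < c; ++i)
            levels.emplace_back(new Bloom(m_bits, h_, seed_));
        m = levels[0]->m;
    }

    // All levels share hash values, so positions are computed once.
    void insert(uint64_t key) {
        uint64_t pos[64];
        levels.back()->positions(key, pos);
        for (auto& lv : levels) {
            if (!lv) throw std::runtime_error("cascade level has been dropped");
            if (!lv->contains_pos(pos)) {
                lv->set_pos(pos);
                return;
            }
        }
    }

    bool solid(uint64_t key) const { return levels.back()->contains(key); }

    Bloom* last() const { return levels.back().get(); }

    void drop_early() {
        for (int i = 0; i + 1 < c; ++i) levels[i].reset();
    }
};

} // namespace bdbg

#endif
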