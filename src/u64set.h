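#ifndef BLOOMDBG_U64SET_H
#define BLOOMDBG_U64SET_H

#include <cstdint>
#include <vector>

#include "kmer_hash.h"

namespace bdbg {

typedef unsigned __int128 u128;

// Open-addressing hash set of 128-bit keys (linear probing, power-of-two
// capacity).  Holds 2-bit-packed canonical k-mers (exact for k <= 64);
// for larger k the caller stores the canonical 64-bit hash instead.
struct U128Set {
    std::vector<u128> tab;
    uint64_t mask;
    size_t n = 0;
    bool has_zero = false;

    explicit U128Set(size_t log2_cap = 20)
        : tab((size_t)1 << log2_cap, 0), mask(((uint64_t)1 << log2_cap) - 1) {}

    static uint64_t mix(u128 x) {
        return mix64((uint64_t)x ^ mix64((uint64_t)(x >> 64)));
    }

    void grow() {
        std::vector<u128> old;
        old.swap(tab);
        tab.assign((size_t)(mask + 1) * 2, 0);
        mask = mask * 2 + 1;
        for (u128 x : old) {
            if (!x) continue;
            uint64_t i = mix(x) & mask;
            while (tab[i]) i = (i + 1) & mask;
            tab[i] = x;
        }
    }

    // true if newly inserted
    bool insert(u128 x) {
        if (!x) {
            if (has_zero) return false;
            has_zero = true;
            ++n;
            return true;
        }
        uint64_t i = mix(x) & mask;
        while (tab[i]) {
            if (tab[i] == x) return false;
            i = (i + 1) & mask;
        }
        tab[i] = x;
        ++n;
        if (10 * n > 7 * (mask + 1)) grow();
        return true;
    }

    size_t size() const { return n; }
};

} // namespace bdbg

#endif
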