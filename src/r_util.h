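#ifndef BLOOMDBG_R_UTIL_H
#define BLOOMDBG_R_UTIL_H

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <string>
#include <vector>

namespace bdbg {

inline std::string to_hex(uint64_t x) {
    char buf[17];
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
    return std::string(buf);
}

inline uint64_t from_hex(const std::string& s) {
    if (s.empty() || s.size() > 16)
        Rcpp::stop("key '%s' is not a 1-16 digit hex string", s.c_str());
    uint64_t x = 0;
    for (char c : s) {
        int d;
        if (c >= '0' && c <= '9') d = c - '0';
        else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
        else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
        else Rcpp::stop("key '%s' is not a hex string", s.c_str());
        x = (x << 4) | (uint64_t)d;
    }
    return x;
}

// Keys arrive from R either as hex strings or as non-negative doubles
// (exact below 2^53).
inline std::vector<uint64_t> parse_keys(SEXP keys) {
    std::vector<uint64_t> out;
    if (TYPEOF(keys) == STRSXP) {
        Rcpp::CharacterVector kv(keys);
        out.reserve(kv.size());
        for (R_xlen_t i = 0; i < kv.size(); ++i)
            out.push_back(from_hex(std::string(kv[i])));
    } else if (TYPEOF(keys) == REALSXP || TYPEOF(keys) == INTSXP) {
        Rcpp::NumericVector kv(keys);
        out.reserve(kv.size());
        for (R_xlen_t i = 0; i < kv.size(); ++i) {
            double d = kv[i];
            if (ISNA(d) || d < 0 || d > 9007199254740992.0)
                Rcpp::stop("numeric keys must be in [0, 2^53]");
            out.push_back((uint64_t)d);
        }
    } else {
        Rcpp::stop("keys must be hex strings or non-negative numbers");
    }
    return out;
}

} // namespace bdbg

#endif
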