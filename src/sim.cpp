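#include <Rcpp.h>
#include "kmer_hash.h"

using namespace Rcpp;
using namespace bdbg;

// I.i.d. substitution errors: each base is replaced, with probability
// `rate`, by one of the three other bases chosen uniformly.  Draws come
// from R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_add_substitutions(CharacterVector reads, double rate) {
    RNGScope scope;
    CharacterVector out(reads.size());
    double n_sub = 0, n_bases = 0;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        n_bases += (double)s.size();
        for (size_t i = 0; i < s.size(); ++i) {
            if (unif_rand() >= rate) continue;
            int c = base_code(s[i]);
            if (c < 0) continue;
            int shift = 1 + (int)(unif_rand() * 3.0);
            if (shift > 3) shift = 3;
            s[i] = code_base((c + shift) & 3);
            n_sub += 1;
        }
        out[r] = s;
    }
    return List::create(_["reads"] = out, _["n_substitutions"] = n_sub,
                        _["n_bases"] = n_bases);
}
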