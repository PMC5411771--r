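Package: bloomdbg
Title: Bloom Filter de Bruijn Graph Unitig Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Memory-efficient unitig assembly of short sequencing reads
    using a probabilistic de Bruijn graph. K-mers are stored in a
    cascading Bloom filter that retains only k-mers seen at least a
    user-chosen number of times ("solid" k-mers), graph edges are
    discovered at traversal time by querying single-base extensions, and
    unitigs are built by extending solid reads left and right with a
    depth-bounded look-ahead that prunes short false branches arising
    from Bloom filter false positives and recurrent sequencing errors.
    Includes rolling canonical multi-hashing of DNA k-mers, analytic
    false-positive-rate sizing of filters, a synthetic read simulator,
    an exact (non-probabilistic) assembly oracle for verification, and
    N50/NG50 contiguity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
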