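---
title: "Unitig assembly with a Bloom filter de Bruijn graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unitig assembly with a Bloom filter de Bruijn graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `bloomdbg`, the parameters
that matter, the design decisions taken where the design was genuinely
open, and what the synthetic test bed does and does not demonstrate.

## The probabilistic de Bruijn graph

The nodes of a de Bruijn graph are the k-mers of the input reads; two
k-mers are joined when they overlap by k − 1 bases.  `bloomdbg` never
materialises nodes or edges.  The canonical k-mer set is held in Bloom
filters, and the out-edges of a node are discovered by querying its
four single-base extensions.  Every structural query is therefore
subject to the filter's false-positive rate (FPR),

$$\mathrm{FPR} = \left(1 - (1 - 1/m)^{hn}\right)^h \approx
\left(1 - e^{-hn/m}\right)^h,$$

for a filter of $m$ bits, $h$ hash functions and $n$ distinct inserted
keys (`fpr_analytic()`, exact and exponential forms).  `size_for_fpr()`
inverts the exact form by bisection on whole bytes: the smallest
byte-granular $m$ whose FPR does not exceed the target.

A false positive adds a phantom node.  Phantom nodes are overwhelmingly
isolated or form short dead-end branches, which the look-ahead removes
(below); a phantom *path* that reconnects two true k-mers overlapping by
only $o < k-1$ bases requires $k-1-o$ consecutive false positives and so
occurs with probability $\mathrm{FPR}^{\,k-1-o}$
(`chance_connection_probability()`) — negligible at the operating FPRs.

## Occurrence thresholding: the cascading filter

Sequencing errors produce k-mers of occurrence count 1–2; true genomic
k-mers at usable coverage occur tens of times.  The cascading Bloom
filter exploits this: `c` equal-sized filters are chained, and each
k-mer occurrence is inserted into the first level where it is absent.
Level `i` then holds k-mers with count ≥ i (inflated only by
false-positive promotions at the earlier levels), and the last level is
kept as the solid-k-mer set.  After loading, the earlier levels are
freed (`cbf_drop_early()`); with the tracking filter (same size as one
level) the peak allocation is $(c+1)\,m$ bits (`total_memory()`).

`min_count` (= `c`) defaults to 2 and is typically 2–4: at 30–75×
coverage, `c = 3` removes nearly all error k-mers while losing almost
no genomic ones.

One subtlety matters for experiments that control the FPR: all levels
share one size $m$, but their loads differ enormously (level 1 receives
every distinct k-mer, most of them error singletons; the last level
only the solid set plus promotions).  The *operative* FPR — the one the
traversal experiences — is that of the last level, computed from its
exact insert count; the assembly report exposes it as `fpr` alongside
`fpr_level1`.  The mapping from $m$ to this operative FPR depends on
promotion feedback between levels, so `fpr_sweep()` measures an
$m\to\mathrm{FPR}$ curve with cheap load-only passes and inverts it,
rather than assuming the single-filter formula.

## Hashing

K-mers are hashed with a rolling cyclic-polynomial scheme: the forward
hash of a window is the XOR of one fixed 64-bit constant per
nucleotide, rotated by the base's distance from the window end; a
one-base shift updates it with two rotations and two XORs.  The
reverse-complement hash is maintained symmetrically, and the canonical
value is `min(fwd, rc)` — chosen over XOR-style mixing because it is
symmetric, order-free, and preserves the O(1) rolling property on both
strands.  The four per-base constants are committed in the source and
frozen by golden-value tests, so filters are bit-identical across
platforms.  `h` bit positions per probe come from an arithmetic
schedule `value_i = base + i · g(base, seed)` with `g` a splitmix-style
mixer forced odd (`multi_hash()`), so one canonical hash yields all
probe positions without rehashing.  Input is uppercased before hashing
(FASTA case conveys masking, not identity); IUPAC ambiguity codes are
not hashed — reads are split at any non-ACGT character.

`h` defaults to 4.  The number of hash functions used in comparable
assemblers is rarely reported; 4 is a common Bloom filter compromise
(at the 5% FPR operating point the optimal $h$ is ≈ 4.3), and `h` is
exposed everywhere should a user wish to trade probe cost against the
FPR curve.

## Look-ahead branch classification

At a branching point during extension, each candidate extension is
classified by a depth-bounded search: *an extension survives iff some
walk of more than `lookahead` nodes exists below it* (the candidate
counts as the first node; walks may revisit nodes, so cycles survive).
A branch that dies out within the bound is a false branch — a Bloom
filter phantom or a recurrent-error tip — and is ignored.  If two or
more extensions survive, the branch is real and extension halts; the
bound defaults to `k` nodes, matching the longest branch a single
sequencing error can induce.

The search is implemented exactly: a depth-first walk over the filter
with a memo of failed budgets per node, having first tried a cheap
memo-less pass with a node budget.  We deliberately rejected a greedy
walk with limited nested-branch handling: a greedy rule both prunes
extensions that do lie on long paths (when the greedy path happens to
die) and spuriously "survives" nested false forks, and either error is
visible at moderate FPR — the first as lost joins, the second as halted
unitigs every few hundred nodes.  The exact bounded search satisfies a
clean contract (verified against a breadth-first oracle in the tests):
no extension on a path longer than the bound is ever pruned, and no
extension without such a path ever survives.  Its cost is bounded by
(reachable nodes) × depth and in the subcritical regime (FPR < 1/4 with
four candidate bases) the expected search tree is a handful of nodes.

Within one pass the outcome per oriented k-mer is cached, so the
per-position cost is paid once rather than once per overlapping read.

## Unitig semantics

Extension steps across an edge $x \to y$ only when $y$ is the unique
surviving successor of $x$ *and* $x$ is the unique surviving
predecessor of $y$ (queried on the reverse strand).  The second
condition — halting at incoming branches — is standard unitig practice
and is what makes the output independent of seed order: without it, a
seed inside a tip could walk backwards through a convergence point and
claim sequence that another seed would also claim.  Solid reads are
split at exactly the positions where this edge condition fails, so
seeds never straddle a boundary.  The same rule governs the exact
reference assembler, which makes assembler-vs-oracle equality a
meaningful whole-pipeline test.

Reads are processed in input order; the tracking filter makes output
deterministic given the input, parameters and seed.  A seed whose
k-mers are all already tracked is skipped.  Tracking false positives
can in principle suppress a genuine unitig (probability ≈ FPR per
single-novel-k-mer seed); this is accepted, as the tracking filter is
sized with the cascade levels and the event is vanishingly rare at the
operating sizes.  A per-unitig visited set guards against cycles:
a circular component is emitted once, linearised at the seed.

Other conventions: `min_unitig_len` defaults to `k` (shorter outputs
are bare seed fragments); unitigs are reported in the orientation of
their seed, and comparisons canonicalise byte-wise
(`canonical_sequence()`); odd `k` is recommended so no k-mer equals its
own reverse complement.

## The synthetic test bed

`sim_config()` emulates the shape of a short-read whole-genome
experiment: uniform random genome, single-end 100 bp reads at 75×
coverage, strands coin-flipped, i.i.d. substitution errors at 0.5% per
base.  Defaults follow the experimental regime this assembler targets;
single-end suffices because the unitig stage uses no pairing
information.  The generator does **not** model quality scores, indels,
coverage bias, GC bias or real repeat structure (an optional
`repeat_spec` plants exact repeat copies to create true branches).
Passing tests therefore demonstrate correctness of the data structures
and traversal semantics under the stated error model — not assembly
quality on real libraries, where error correction and paired-end
stages do additional work.

`exact_unitigs()` is the verification oracle: the same algorithm
(solid reads, splitting, look-ahead with a breadth-first survival
search, exact visited-set deduplication) over exact hash-table counts
and string sets, sharing no code with the rolling-hash/Bloom machinery.
With the probabilistic assembler's filters sized for a negligible FPR
(10⁻⁶ in the tests), the two must produce identical canonical unitig
sets; the test suite checks this on 20 seeded instances spanning
genomes of 5–50 kb, 30–75× coverage, 0–1% errors and `c` ∈ {2, 3}.
Note the oracle deliberately reproduces the *algorithm's* semantics,
including look-ahead tip suppression — with errors and `c = 2`,
recurrently erroneous k-mers are solid, and plain maximal
non-branching paths would differ from the assembler by construction.

## The committed FPR benchmark

The contiguity-vs-FPR experiment uses a fixed 1 Mb genome, 75×, 100 bp,
0.5% errors, `c = 3`, `k = 61` (seeded; ~8.8 M distinct 61-mers).
`k = 61` is deliberate: with 100 bp reads an error-induced tip contains
at most `L − k + 1 = 40` nodes, comfortably inside the look-ahead bound
of 61, so tip classification has margin and contiguity is insensitive
to moderate FPR.  (With `k` below about half the read length the
longest error tips reach exactly `k` nodes — the pruning boundary — and
single false-positive extensions convert them into halting branches,
eroding NG50 gradually with FPR.  That regime works, but is the wrong
place to measure a stability plateau.)  On this benchmark NG50 stays
within a fraction of a percent of the genome length from near-zero FPR
through ~10%, while traversal probe counts grow with FPR; above the
percolation point of phantom branching (one expected phantom successor
per phantom node, FPR = 1/4) look-ahead can no longer separate false
from true branches and NG50 collapses — the sweep's high-FPR point
(~28% realized) shows this.  Problem sizes throughout the test suite
(5 kb unit fixtures, 5–50 kb oracle instances, the 1 Mb sweep) were
chosen as the smallest at which each effect is cleanly measurable.

## Known limitations

* The unitig stage only: no paired-end contigs, scaffolding, gap
  filling, or read correction.
* Distinct-k-mer counts for filter sizing are exact (2-bit packed set)
  for k ≤ 64; beyond that a 64-bit canonical-hash set stands in, which
  is exact up to astronomically unlikely hash collisions.
* Counts in the cascade saturate at `c`; there is no k-mer rescue for
  low-coverage regions — reads containing any sub-threshold k-mer are
  simply skipped as seeds.
* The serialized filter format stores a single Bloom filter
  (`save_bloom()` / `load_bloom()`); resumable two-pass assembly is not
  wired into the command-line driver.
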