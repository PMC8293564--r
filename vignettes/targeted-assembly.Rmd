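---
title: "Target-guided de Bruijn graph assembly: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-guided de Bruijn graph assembly: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model behind `targetasm`, the parameters that
matter, the synthetic-data generator used throughout the test suite, and
the design decisions taken where several reasonable implementations exist.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The assembly model

`targetasm` performs de-novo assembly restricted to the neighbourhoods of
user-supplied *target* sequences. The assembly substrate is a de Bruijn
graph over canonical k-mers of the reads, not an alignment of reads to the
target: the target only steers which subgraphs are explored and how far
paths are trusted. Consequences of this choice:

* the assembled sequence is composed entirely of read k-mers — the target
  never contributes a base;
* divergence between sample and target is tolerated up to the alignment
  drop-off, so an 85%-identity homolog can recover a gene at 100% identity
  to the sample (this is exercised end to end in the test suite);
* k-mers carry less information than reads, so a separate read/pair
  filtering stage removes graph connections no read supports.

Two graphs are kept. The **primary** graph (k ≈ half the read length)
drives extension; its long k-mers keep repeats apart. The **secondary**
graph (k ≈ a fifth of the read length, at least 21) is consulted only
where the primary graph runs out: at dead ends, or — when the minimum
count is lowered to 1 for low-coverage data — at single extensions whose
new k-mer count is at most `secondary_kmer_threshold`. With the default
minimum count of 2 and threshold 1, the second trigger can never fire;
this is a property of the defaults, not an accident of the code.

### Seeding

A k-mer seeds assembly at a target position when an exact suffix word
(8 bp; 12 bp = 4 aa translated in protein mode) anchors it, its overall
similarity clears the Hamming-match threshold `min(k − 1, V)` with
`V = floor(k/10) + k·penalty/(reward + penalty)` (protein mode: gap-free
BLOSUM62 score above 0.75 of the target fragment's self-score), the
position is unique, the k-mer can extend about 100 bp in both directions
in the graph, and its read count is both greater than 1 and at least a
`fraction` (0.05) of the strongest seed at that position. Reverse-strand
placements match the *first* word bases of the reverse complement, because
the word hash is built over k-mer suffixes.

Positions collecting at least `kmer_complexity` (2000) distinct seeds are
treated as hyper-repetitive: their seeds are deleted and the k-long target
window is hard-masked (N for nucleotide targets, X for proteins), which
deliberately fragments assembly across low-complexity intervals instead of
letting path counts explode.

One rule here goes beyond the seed conditions as usually stated: the
strand-balance test applied to extension choices is also applied per
target position to seed candidates (a candidate seen predominantly on one
strand is dropped whenever a strand-balanced candidate seeds the same
position). Without it, a strand-specific sequencing error with read count
2 can pass every other seed condition, build its own short error chain,
and re-enter the main path through the secondary-graph rescue — producing
an error bubble that read/pair filtering cannot remove because the error
reads themselves confirm it. Filtering strand-specific artefacts is the
stated purpose of the strand heuristic, so applying it at both entry
points is the coherent reading.

### Extension and alignment

Extension proceeds one base at a time, depth first over a stack of
branches. Candidates below `extension_fraction` (0.1) of the strongest
candidate are noise; if any surviving candidate is strand-balanced, the
predominantly-one-strand candidates are dropped. We quantify "balanced"
as: minor-strand count at least 10% of the total and nonzero. The 10%
cutoff is our choice (the underlying idea fixes no number); it is
deliberately permissive so that genuine alleles at 30× coverage (minor
strand ≥ 2 of ~15) are essentially never dropped, while one-strand-only
artefacts always are. A base is accepted only if the resulting k-mer can
itself be extended under the same rules (the double-step rule), which
stops paths one step before obvious dead ends.

The path-to-target alignment is an incremental banded affine-gap dynamic
program (Gotoh recurrence; gap of length L costs `gap_open +
L·gap_extend`), anchored at the seed and advanced one base (one codon in
protein mode, translated on the fly under the user's NCBI genetic code)
per accepted extension. The running score is the best alignment of the
full path prefix against any target prefix; when it exceeds the best seen,
best score and position update; when it falls more than `drop_off` below
the best, the path — and any stored branch points beyond the best
position — are clipped back to the best-scoring position, and the clip
point is marked as a fork for the filtering stage. Score defaults (match
+1, mismatch −2, gap 5/2 nucleotide; BLOSUM62 half-bits with gap 11/1
protein; drop-off 25 nt / 50 protein; frameshift opening 30 when
frameshifts are enabled) mirror common BLAST-family settings and are all
overridable; the alignment arithmetic is integer-exact in both modes.
Correctness of the incremental frontier is established in the tests by
comparison against an independent full-matrix oracle on hundreds of
random instances, including the clipping property that no clipped suffix
could have beaten the recorded best.

Left extensions reuse the right-extension machinery on the reverse
complement, with the target prefix reverse-complemented (protein mode:
residues reversed and codons reverse-complemented before translation, so
codon boundaries are preserved).

Two guards bound work in repetitive regions: an *anchor* optimisation
merges convergent branches — when a path reaches a k-mer another branch
reached with the same best-scoring target coordinate, and fewer than k/4
bases have accrued past the best position, the path stops and reuses the
earlier continuation — and a *fork-density* abort stops the current seed
when the trailing 200 bp (`buf_length`) contain strictly more than
`max_fork_density` (0.1) forks per base. Paths shorter than the buffer
use their actual length as denominator. A per-seed branch budget (10 000)
is a final backstop.

All emitted paths for a target are merged by k-mer adjacency and
compressed into unitigs; the assembled graph is therefore a subgraph of
the union of the two de Bruijn graphs, kept in target orientation.

### Filtering by reads and pairs

Filtering examines every segment C with at least two predecessors and two
successors, i.e. the four-way context A,B → C → D,E. For each combination
A‑C‑D, reads containing C are extended outward without mismatches;
`Y = not_aligned_len/2` exact bases beyond both junctions confirm, while
an extension that stops exactly at one junction with at least 2Y read
bases still available contradicts. Pairs do the same with one mate per
junction, anchored by exact 12-mer seed-and-extend placement, requiring
innie orientation and a pair span inside the estimated insert range. A
combination is removed when contradictions reach `not_aligned_count` (3)
and confirmations stay strictly below `aligned_count` (2); removal
regroups the left choices by their surviving right sets, duplicating C per
group. If a filtering pass inflates the segment count beyond 15× the
input, the pass is rolled back and the input graph returned; note that a
single context can add at most (number of left choices − 1) segments, so
this safeguard is reachable only on graphs far denser than the fixtures
used here — the code path exists, the condition is tested indirectly
through the bound.

Reads are checked before pairs (the two passes commute on all fixtures we
construct; an order had to be fixed). The insert range itself is estimated
beforehand by joining mates through strictly unambiguous graph walks and
taking the 1st–99th percentile of joined lengths (cap 1000 bp; below 100
joins a conservative fallback range is used with a warning). The
percentile choice is ours: it is robust to rare chimeric joins while
keeping the range tight on clean data, and the tests verify that a
simulated insert distribution is recovered within read-length slack.

### Multiple targets and output

Unless `keep_subgraphs` is set, an assembled graph whose complete
secondary-k canonical k-mer set is contained in another graph's set is
redundant and dropped (checked before and after filtering). The secondary
k is smaller than the segment overlap, so the k-mer set of a graph equals
the union over its segments — no junction bookkeeping is needed. The
intended consequence: given targets for two genes and their fusion, on
fusion-bearing reads only the fusion graph survives.

Variants are source-to-sink paths of the graph, each link used at most
once per path (our cycle policy; it bounds enumeration on repeat-induced
cycles and is the only place the graph is "DAG-ified"). Variants shorter
than `target_coverage` (0.5) of the target length — measured before any
end extension, whose added lengths are recorded per segment end — are
suppressed, unless the user instead sets an absolute `min_hit_len`.
Support is the sum of secondary-k read counts over all k-mers of the
variant; ties break lexicographically for determinism. When more than
`max_variants` (1000) variants exist, counting stops at the cap and the
top `max_variants` by support are reported. `select_variants()` reports
the best-supported enumerated path through each link, duplicates
collapsed, for graphs whose full enumeration is impractical.
`collapse_snp_bubbles()` merges equal-length substitution-only bubble arms
into IUPAC ambiguity codes (indel bubbles untouched), which shrinks
lattice-like low-complexity graphs dramatically (a 10-site toy collapses
from 1024 enumerable paths to 1; computed in the tests).

Graphs are written as GFA 1.0 (S/L lines, `(k−1)M` overlap CIGARs, plus
orientations in target frame) and variants as 80-column FASTA.

## The synthetic-data generator

`sim_config()`/`simulate_genome()`/`simulate_reads()` emulate the aspects
of Illumina data this method is sensitive to: fixed-length paired reads
(quality constant 'I'), Normal insert sizes truncated at the read length,
substitution errors, haplotypes differing at chosen SNPs, carryover-style
contamination as fragments of an unrelated sequence, and — for the strand
filter — a planted substitution placed only on forward-oriented reads
covering a chosen locus, which is exactly the signature of a
strand-specific systematic error (all occurrences of the error k-mer on
one strand). It does not model quality-score decay, GC bias, PCR
duplicates, or indel errors; a pass on these fixtures therefore
demonstrates the graph logic, the alignment and the filters, not
robustness to base-quality artefacts (the pipeline never reads qualities)
or to indel sequencing errors.

Default study conditions used in the tests and the acceptance script:
2–2.4 kb loci at 30× coverage, 150 bp pairs with insert 300 (±7–10 bp sd),
error-free unless the scenario is about errors, homolog targets at 85%
identity (60% for the degradation check), three linked SNPs within one
insert for haplotype separation, a 10% plus-strand-only error allele for
the strand filter, and single-copy 50 bp reads across a gap in 150 bp
coverage for the secondary-graph rescue. These sizes keep each scenario
in the seconds-to-a-minute range on one CPU while leaving every quantity
(coverage windows, insert estimation, fork statistics) well away from
degenerate small-number regimes.

## Degenerate inputs and numerical corner cases

* Reads containing N are split at N runs; a fragment keeps its pairing
  metadata only if it is the entire mate.
* Palindromic k-mers (possible only for even k, which production settings
  never use) count to the plus strand by convention.
* Automatic k-mer selection refuses read lengths below 42 (primary k
  would drop under 21) and asks for explicit sizes.
* An empty seed list, an empty graph, and a target absent from the reads
  are all valid, empty results — not errors.
* Protein paths hitting a stop codon score the minimum of the BLOSUM62
  `*` column and are left to the drop-off to terminate; the reporting
  layer does not force-truncate.
* Masked target positions score as mismatches (N/X), so extension across
  a masked window survives only within the drop-off budget.

## Known limitations

* Each target is assembled in its own orientation frame; a read set whose
  homolog spans both strands of one target (e.g. an inverted duplication)
  yields two unconnected segment sets rather than a mixed-orientation
  graph.
* Read/pair filtering checks the four-way contexts of the fork figure;
  choices expressed only as simple bubble arms are policed at seed and
  extension time (strand balance, noise fraction) rather than by the
  filter, and context expansion for mate placement follows unambiguous
  links only.
* Exact-match placement (12-mer anchors) requires reads to agree with the
  graph over at least 12 consecutive bases on each placed region; at
  desk-scale error rates this is immaterial, at several percent error it
  would undercount support.
* Execution is single-threaded by design; `--cores` is accepted for
  interface parity only, keeping runs bit-reproducible.
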