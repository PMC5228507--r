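---
title: "Reference-guided CRISPR spacer detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided CRISPR spacer detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprscout)
```

## The detection model

CRISPR arrays alternate near-identical direct repeats (DRs, empirically
23–47 bp) with spacers (26–50 bp) acquired from mobile genetic elements.
Because arrays resist assembly, `crisprscout` searches *raw reads* for
approximate occurrences of user-supplied DR query sequences and extracts
the fragments between admissibly spaced occurrences as spacers.

The matching model is the unit-cost Levenshtein distance — insertions,
deletions and substitutions each cost one edit — with one deliberate
tightening: `N` never matches any base, itself included. A read position
called as `N` can therefore consume an edit but can never help a candidate
repeat reach the budget, so low-quality base calls cannot fabricate arrays.

`find_occurrences()` implements semi-global search: for every query and
every read position at which *some* substring lies within `d_max` edits of
the query, a candidate is generated (the dynamic program carries, per end
position, the minimum edit count and the largest start attaining it, with a
standard last-active-row cutoff for speed). Overlapping candidate end
positions of one query/strand are then collapsed to the single best
candidate — minimum edits, then shortest span, then leftmost start — which
prevents a degenerate repeat from spawning shadow matches one base apart.
The contract is defined by output, not by algorithm: the test suite holds
the implementation to a naive scan over all substrings (distances from an
independent C implementation) on hundreds of random cases.

**Strand handling.** CRISPR arrays occur on either strand, so queries are
searched in both orientations by default (`both_strands = TRUE`); matches
to the reverse complement are reported with strand `-`, and minus-strand
spacers are reverse-complemented on extraction so all emitted spacers
follow the query's orientation. A flag disables this for strict
replication of single-strand protocols, since published descriptions of
reference-guided CRISPR searches do not always state their strand
behaviour.

**Overlap chaining.** Where matches overlap within a read,
`chain_nonoverlapping()` keeps a non-overlapping subset chosen best-first
under the quality ordering (fewer edits, longer span, leftmost start,
query id, strand). Best-first greedy is used rather than a positional
left-to-right sweep because it is provably the optimum over all
non-overlapping subsets when chains are compared by their quality-sorted
elements — which makes the exhaustive-enumeration oracle in the tests
well-defined and the behaviour deterministic.

**Spacer calling.** Only *adjacent* chained occurrences of the *same*
query on the *same* strand form a spacer, and only when their gap lies in
`[min_spacer, max_spacer]` = [26, 60] bp by default (60 bp is the
protocol's maximum allowed distance between detected repeats). A repeat
triplet therefore yields two spacers, matching array structure. Mixed
flanks from two different queries are rejected: a query set typically
pools repeats from many taxa, and a chimeric repeat pair has no biological
reading. Deduplication at this stage is exact string identity only, with
provenance of every duplicate retained; similarity-based reduction is
deferred to the clustering step, mirroring the hash-then-cluster order of
the original protocol.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `d_max` | 3 | edits | protocol varied 0–3; 3 is its most sensitive setting |
| `min_spacer` | 26 | bp | lower end of the empirical spacer range |
| `max_spacer` | 60 | bp | protocol's maximum repeat-to-repeat distance |
| `both_strands` | TRUE | — | arrays occur on either strand |
| cluster `threshold` | 0.9 | identity | protocol's clustering similarity |
| `evalue_cutoff` | 1e-03 | — | protocol's BLAST retention threshold |
| `match_reward`/`mismatch_penalty` | +1/−2 | — | common short-nucleotide scoring |
| `seed_length` | 11 | bp | default nucleotide seed; adequate for 26–60 bp spacers |
| k-mer `k` | 2 and 3 | — | dimer and trimer usage panels |

## Clustering semantics

The protocol names only a greedy clustering tool and a 0.9 threshold.
`greedy_cluster()` reproduces the semantics precisely and declares the
unstated parts: sequences are sorted by decreasing length (ties by id);
each sequence joins the *first* cluster whose representative it matches at
identity ≥ 0.9, else founds a new cluster. Identity is the maximal number
of identical aligned positions over all global alignments (equivalently,
the longest-common-subsequence length; computed by dynamic programming)
divided by the shorter sequence's length — the short-denominator
convention of greedy clustering tools, stated here explicitly because the
source protocol invokes the tool only by name. Comparison is
strand-insensitive by default, the usual choice for unoriented metagenomic
spacers. Word-filter speed heuristics are not reproduced; on spacer-sized
inputs the quadratic scan is instant, and the guarantee is about
semantics, not speed. The tests re-verify every member–representative
identity with an independent maximal-identity alignment from Biostrings.

## Spacer-to-virus mapping and E-values

The built-in aligner is an ungapped seed-and-extend search: every exact
11-mer shared between a spacer and a library genome nominates a diagonal,
and per (spacer, subject, strand, diagonal) the maximal-scoring ungapped
segment under +1/−2 is kept (Kadane's rule, leftmost maximal segment on
ties). For 26–60 bp protospacers, which rarely tolerate gaps, ungapped
alignment is adequate; bit-for-bit parity with NCBI BLAST is a declared
non-goal, and `read_tabular_hits()` ingests genuine 12-column BLAST output
for strict replication studies. E-values follow Karlin–Altschul,
E = K·m·n·e^(−λS), with λ solved at run time from Karlin's equation for
the scoring pair (λ ≈ 1.33 for +1/−2 under uniform base frequencies) and
K = 0.621, the standard ungapped value for this pair. The search space
`n` is the *summed* library length — a database-style convention that the
documentation states explicitly because retained-hit counts depend on it.
Network edges carry the host-taxon annotation of the DR that detected the
spacer — never anything inferred from the virus side — and unannotated
queries propagate as `"unknown"`.

## K-mer usage distances

`kmer_frequencies()` counts all overlapping k-mers on the forward strand
(the conventional strand-naive counting of nucleotide composition tools),
skips windows containing `N` so the result stays a proper distribution,
and normalizes by counted windows. The virus–host dissimilarity is the
sum of squared frequency differences over all 4^k words, reported per
host group and per metagenome as mean ± 2·SE (SE = sd/√n, defined as 0
for singleton groups). Host genomes with several replicons are *not*
auto-concatenated — the operation compares exactly the sequences given,
matching protocols that use a single chromosome per host. Frequencies are
normalized rather than raw counts: the source describes "frequencies",
and normalization is the only reading that makes genomes of different
lengths comparable.

## What the synthetic generator emulates — and what it does not

`simulate_metagenome()` draws read lengths from a truncated normal (mean
480 bp, sd 40, minimum 100 bp), matching the 429–523 bp per-site averages
of the pyrosequencing metagenomes the defaults are anchored to, with a
29-query repeat set mirroring the original query panel's size. Each
planted array is DR′–spacer–DR′(–spacer–DR′), where each repeat copy
independently draws an edit count *e* uniform on {0, …, 3} and receives
*exactly e* edits — exact rather than "up to", so that detectability at
every budget is knowable a priori and recall denominators are crisp.
Edits are placed at interior positions (≥ 4 bp from either repeat end) so
the planted boundary remains the minimal-edit boundary. After
construction, each planted read is re-verified with the detector's own
geometry at the maximum budget: if the mutated repeats admit an equally
parsimonious alternative boundary, or a random flank or excised spacer
happens to contain a chance repeat occurrence, the read is re-drawn. This
keeps the truth manifest *exact* — `detectable = TRUE` implies the
detection preconditions hold verbatim — at the cost of excluding
genuinely ambiguous corner cases from the planted population. Background
reads are rejection-sampled to contain no query within 3 edits on either
strand, giving precision a clean denominator.

Features of real data deliberately **not** emulated: pyrosequencing
homopolymer errors (edits are injected only into repeat copies, keeping
truth exact), community abundance structure, paired-end layouts, and
host-genome-derived background. Passing the planted-recovery tests
therefore demonstrates the correctness of the detection machinery under
the stated geometry, not robustness to sequencing artefacts — on real
reads, sequencing errors inside repeats consume edit budget and reduce
sensitivity, which is exactly why the protocol exposes `d_max`.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere; file readers and writers
  convert at the boundary (12-column alignment tables are 1-based
  inclusive, with `sstart > send` encoding the minus strand).
* Ties in candidate collapse, chaining, clustering and segment extension
  are broken deterministically (documented above); two runs on identical
  input produce byte-identical output files, and a fixed generator seed
  produces byte-identical simulations.
* Reads shorter than any query minus the budget simply yield no matches;
  spacers shorter than the seed length yield no alignments (with a
  warning); an empty network still writes valid, headers-only files.
* Identity thresholds are compared with a 1e-12 tolerance in re-checks;
  the E-value solver uses `uniroot` to 1e-12 on a bracket the Karlin
  equation is guaranteed to sign-change over.

## Problem sizes used in the checks

The shipped verification runs use a 1,000-read metagenome (50 planted
arrays, 950 repeat-free background reads), 29 synthetic queries and a
100-virus library of 5–50 kb genomes — small enough to run in about a
minute on one core while exercising every stage, and large enough that
each run plants tens of spacers across the full 0–3 edit range. The
oracle-equivalence property is checked on 500 random read/query/budget
triples with reads up to 300 bp. No empirical claim is made beyond what
those runs compute.

## Known limitations

* The aligner is ungapped; a protospacer split by a genuine indel will be
  reported as the better-scoring ungapped piece (or missed if neither
  piece clears the E-value cutoff).
* Greedy first-fit clustering is order-dependent by construction (as in
  the tool it reproduces); a sequence within 0.9 of two representatives
  joins the earlier-founded cluster.
* Host-taxon labels are only as good as the DR annotations supplied; the
  package never infers taxonomy.
* De novo (repeat-agnostic) CRISPR discovery, array reconstruction across
  reads and spacer-order inference are out of scope.
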