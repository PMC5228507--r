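# crisprscout

Reference-guided CRISPR spacer detection and virus–host mapping from
unassembled metagenomic reads.

## The problem

CRISPR arrays record a prokaryote's viral encounters: short **direct
repeats** (DRs, 23–47 bp) alternate with **spacers** (26–50 bp) excised from
invading viruses. A spacer that aligns to a viral genome therefore links
that virus to the host carrying the array. In shotgun metagenomes the
repetitive structure of arrays defeats assembly, so spacers must be found in
raw reads. `crisprscout` does this the reference-guided way: given a set of
known DR sequences (each optionally annotated with the taxon whose genomes
it came from), it

1. **recruits** every read containing an approximate DR occurrence within a
   Levenshtein edit budget *d* ∈ {0, …, 3} (insertions, deletions and
   substitutions; `N` never matches anything),
2. **calls spacers** from consecutive same-DR, same-strand occurrences whose
   gap *g* satisfies 26 ≤ *g* ≤ 60 bp, and collapses exact duplicates into
   a non-redundant set with full per-read provenance,
3. **clusters** spacers greedily at ≥ 90 % identity (identity = maximal
   identical aligned positions / length of the shorter sequence, longest
   sequence founds each cluster — the semantics of greedy incremental
   clustering tools),
4. **maps** spacers to a viral genome library with an ungapped
   seed-and-extend aligner (+1/−2, seed 11) under Karlin–Altschul E-value
   statistics, E = *K·m·n·*e^(−λS), keeping hits with E ≤ 10⁻³, and emits
   the bipartite spacer–virus network (SIF + attribute tables); each edge
   carries the host-taxon label of the DR that detected the spacer,
5. **compares** virus and host oligonucleotide usage: overlapping di-/
   trinucleotide frequencies, distance D = Σ_w (p_w − q_w)², summarized per
   group as mean ± 2·SE.

A fully reproducible **synthetic metagenome generator** plants
repeat–spacer–repeat arrays (each repeat copy mutated by an exact, recorded
number of edits; spacers excised from simulated viral genomes at recorded
coordinates) in pyrosequencing-style reads (~480 bp) over a repeat-free
background, and writes a truth manifest so recall and precision are exactly
measurable offline.

## Worked example

```r
library(crisprscout)

params <- sim_params(seed = 1, n_queries = 29, n_viruses = 100,
                     virus_length = c(5000, 50000),
                     n_array_reads = 50, n_background_reads = 950)
sim <- simulate_metagenome(params)

spacers <- detect_spacers(sim$reads, sim$queries, detection_params(d_max = 3))
glance(spacers)
#> # A tibble: 1 x 5
#>   n_reads n_recruited n_detections n_spacers d_max
#>     <int>       <int>        <int>     <int> <int>
#> 1    1000          50           78        78     3

score_detection(sim$truth, spacers, d_max = 3)
#> # A tibble: 1 x 6
#>   n_detectable n_detected_plantings recall n_detected n_traced precision
#>          <int>                <int>  <dbl>      <int>    <int>     <dbl>
#> 1           78                   78      1         78       78         1

clusters <- greedy_cluster(spacers)          # 0.9 identity threshold
hits     <- align_spacers(spacers, sim$viruses)
network  <- build_network(hits, spacers)
glance(network)
#> # A tibble: 1 x 4
#>   n_edges n_spacers n_viruses n_host_taxa
#>     <int>     <int>     <int>       <int>
#> 1      78        78        52           6
```

All 50 planted arrays are recruited, all 78 planted spacers are recovered
exactly (recall 1), nothing else is called (precision 1), and every spacer
maps back to its source virus. Lowering `d_max` shrinks the detected set
monotonically (8, 19, 47, 78 spacers at d = 0…3 for the run above) because
repeat copies carrying more edits than the budget stop matching —
the detection-sensitivity trend the method is designed around.

A file-level interface mirrors the in-memory one (`run_simulate()`,
`run_detect()`, `run_cluster()`, `run_map()`, `run_kmerdist()`), and
`inst/cli/crisprscout.R` exposes the same five steps as shell subcommands.

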