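# gsgtools

Transcriptomic structural variants (TSVs) — novel transcript adjacencies
caused by genomic rearrangement, such as fusion genes — leave a signature
in RNA-seq data: read pairs whose alignments contradict the reference
genome. In heterogeneous samples (tumours above all), several alleles
coexist, and adjacencies from different alleles can be mutually
contradictory; a single-allele model discards them as errors. `gsgtools`
is an R package for calling TSVs from **genome segment graphs** (GSGs)
under an explicit k-allele model, aimed at methodologists and pipeline
builders working downstream of RNA-seq alignment.

A GSG `G = (V, E, w)` has a head and a tail vertex for each genomic
segment and weighted edges between endpoints of different segments, the
weight being read support. An *arrangement* `(π, f)` — a permutation of
segments plus per-segment orientation — models one allele; an edge from
`u` on end `a` to `v` on end `b` with `π(u) < π(v)` is *concordant* when
`f(u) = 1[a = t]` and `f(v) = 1[b = h]`. The core problem solved here
seeks `k` arrangements maximising

```
Σ_e w(e) · 1[e concordant in ≥ 1 of the k arrangements]
```

The problem is NP-complete. The package provides:

* **greedy solvers** with proven floors — end-placement (≥ w(E)/4) and
  insertion variants, plus an iterative multi-arrangement scheme (≥ 3/4 of
  the k = 2 optimum with an exact subsolver, ≥ 3/16 with the greedy one);
* an **exact integer-program formulation** for general k, solved by a
  built-in deterministic branch-and-bound backend, with per-connected-
  component decomposition and time limits (`detect_tsvs`, the diploid
  k = 2 default);
* a **brute-force oracle** for small instances, backing every guarantee
  with exhaustive enumeration;
* **conflict-structure analysis**: per-edge classification of discordant
  evidence as requiring a second allele or not, via simple-cycle
  compatibility with timeout/rerun labelling, and a
  per-sample heterogeneity fraction;
* a **TSV caller** with BEDPE output and a seeded **synthetic instance
  generator** with known ground truth.

## Worked example

Two segments `u = [0, 100)` and `v = [100, 200)` on one chromosome carry
two mutually conflicting discordant edges: tail–tail (weight 3) and
head–head (weight 2). No single arrangement satisfies both.

```r
library(gsgtools)
g <- example_conflict_gsg()
g
#> Genome segment graph: 2 segments on 1 chromosome(s), 2 edges (total weight 5)

solve_ilp(build_ilp(g, 1))$status$objective   # homogeneous model
#> [1] 3

res <- detect_tsvs(g, k = 2)                  # diploid model
res$objective
#> [1] 5
res$calls[, c("pos1", "pos2", "type", "category", "weight", "alleles")]
#>   pos1 pos2 type   category weight alleles
#> 1    0  100   HH REARRANGED      2       2
#> 2  100  200   TT REARRANGED      3       1
write_arrangements(res$arrangements)
#> 1  u  -v
#> 2  -u  v
```

Under the homogeneous model only the heavier edge (weight 3) can be
explained; with two alleles, flipping `v` in one arrangement and `u` in
the other satisfies both edges (objective 5 = total weight), and both are
reported as `REARRANGED` TSVs with their breakpoints and supporting
allele. The conflict census confirms the sample cannot be homogeneous:

```r
heterogeneity_fraction(g)$fraction
#> [1] 1
```

A command-line front end wraps the same functionality:

```sh
exec/gsgtools solve --gsg locus.gsg --method ilp --k 2 --out-prefix out
exec/gsgtools conflicts --gsg locus.gsg --out-prefix out
exec/gsgtools simulate --seed 7 --k-alleles 2 --out-prefix sim
exec/gsgtools evaluate --truth sim.truth.bedpe --calls out.tsv.bedpe
```

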