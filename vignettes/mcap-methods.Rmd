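---
title: "Detecting transcriptomic structural variants in heterogeneous samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptomic structural variants in heterogeneous samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsgtools)
```

## The problem

Transcriptomic structural variants (TSVs) are novel adjacencies in
transcript sequences caused by genomic structural variation — fusion genes
and genic/intergenic joins — that cannot be explained by alternative
splicing. RNA-seq read pairs whose alignments disagree with the reference
genome are the evidence; the difficulty is that tumour samples are
heterogeneous: several distinct alleles coexist, and adjacencies from
different alleles can be mutually contradictory. Under a homogeneous
(single-allele) model, contradictory candidates look like errors and are
discarded, so true variants are lost.

`gsgtools` models the sample explicitly as $k$ alleles. Its inputs are
*genome segment graphs* (GSGs): the genome is partitioned into disjoint
segments, each segment contributes a head vertex (5'-proximal end) and a
tail vertex, and a weighted undirected edge between endpoints of two
different segments records the number of read pairs supporting that
adjacency. Building a GSG from alignments is upstream of this package; the
graph is read from a small line-based text format (see `?read_gsg`).

## Arrangements and concordance

An *arrangement* $(\pi, f)$ is a permutation of all segments plus a
per-segment orientation bit ($f(u) = 1$ keeps the original orientation,
$0$ inverts), modelling one allele's rearranged genome. An edge joining
segment $u$ on end $a$ and segment $v$ on end $b$ with $\pi(u) < \pi(v)$
is *concordant* when

$$f(u) = \mathbf{1}[a = t] \quad\text{and}\quad f(v) = \mathbf{1}[b = h],$$

i.e. reading the arranged genome 5' to 3', the connection leaves $u$
through a tail and enters $v$ through a head. The test is symmetric in the
edge's stored endpoint order, and a vertex may carry several concordant
edges at once — that is how alternative splicing is accommodated. One
useful consequence, exercised in the tests: for a fixed placed segment and
a connecting edge, exactly one of the four placements of the other segment
(before/after $\times$ two orientations) makes the edge concordant.

Given $k$ arrangements $A$, the *multiple compatible arrangements*
objective is

$$\max_A \sum_{e \in E} w(e)\, \mathbf{1}[e \sim A],$$

where $\mathbf{1}[e \sim A]$ is 1 when $e$ is concordant in at least one
arrangement of $A$. Each edge counts once however many alleles satisfy it.
$k = 1$ is the homogeneous special case. The problem is NP-complete, which
motivates the three solver families below.

## Solvers

**End-placement greedy** (`scap_greedy_ends`). Segments are placed one at
a time, by default in genomic order; each new segment is tried at four
options — append or prepend, in both orientations — and the option making
the largest weight of edges to already-placed segments concordant wins.
The four options satisfy disjoint subsets of those edges whose union is
all of them, so the chosen option captures at least a quarter of that
weight; summing over iterations gives the guarantee
$w(E')\ \ge\ w(E)/4 \ \ge\ \mathrm{OPT}_1/4$. Gains are computed by direct
evaluation of the concordance rule on the tentative arrangement (not by
the closed-form endpoint subsets, which assume original orientations for
placed segments); the partition property is kept as a test invariant.

**Insertion greedy** (`scap_greedy_insert`). Identical, except every
internal insertion position is also tried. Insertion never changes the
relative order or orientation of already-placed segments, so previously
concordant edges stay concordant; the candidate set contains the four end
options, so the same $1/4$ floor holds, and in practice it is often
better (the package's own three-segment example: insertion attains the
optimum 7 where end-placement reaches 6).

**Iterative multi-arrangement** (`mcap_iterative`). Round $i$ solves a
single-arrangement instance on the residual graph in which edges already
satisfied have weight zero (weights are zeroed, not edges deleted, so the
topology seen by the oracle is unchanged). With an exact oracle and
$k = 2$ the result is at least $\tfrac34$ of the two-arrangement optimum;
with the end-placement greedy as oracle, at least $\tfrac{3}{16}$. Both
floors are verified empirically against the brute-force oracle on 500
random instances (3–5 segments, 3–8 edges, integer weights 1–10); observed
minima run well above the proven floors (about 0.45, 0.81 and 0.62 in a
typical run).

**Exact ILP** (`build_ilp` / `solve_ilp`). For general $k$ the problem is
written as a 0/1 program: per arrangement, orientation variables $y_u$,
one ordering variable $z_{uv}$ per unordered segment pair ($u$ precedes
$v$; the reverse is structurally $1 - z_{uv}$, so antisymmetry holds
identically), and per-edge indicators $x_e$; a cover variable $q_e$ with
$q_e \le \sum_i x_e^i$, $q_e \le 1$ feeds the objective
$\sum_e w(e) q_e$. Each edge contributes four one-sided cap constraints
per arrangement tying $x$ to its connection type (tail–head:
$z = y_u = y_v$; tail–tail: $z = y_u = 1 - y_v$; head–tail:
$z = 1 - y_u = 1 - y_v$; head–head: $z = 1 - y_u = y_v$), and each
segment triple a transitivity band $0 \le z_{uv} + z_{vw} - z_{uw} \le 1$.
Caps are one-sided because maximisation supplies the converse. With this
encoding the model for the two-segment worked example at $k = 1$ has 7
variables and 12 constraints.

The model is backend-agnostic (a triplet constraint matrix with row
bounds). It is solved by the package's own exact branch-and-bound backend
(`src/bnb.cpp`): depth-first search with bound-consistency propagation on
every row, the trivial objective bound (sum of attainable coefficients),
and a fixed branching order — per-edge indicators heaviest edge first,
then ordering and orientation variables — with value 1 tried before 0.
The backend is fully deterministic; a seed argument is accepted for
interface stability but has no effect. Feasibility tolerance is $10^{-9}$.
When a time limit is set, the search aborts at the first check after an
incumbent exists and reports `FEASIBLE_TIME_LIMIT`; the incumbent is
decoded as usual. Arrangements are decoded from $z$ (a total order by
antisymmetry plus transitivity: a segment's rank is the number of segments
preceding it) and $y$; an $x$ variable may be 0 on an edge the decoded
arrangement happens to satisfy, so the decoded objective can only equal or
exceed the solver objective — both facts are test invariants. Exactness is
checked against exhaustive enumeration on hundreds of random instances for
$k \in \{1, 2\}$.

**Brute force** (`scap_exact` / `mcap_exact`). The ground-truth oracle:
all $n!\,2^n$ arrangements enumerated in chunks (size caps: 8 segments for
$k = 1$, 5 for $k \ge 2$). For $k \ge 2$ the per-arrangement
concordant-edge masks are packed into integers and deduplicated — an
arrangement and its reverse share a mask, and many arrangements collapse
onto few masks — before the best $k$-subset union is searched. Ties break
by enumeration order, so results are deterministic.

**Production pipeline** (`detect_tsvs`). The diploid default: split the
graph into connected components, solve each component's ILP with $k = 2$
under a per-component time limit (default 3600 s), compose per-component
arrangements into genome-wide arrangements in genomic order (valid because
no edge crosses components), and call TSVs. A failed component falls back
to its reference arrangement with a warning. The greedy and brute methods
are selectable alternatives for large or tiny inputs respectively. The
greedy solvers themselves run in one pass over the whole graph: placement
gains only involve edges between the new segment and placed segments, all
of which are intra-component, so per-component execution would choose the
same relative placements and the same objective.

## TSV calling conventions

An edge is reported as a TSV when it is concordant in at least one
solution arrangement and is not an ordinary nearby reference adjacency.
Categories:

* `REARRANGED` — the edge fails the concordance rule under the reference
  arrangement: the adjacency exists only in a rearranged allele.
* `DISTANT` — the edge satisfies the concordance rule under the reference
  order too, but joins segments on different chromosomes or separated by a
  genomic gap above `max_distance`: too far to be alternative splicing.

Design choices a user should know: (1) *reference concordance* for
conflict labelling additionally requires both endpoints on one chromosome
— chromosome concatenation order is arbitrary, so cross-chromosome
adjacencies always surface as TSVs; (2) the category-2 distance is the
*gap* between the segment intervals (start of the later minus end of the
earlier), not breakpoint-to-breakpoint, with default
`max_distance = 200000` bp (configurable; typical intron scales make
shorter same-chromosome reference adjacencies plausible splices);
(3) breakpoint coordinates map an H endpoint to the segment's start and a
T endpoint to its end, making BEDPE output deterministic; (4) when several
arrangements satisfy an edge, all allele indices are reported — phasings
are generally non-unique and no canonical one is chosen.

## Conflict structures and heterogeneity

To ask whether a *single* allele could explain all discordant evidence,
the graph is augmented with one segment edge per segment joining its own
head and tail (`conflict_graph`). Two facts drive the analysis: any
subgraph acyclic in adjacency-plus-segment edges is satisfiable by one
arrangement; and a simple cycle is satisfiable if and only if exactly two
of its vertices carry two adjacency edges within the cycle and those two
vertices lie on different segments (`is_cycle_compatible`).

The practical labelling procedure (`classify_discordant_edge`) follows the
standard recipe: enumerate simple paths between a discordant edge's
endpoints with the edge removed (depth-first, deterministic neighbour
order on the first attempt), close each path into a cycle, and stop at the
first cycle failing the compatibility test — the edge is `IN_CONFLICT`
with that witness cycle attached. If enumeration completes without one,
the edge is `NOT_IN_CONFLICT`. An attempt exceeding the timeout (default
0.5 s) is retried with a seeded shuffle of the neighbour order; after
`max_reruns` retries (default 1000) the label is `UNDECIDED`. A
non-positive timeout times out immediately, so `timeout = 0` with
`max_reruns = 0` labels everything `UNDECIDED` — a useful contract check.
`heterogeneity_fraction` classifies every discordant edge and reports the
`IN_CONFLICT` share: the more discordant evidence needs a second allele,
the more heterogeneous the sample.

**Known limitation.** The cycle characterisation's proof covers cycles in
which interior vertices alternate between adjacency and segment edges —
at most two "pass-through" vertices carrying two adjacency edges. On
unrestricted simple cycles the test is *conservative*: a compatible
verdict is always confirmed by brute force, but cycles threading four or
more endpoints by pairs of adjacency edges (splice-like chains) can be
satisfiable by one arrangement yet still be flagged as conflicts. The
package keeps this characterisation as-is; the property suite asserts
exact agreement with brute force within the proof's scope, the one-sided
guarantee outside it, and keeps a frozen counterexample. Heterogeneity
fractions should therefore be read as upper bounds in graphs rich in such
chains.

## The synthetic generator

`simulate_instance` emulates the GSG a heterogeneous sample would induce,
with every knob in `sim_config`. Defaults model a small diploid locus and
are the conditions under which the validation suite runs: one chromosome
cut into five 1-kb segments; two alleles, each derived from the reference
arrangement by one random operation (inversion of a run, move of a run, or
a two-segment swap); per allele, edges drawn between facing ends of
segment pairs ordered in that allele — adjacent pairs with probability
0.7, otherwise any ordered pair, so splice-like skips occur — which makes
every planted edge concordant in its source allele by construction (and
asserted at generation time); integer weights from a Poisson law around
mean 10 (support at least 1); zero noise edges by default, and when
requested, uniform endpoint pairs with weights capped at 3 so planted
signal dominates (both overridable). The ground truth records the planted
arrangements, each planted edge's source allele, and the planted
reference-discordant edges — the true TSVs. `evaluate_calls` scores calls
against truth by exact breakpoint-pair identity (simulation and calling
share one coordinate system, so no positional tolerance is needed),
ignoring phasing.

What the generator does *not* model: read-level errors and coverage
fluctuation, alignment artefacts, expression levels, tumour purity
mixtures, or segmentation errors. Passing recovery tests therefore show
that the solvers and caller invert the generative model exactly at
matching $k$ on clean small instances — not that calling is robust to
upstream noise on real alignments.

## Validation sizes and numerical choices

The validation suite runs entirely on generated instances: approximation
floors on 500 random graphs (3–5 segments, 3–8 edges, weights 1–10); ILP
exactness on 200 ($k=1$) plus 100 ($k=2$) graphs of up to 4 segments;
theorem properties on 200 random segment trees and 200 random simple
cycles within the proof's scope; noise-free recovery on 50 seeded diploid
instances of 5 segments; and a quarter-weight floor sweep over 1000 graphs
of up to 8 segments. These sizes keep the brute-force oracle exact and
the whole suite fast while exercising every code path; the same
computations are reproduced by `scripts/acceptance.R`.

Numerical and tie-breaking choices, in one place: weights are accepted as
nonnegative reals (integer read counts are typical; zero-weight edges are
kept but contribute nothing); duplicate edge records merge by weight
summation, so a graph holds at most one edge per endpoint pair; greedy
tie-breaks are fixed (append/1, append/0, prepend/1, prepend/0; for
insertion, lowest position first, orientation 1 before 0); brute-force
ties break by enumeration order; the branch-and-bound uses a $10^{-9}$
tolerance and prunes nodes that cannot strictly improve the incumbent;
coordinates are 0-based half-open throughout (BED-compatible). Within-
segment edges are rejected at parse time — the concordance rule
presupposes two distinct segments. Degenerate inputs (empty graphs,
edgeless segments, single segments) are legal everywhere and return empty
or zero-weight results.
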