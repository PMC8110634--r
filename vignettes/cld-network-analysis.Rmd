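---
title: "Network analysis of signed causal loop diagrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network analysis of signed causal loop diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldtools)
```

## The object of study

A causal loop diagram (CLD) is a conceptual model of a complex system: a
directed graph whose nodes are system variables and whose edges are
hypothesized causal influences, each carrying a polarity. A positive
connection means that when the source variable moves, the target moves in
the same direction; a negative connection means it moves in the opposite
direction. CLDs are the standard artifact of group model building, in which
a panel of domain experts converges on a shared map of a system — for
example, the biopsychosocial etiology of Alzheimer's disease, mapped as a
few dozen variables in brain-health, physical-health and psychosocial
categories with on the order of 150 connections.

Such diagrams are qualitative, but their *structure* can be interrogated
quantitatively. This package implements the standard structural analyses:

1. **Centrality** — which variables sit on many causal pathways
   (betweenness) or can reach much of the system quickly (closeness)?
2. **Robustness** — how stable are those centrality values to small errors
   in the wiring?
3. **Feedback loops** — which reinforcing (self-amplifying) and balancing
   (homeostatic) cycles does the diagram contain, and do they stay within
   one spatial scale or cross scales?
4. **Omission sensitivity** — does the centrality ranking of a variable of
   interest survive removal of related detail variables?

## Centrality on a causal diagram

Shortest paths in a CLD are the causal pathways with the fewest mediating
variables; if each mediator is an opportunity for interference or noise,
shortest paths are plausibly the strongest pathways. Both measures ignore
polarity and edge weights — a CLD asserts existence and sign of influences,
not their strength.

The normalized betweenness centrality of variable $v$ in a diagram with $N$
variables is

$$\mathrm{BC}_v = \frac{1}{(N-1)(N-2)} \sum_{s \ne v \ne t}
  \frac{\sigma(s,t\,|\,v)}{\sigma(s,t)},$$

where $\sigma(s,t)$ counts distinct shortest directed paths from $s$ to $t$
and $\sigma(s,t\,|\,v)$ those passing through $v$. Two conventions are
fixed deliberately:

* **Endpoint exclusion.** The sum ranges over ordered pairs with
  $s \ne v \ne t$. This is what makes $\mathrm{BC} = 0$ an exact structural
  signature of exogenous variables (in-degree zero): no path can pass
  *through* a variable nothing points at. The package asserts this
  invariant property-style on arbitrary generated diagrams.
* **Unreachable pairs contribute zero** (the $\sigma(s,t) = 0$ terms are
  skipped); CLDs are rarely strongly connected.

Closeness is **outward**:

$$\mathrm{CC}_v = \frac{n-1}{\sum_{u} d(v,u)},$$

summed over the $n-1$ variables *reachable from* $v$. Outward direction
matters scientifically: an exogenous driver such as education level can
have high closeness (it reaches much of the system in few steps) while its
betweenness is exactly zero. For disconnected diagrams two conventions
circulate, and the package exposes both: `as_printed` computes the formula
on the reachable set only, while `wf_scaled` additionally multiplies by the
reachable fraction $(n-1)/(N-1)$ (the Wasserman–Faust correction), which
penalizes variables that reach only a small component. They coincide on
strongly connected diagrams; rank correlations between betweenness and
closeness are reported under both, since the choice is consequential
exactly when the diagram has many near-sink variables.

Betweenness uses Brandes' dependency accumulation over a breadth-first
shortest-path census; the census itself (`single_source_shortest_paths`)
is exposed because $\sigma$-counts are useful diagnostics in their own
right. The test suite pins both measures to brute-force oracles —
exhaustive simple-path enumeration for betweenness, an independent
distance-matrix computation for closeness — across hundreds of random
digraphs, and to hand-computed values on canonical small cases.

## Robustness: the mutation ensemble

A group-built diagram is a consensus artifact; individual connections may
be wrong. The robustness procedure asks whether conclusions about *which
variables are central* would survive such errors. From the original
diagram, `centrality_ensemble()` generates (by default) 1000 mutants, each
5 mutations away, recomputes both centralities on every mutant, and
summarizes each variable's distribution by quartiles; the interquartile
range is the error bar (`plot_centrality_robustness()` draws the familiar
ranked point-with-IQR figure).

A mutation is, with equal probability 1/3 each: a **rewire** (keep source
and polarity, resample the target among variables the source does not
already influence), an **addition** (a uniformly random absent ordered
pair), or a **deletion** (a uniformly random connection). Choices fixed
here, with their rationale:

* *Equiprobable kinds* are read as 1/3 each. A defensible alternative reads
  "rewiring or addition-or-deletion" as 1/2 : 1/4 : 1/4; `kind_probs`
  exposes it. Edge-count drift after $k$ mutations is bounded by $k$ either
  way, which the suite asserts from the mutation event logs.
* Mutations apply *sequentially* to the evolving copy, and an infeasible
  draw (e.g. addition on a complete digraph) is redrawn, so a mutant is
  always exactly $k$ mutations from the original.
* An added connection is positive with probability equal to the original
  diagram's positive fraction. Polarity cannot affect centrality (which is
  sign-blind), so this choice only matters if mutants are exported and
  their loops analysed.
* Quartiles use linear interpolation (`stats::quantile` type 7), recorded
  in the summary object.
* **Seeding.** One integer seed; per-replicate child seeds are drawn once
  up front (`sample.int(.Machine$integer.max, n_replicates)` under
  `set.seed(seed)`) and each replicate runs under its own `set.seed`.
  Summaries are therefore bit-reproducible and independent of replicate
  execution order, and the caller's RNG state is restored afterwards. Note
  the published experiment this mirrors did not state its RNG, so
  reproduction is at the level of the protocol (1000 × 5, equiprobable),
  not bit-level.

On the packaged 38-variable diagram the full 1000 × 5 ensemble takes a few
seconds, so the suite runs it at published scale.

## Feedback loops

Feedback drives the nonlinear behavior of dynamical systems. A loop is
**reinforcing** when the product of its edge polarities is $+1$ (an even
number of negative links — perturbations are amplified) and **balancing**
when the product is $-1$ (self-limiting, homeostatic). Loops of exactly two
variables are **direct**; longer ones **indirect**. A loop whose members
all share one spatial-scale label is **within-scale**; one spanning several
labels is **cross-scale** — the kind most easily missed by single-domain
research. When explicit scale labels are absent, the health category
(brain/physical/psychosocial) serves as the proxy label, recorded in the
result's metadata.

`enumerate_loops()` performs a bounded-depth DFS with the root-is-minimum
pruning rule: each simple directed cycle up to `max_length` is found
exactly once, in canonical rotation (starting at its lexicographically
least member). Cycles are identified up to rotation but *not* reversal —
the two traversal directions of the same variable set are genuinely
different causal loops, and both can coexist. The bound is deliberate: a
full cycle census is combinatorial, and interpretation of long loops in a
qualitative diagram is ambiguous anyway; the intended regime is
`max_length` up to about 6 on diagrams of some tens of variables.
Enumeration is pinned, again property-style, to a brute-force check of
every vertex subset and ordering on small random digraphs, and to planted
diagrams with a known census.

`loop_table()` emits the conventional table with `RD*` (direct) and `RI*`
(indirect) identifiers in deterministic order.

### The packaged fixtures and their limits

Two related fixtures ship with the package:

* `ad_loop_rows()` — the transcription of the published table of 30
  reinforcing loops (14 direct, 16 indirect) from the Alzheimer's disease
  diagram, and `fixture_from_loop_table()`, which builds the implied edge
  union reading each row as a cycle `first -> second (-> third) -> first`
  with the canonical all-positive polarity assignment (only the polarity
  *product* of each loop is constrained by a reinforcing-loop table; the
  all-positive representative is counterfactual for some real connections,
  e.g. the mutually negative physical-activity/depressive-symptoms pair,
  without affecting any loop-class conclusion).
* `synthetic_ad_cld()` — a full 38-variable / 150-connection synthetic
  reconstruction. The deposited diagram itself is not redistributed here;
  the reconstruction embeds every printed structural fact — all 30 loops,
  the three exogenous variables, the category sizes, neuronal dysfunction
  as the dominant hub — and fills the remaining connections once from the
  narrative description of the system (risk factor to vascular to
  neurodegenerative to functional pathways), under the construction rule
  that filler edges close no new cycle of length three or less.

One genuine limitation is worth stating precisely, because it is a theorem
about the printed table rather than a software choice. The union of the 30
printed loops *necessarily* contains short cycles beyond the printed ones:
printed loops share edges, and shared edges compose into new cycles. For
example, the printed 2-loops sleep-quality/stress and sleep-quality/social-
relationships plus the printed stress–social-relationships link force a
stress/sleep/social-relationships triangle that the printed table does not
list, in either traversal direction; an exhaustive search over all $2^{16}$
row orientations shows at least 20 indirect loops (and physical activity in
at least 9) in any diagram containing all 30 printed loops. The printed
table is thus a curated selection, not an exhaustive census. Consequently
fixture-based tests assert *containment* — every printed loop is recovered
— while exact printed counts (16 indirect in total; 7 indirect through
physical activity) are not reproducible from printed information alone, and
the corresponding checks document this as expected failures. The
reconstruction uses the orientation with the minimal number of forced extra
cycles (two rows traversed opposite to column order, one of which the
narrative text independently supports); the loop-table fixture keeps the
column order as printed.

The same caveat applies to continuous statistics: the rank correlation
between betweenness and closeness measured on the reconstruction (about
0.40 under `as_printed` closeness, 0.36 under `wf_scaled`) reflects the
reconstruction's filler wiring, which was written from the narrative once
and not adjusted thereafter; the published value (0.50) lives on the
unavailable true wiring. Passing structural tests on the reconstruction
shows the *algorithms* reproduce printed structure; it does not validate
the reconstruction's unprinted details against the real diagram.

## Omission sensitivity

`omit_and_recompute()` removes chosen variables with their incident
connections and recomputes both centralities on the induced subdiagram.
The motivating use is an aggregation-bias check: cerebrovascular pathology
appears in the published diagram both as an aggregate (cerebral endothelial
dysfunction) and as detail variables (white matter hyperintensities,
microbleeds, lacunar infarcts); if removing the detail variables barely
moves the aggregate's betweenness rank, the aggregate's central position is
not an artifact of double representation. Ranks are dense over the
surviving variables on both sides of the comparison, ties broken by name,
and the report returns numbers (rank shifts and both centrality tables),
leaving "comparable level" judgments to the analyst.

```{r omission}
d <- synthetic_ad_cld()
om <- omit_and_recompute(d, c("White matter hyperintensities",
                              "Microbleeds", "Lacunar infarcts"))
om$rank_shift[["Cerebral endothelial dysfunction"]]
```

## Synthetic diagrams

`generate_random_cld()` emulates the gross structure of group-built health
CLDs: 38 variables, 150 connections (about four per variable), three
categories, three exogenous variables, about a third of connections
negative, and about 19% of connections in reciprocal pairs. Those defaults
are the published diagram's shape; all are parameters. The generator
guarantees its contract exactly where the contract is structural (exact
connection count, no self-loops, exogenous set of exactly the requested
size) and approximately where random fill can interfere (the reciprocal
fraction). What it does **not** emulate: real CLDs are not uniform random
graphs — they have hub structure, near-DAG backbones from risk factors to
outcomes, and clustered feedback; conclusions about real diagrams should
lean on the fixtures above, with the generator serving as the source of
arbitrary valid inputs for property-style testing. `planted_cycle_cld()`
builds vertex-disjoint cycles so the loop census is known by construction
— the oracle for enumeration tests.

## Numerical and degenerate-input choices

* Betweenness requires $N \ge 3$ (the normalization is otherwise
  undefined) and omission must leave at least 3 survivors; both error
  explicitly.
* A variable reaching nothing has closeness 0 by convention.
* All name matching is case-sensitive after trimming and collapsing
  internal whitespace; polarity tokens `+`, `-`, `+1`, `-1`, `1`, `-1` and
  the typographic minus are accepted.
* Validation (`validate_cld()`) is total — it reports coded errors and
  warnings and never raises, so it can be used to triage arbitrary input;
  constructors (`cld()`, `parse_edge_tables()`) raise on the first
  structural violation instead.
* Serialization is deterministic (variables sorted by name, connections by
  source then target), so exported artifacts diff cleanly under version
  control.

## Problem sizes in the shipped tests

The suite checks the algorithms against brute-force oracles on hundreds of
random digraphs of up to 6 nodes (where exhaustive enumeration is exact and
fast), runs the robustness ensemble at the published 1000 × 5 scale on the
38-variable reconstruction (a few seconds), and exercises the pipeline and
command-line front end end-to-end on small generated diagrams. These sizes
were chosen so the whole suite completes in a few minutes while every
algorithmic path is covered exactly.
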