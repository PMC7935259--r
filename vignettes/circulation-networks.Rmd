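---
title: "Circulation networks from sampling-inspection records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circulation networks from sampling-inspection records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind each
statistic, the conventions adopted where the literature leaves a choice open,
the tunable parameters with their defaults, and what the synthetic-data
generator does and does not emulate. The README shows a worked run; here we
explain why the machinery is built the way it is.

## 1. The data model and the cleaning rules

A record is one sampled food item: a status (`qualified` or `substandard`),
free-text manufacturer and distributor addresses, and optionally a date and a
food name. Two preprocessing rules are applied by `clean_records()`:

1. **Missing-party removal.** Records lacking either address are useless for
   route construction and are dropped, after normalization — whitespace is
   collapsed and full-width ASCII forms (common in Chinese administrative
   exports) are converted to half-width, so a cell of ideographic spaces
   counts as empty.
2. **Exact deduplication.** Public inspection systems republish entries; we
   collapse exact matches on the tuple *(status, manufacturer address,
   distributor address, food name, sample date)*, keeping the first. This is
   deliberately conservative: no fuzzy linkage, no same-day heuristics, so the
   rule is reproducible and cannot merge genuinely distinct samples. Records
   whose status cannot be coerced to either enum value are dropped and
   counted, never guessed.

Both rules report their removal counts, because in this kind of analysis the
headline preprocessing numbers (raw records, retained substandard records) are
themselves results. `clean_records()` is idempotent and never mutates its
input.

## 2. Offline geocoding against a gazetteer

The original workflow for data of this kind calls a commercial geocoding API.
The package replaces that with an offline gazetteer — a two-level table of
provinces and cities with match keys — for three reasons: reproducibility
(identical input, identical output, no network), testability, and the
observation that every downstream statistic uses only province/city
*identity*, never coordinates. Gazetteer centroids are carried as opaque
display values; no datum conversion is attempted since coordinates never enter
any formula.

Matching is by longest key, then leftmost occurrence, within each level. A
city match implies its parent province; any contradiction — tied keys naming
different cities, two distinct province keywords in one address, or a province
keyword disagreeing with the matched city's parent — yields `unresolved` with
a conflict note rather than a guess. Direct-administered municipalities are
modeled as a province-level and a city-level unit with the same name (match
keys are unique per level, not globally), so they appear in both networks, as
they should.

A single-function plugin contract (`fallback = function(addresses) ...`) lets
a remote geocoder fill gazetteer misses; its answers can be cached to CSV so
re-runs stay offline and reproducible. Tests never call remote services.

## 3. Networks and the self-loop policy

`build_network()` counts records per ordered (manufacturer unit, distributor
unit) pair. Within-unit records become explicit self-loops: they are the
*local circulation* mass, typically the majority of all routes, and are
reported via `within_unit_fraction()`. All degree-based topology statistics —
degree, density, betweenness, communities, key players — exclude self-loops,
matching the default behavior of the standard network toolchain this field
uses; a self-loop says nothing about between-unit structure. The two headline
facts are thus kept separate by construction: how much circulation is local
(self-loop share) and how the non-local part is organized (everything else).

Conservation invariants are enforced and tested: total edge weight equals the
record count fed in; the province network equals the city network aggregated
by parent (`aggregate_to_province()`), exactly.

## 4. Descriptive statistics: conventions

- **Flow ratio.** The in/out ratio is computed on *weighted* flows by default
  (`weighted_in / weighted_out`), because net-source/net-destination language
  is about record volumes; the unweighted degree ratio is returned alongside
  (`ratio_unweighted`) for users who want the partner-count version. Nodes
  with zero outflow get an explicit `Inf` sentinel, isolated nodes `NaN`.
- **Mean degree.** Indicator tables in this literature are not always explicit
  about whether an edge counts once or at both endpoints, and the printed
  values do not reconcile under a single convention; `summarize_network()`
  therefore emits both `e/n` and `2e/n`, and likewise mean weighted degree
  with and without self-loop mass.
- **Diameter.** On directed graphs that are not strongly connected the
  textbook diameter is infinite, yet surveillance networks routinely contain
  pure sources and pure sinks. We report the longest shortest path over
  *reachable ordered pairs*, with the unreachable-pair count and a
  strong-connectivity flag alongside, so the number is finite and its caveat
  is visible.
- **Circulation intensity** is substandard flow per 1,000 samples taken in the
  unit: `1000 * flow / total_samples`, where the denominator counts all
  sampled items (qualified + substandard) whose distributor resolves to the
  unit — sampling happens at the point of sale. Within-unit mass counts toward
  both in- and out-intensity by default (a locally circulated record is both
  supplied and received there); `include_self_loops = FALSE` gives the
  cross-border variant. Units without a positive denominator are flagged
  `unscorable`, never silently zeroed.

## 5. Natural breaks and pattern quadrants

`jenks_classes()` implements the exact Fisher–Jenks dynamic program (O(k n²)),
not the popular iterative approximation: it minimizes the total within-class
sum of squared deviations over all placements, which the test suite verifies
against exhaustive enumeration of break positions. Intervals are reported
half-open `[lo, hi)` with a closed last interval, each class's upper edge
being the next class's minimum — the bracket pattern conventional in
choropleth class tables. Ties in the DP are broken toward the smallest start
index of the last class, making breaks deterministic. Fewer distinct values
than classes is an error, not a silent merge.

Pattern quadrants cross the two class scales: `A_high_both` (both intensities
in the top class), `B_net_destination` (in top only), `C_net_source` (out top
only), `D_low_both` (both bottom), else `unclassified`. With four classes this
deliberately labels only the extremes; middle-class units stay unclassified
rather than being forced into a quadrant.

## 6. Betweenness

Node betweenness sums, over ordered pairs (i, j) with i ≠ j ≠ k, the fraction
of shortest directed i→j paths through k (endpoints excluded); edge
betweenness is the analogous per-edge passage fraction with i ≠ j. Pairs with
no connecting path contribute nothing. The implementation is Brandes'
dependency accumulation, exact, computed per source with level-synchronous
BFS.

**Distances are hop counts by default.** Edge weights here are flow volumes,
not lengths; a tool that silently treats weight as distance makes the heaviest
route look *longest*, inverting the meaning. A weighted mode interpreting
distance as `1/weight` (heavier flow = closer) is available behind
`weighted = TRUE` and is documented as non-default. Percentage shares
(`score / Σ score × 100`) accompany raw scores, since ranked key-path tables
are conventionally presented as shares of total betweenness.

## 7. Louvain communities

Modularity is evaluated on the *symmetrized* weighted graph
(`w_sym(u,v) = w(u,v) + w(v,u)`), the standard treatment of directed input by
the common implementations, and stated here prominently because the formula
itself is undirected. Original self-loops are excluded (section 3); self-loops
created by aggregating communities into super-nodes carry the internal
community weight and do count, with the usual convention that a self-loop of
weight *s* adds 2*s* to its node's strength — this is what makes the
aggregated graph's modularity equal the original partition's.

The sweep moves each node, in a seeded random order, to the neighboring
community with the largest strictly positive gain, ties toward the lowest
community id; phases iterate until Q stops improving (tolerance 1e-12). The
one-node gain formula has a subtlety worth recording: written with community
sums `S_in` and `S_tot` that count internal adjacency from both endpoints, the
node's own term must also be counted from both endpoints — `k_i_in` is *twice*
the symmetric weight from the node to the community. Under that reading the
fast formula is algebraically identical to the direct modularity difference,
which the test suite verifies over exhaustive move sets; under the "once"
reading it is off by a factor on the linear term. `delta_q()` exposes the
formula for the isolated-node case it is defined for and errors otherwise.

The seed is a required, defaulted (42) parameter: identical seed and input
give an identical partition, and the pipeline records it in every output. On
small graphs the achieved Q is compared in tests against the exhaustive
optimum over all set partitions; Louvain is greedy, so on unstructured random
graphs a small optimality gap can remain — the tests assert the achieved Q
never exceeds the true optimum and recovers it exactly on structured fixtures.

Gatekeepers are each community's betweenness maximum — the member most often
bridging shortest paths, typically its link to other clusters.

## 8. Key players

The reach measure is `D_R = (1/n) Σ_i 1/d(S, i)` with `d(S, i)` the minimum
shortest-path distance from the set. Two cases the formula leaves open are
fixed as in the original key-player software: members contribute 1 each
(self-distance zero maps to reciprocal 1), and unreachable nodes contribute 0.
Consequently `D_R ∈ [0, 1]`, is monotone under set enlargement, and equals 1
exactly when every node is in S or one hop from it — all three are tested
properties.

Distances follow edge direction *outward* from S by default (interventions
propagate along circulation out of key cities); `mode = "undirected"` matches
the original undirected formulation. The search is greedy forward selection
plus pairwise swap improvement, over seeded restarts: the first restart is
deterministic greedy, even restarts randomize greedy tie-breaking, odd
restarts start from random sets so the swap phase can escape greedy basins.
The result is therefore never worse than pure greedy, and on every exhaustively
searchable instance in the test suite (n ≤ 12, k ≤ 3) it equals the true
optimum. `key_player_profile()` optimizes each set size independently —
membership may churn between rows, which is expected, not a defect — and
reports the smallest k at which greedy extension attains full reach (an upper
bound on the true minimum).

## 9. The synthetic generator

`generate_records()` emulates the statistical structure the analysis assumes,
with full ground-truth bookkeeping (flow matrix, per-unit totals, hub and
block identities), so every pipeline stage is testable offline. Its defaults
are the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `n_provinces`, `cities_per_province` | 34, 11 | a national two-level system of ~374 cities |
| `samples_per_city` | 2600 | ≈ 1M samples nationally |
| `substandard_rate` | 0.021 | retained substandard share of all samples |
| `p_within_city` | 0.572 | routes staying inside the sampling city |
| `p_within_province` | 0.5724 | staying in-province, given cross-city; 0.572 + 0.428 × 0.5724 ≈ 0.817 overall |
| `weight_tail` | 1.1 | Zipf exponent of city base weights (long-tailed volumes) |
| `hub_fraction`, `hub_attraction` | 0.03, 3 | a few destination hubs |
| `seed` | 42 | fixes the entire dataset |

Destination (sampling) cities are drawn proportionally to a Zipf-tailed base
weight — the long-tail family is a free choice; any heavy-tailed positive
weight would serve — boosted on hubs; sources follow the
within-city/within-province/cross-province cascade; addresses are templated
from the gazetteer names so geocoding round-trips exactly. Qualified records
are generated alongside substandard ones so intensity denominators exist.
Gazetteer names are synthetic (`P03-C07 City`): the package ships no real
administrative data, and users supply their own gazetteer for real runs.

Two planted scenarios provide recovery targets. `plant_two_hub_scenario()`
gives two hubs in different provinces a fixed large share of cross-city flow,
each covering its own half of the provinces, while non-hub cities send
cross-city flow only to a small fixed neighborhood — so the hub pair is, by
construction, the unique size-2 set with full reach, and hub weighted degree
dominates every non-hub. `plant_block_scenario()` assigns provinces to blocks
and keeps cross-province routes inside their block with probability
`p_within_block`; at strong signal the city network's community structure is
the planted partition, and Louvain's recovery is scored by adjusted Rand
agreement.

What the generator does **not** emulate: real geography (adjacency,
distance-decay between specific provinces), food-category structure, temporal
trends, address misspellings or granularity noise, and correlated
inspection-intensity differences between regions. Passing tests on synthetic
data therefore demonstrate the correctness of the computations and the
recoverability of planted structure — not that any particular real dataset
will show the same network shape.

## 10. Numerical choices and problem sizes

Floating-point comparisons (gain positivity, reach improvement, Q
stabilization, tie detection) use a 1e-12 tolerance. All ranked outputs break
ties lexicographically by unit name so output order is deterministic.
Degenerate inputs have defined behavior throughout: empty networks warn and
return empty structures; modularity and `within_unit_fraction()` error on
zero-mass graphs; `density` requires n ≥ 2; intensity without a denominator
flags rather than zeroes.

Verification sizes were chosen so every oracle is exhaustive where that is
feasible: path-enumeration betweenness on ~200 random digraphs with n ≤ 8;
all set partitions (Bell numbers) for modularity optima at n ≤ 10; all
C(n, k) subsets for key players at n ≤ 12, k ≤ 3; all break placements for
Jenks at ≤ 25 values; and a 50,000-record generator run for parameter
recovery within three binomial standard errors. The acceptance script runs the
full pipeline at the generator's national-scale defaults (≈ 1M records, ~374
cities), which completes in about a minute on one core.

## 11. Known limitations

- Routes are single-hop by construction of the source data (manufacturer →
  distributor); no multi-hop reconstruction is attempted.
- Deduplication is exact-match only; spelling variants of the same enterprise
  count as distinct.
- Louvain is a greedy heuristic: community counts on weak-structure networks
  vary with the seed (the pipeline fixes and records it; the acceptance script
  reports the modal count over ten seeds).
- The key-player search is heuristic beyond exhaustively checkable sizes,
  matching the nature of the original software.
- Betweenness on networks whose weights should be interpreted as capacities
  rather than counts may warrant the weighted (`1/weight`) distance mode; that
  interpretation is left to the analyst.
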