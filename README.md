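# circnet

Multilevel circulation-network analysis of food sampling-inspection records.

## The problem

National food-safety surveillance programs publish sampling-inspection
results: each record is one sampled food item, its qualification status
(qualified or substandard), and the free-text addresses of its manufacturer
and its distributor. Each substandard record therefore witnesses one
circulation route — substandard food moved from the manufacturer's
administrative unit to the distributor's. Aggregated over tens of thousands
of records, these routes form directed, weighted circulation networks at the
province and the city level, and standard social-network machinery then
answers the questions regulators care about: where does substandard food
circulate, which units are net sources or net destinations, which cities
bridge the network, how does it decompose into regional clusters, and which
small set of cities would a targeted intervention have to cover?

`circnet` is a tested, reusable implementation of that pipeline for
statisticians and food-safety analysts. It takes a tabular record file plus an
administrative gazetteer and produces every standard report table; a fully
seeded synthetic-data generator with ground-truth bookkeeping makes the whole
chain testable without any restricted data.

## What it computes

For a network with `n` nodes, `e` directed cross-unit edges and weights
`w_ij` (record counts on route i→j):

- **Degree and flow metrics** — in/out degree, weighted in/out degree
  (`wd_i = Σ_j w_ij`), and the in/out flow ratio `r_i` separating *net
  destinations* (`r_i > 1`) from *net sources*.
- **Density** `e / (n (n − 1))`, diameter (longest directed shortest path over
  reachable pairs), weak components, and the usual medians/ranges.
- **Circulation intensity** — substandard in/out flow per 1,000 samples taken
  in a unit, classified into Lower/Low/High/Higher by exact Fisher–Jenks
  natural breaks, and crossed into pattern quadrants (high-both,
  net-destination, net-source, low-both).
- **Node and edge betweenness** — exact Brandes accumulation of shortest-path
  passage fractions `Σ_{i≠j≠k} σ_ij(k)/σ_ij` on the directed graph, reported
  as raw scores and percentage shares.
- **Louvain communities** — two-phase greedy maximization of modularity
  `Q = (1/2m) Σ_ij [A_ij − k_i k_j / 2m] δ(c_i, c_j)` with the fast one-node
  gain update, seeded and reproducible, plus per-community gatekeepers (the
  highest-betweenness member).
- **Key players** — the Borgatti reach formulation: the size-k node set S
  maximizing the distance-weighted reach `D_R = (1/n) Σ_i 1/d(S, i)`, found by
  greedy selection plus pairwise swaps over seeded restarts (exact on small
  graphs, verified against exhaustive search).

Everything upstream of those statistics — record cleaning and exact
deduplication, offline gazetteer geocoding of free-text addresses with a
pluggable remote-resolver hook, network construction with explicit self-loop
(within-unit) mass — is part of the package and tested.

## Worked example

```r
library(circnet)

ds <- generate_records(generator_config(n_provinces = 6, cities_per_province = 4,
                                        samples_per_city = 800,
                                        substandard_rate = 0.05, seed = 42))
ds
#> <synthetic_dataset> 19200 records over 24 cities (1013 substandard), seed 42

rep <- run_pipeline(ds$records, ds$gazetteer, seed = 42, k_max = 3, restarts = 10)
#> resolved 19200/19200 records at city level (100.0%)
rep
#> <pipeline_report>
#>   records: 19200 cleaned, 1013 substandard
#>   province: 6 nodes, density 0.967, within-unit 81.2%, 2 communities
#>   city: 24 nodes, density 0.322, within-unit 58.0%, 5 communities
```

19,200 samples yield 1,013 substandard records; 81.2% of their routes stay
inside one province and 58.0% inside one city (the generator's defaults target
0.817 and 0.572), so the cross-unit network is thin relative to the local
mass — the regime this analysis is built for. The heaviest routes and the
key-city profile:

```r
top_paths(rep$levels$city$network, k = 3)
#>   source  destination source_name  destination_name weight  rank
#> 1 P01-C01 P01-C03     P01-C01 City P01-C03 City         24     1
#> 2 P01-C02 P01-C03     P01-C02 City P01-C03 City         23     2
#> 3 P01-C04 P01-C03     P01-C04 City P01-C03 City         15     3

rep$levels$city$key_players
#>       k members                                  reach reach_pct
#> 1     1 P04-C02 City                             0.764      76.4
#> 2     2 P04-C02 City, P06-C01 City               0.896      89.6
#> 3     3 P01-C04 City, P04-C02 City, P06-C01 City 0.979      97.9
```

Covering three well-chosen cities already places 97.9% of the network within
reciprocal-distance reach of the set — the kind of statement the key-player
profile is for. Note the size-3 set is not a superset of the size-2 set: each
row is optimized independently.

For real data, replace the generator with `load_records()` (CSV/XLS/XLSX plus
a column map), `clean_records()`, and your own `read_gazetteer()` table.

## Further reading

The methods vignette (`vignettes/circulation-networks.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, the numerical conventions (tie-breaking, degenerate inputs,
self-loop policy), and what the synthetic generator does and does not emulate.
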