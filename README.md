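# nitroguild

Genome-resolved functional inference for nitrogen-removing microbial
communities.

Engineered communities that convert ammonia to dinitrogen gas — partial
nitritation/anammox (PNA) reactors — are assembled from a few autotrophic
ammonia oxidizers (aerobic AOB, anaerobic AnAOB) surrounded by a diverse
heterotrophic flora. Once a set of metagenome-assembled genomes (MAGs) has
been recovered and annotated, the interesting questions are functional:
which genomes carry which nitrogen-cycle genes, which guilds are present
or (for canonical nitrite oxidizers) conspicuously absent, whose
denitrification pathways are truncated and where the resulting NOx
intermediates must flow between cells, and who depends on whom for amino
acids and B-vitamins. `nitroguild` turns per-MAG gene annotation tables
into those answers.

## What it computes

Starting from two TSVs (per-genome gene annotations with optional hit
statistics; a MAG quality table with completeness/contamination), the
package provides:

* **Core filtering** — annotation hits kept at `E < 1e-5`, bitscore
  `> 60`, identity `> 30 %`; MAGs kept at completeness `>= 70 %` *or*
  zero contamination; dereplication by (completeness, contamination,
  assembly size).
* **Pathway calls** — declarative pathway definitions (steps with
  alternative enzymes) and the completeness heuristic used for draft
  genomes: a pathway with more than two steps tolerates one missing step;
  shorter pathways require every step. Autotrophy is called by key-gene
  screening of five carbon-fixation pathways (CBB, rTCA, Wood-Ljungdahl,
  3-HP, 3-HP/4-HB).
* **Nitrogen census and guilds** — operon-aware marker flags (amoCAB,
  hao, hzsABC, hdh, nxr classes, narGH, napAB, nirS/nirK, nirBD, nrfHA,
  norBC/norZ, nosZ clades I/II) and guild calls: AOB, AnAOB, canonical
  NOB, comammox, complete DNRA, complete denitrifier.
* **NOx exchange network** — per-genome transformation edges over
  NH3/NH2OH/NO2-/NO3-/NO/N2O/N2/NH4+/N2H4, denitrification endpoint
  labels ("NO3->NO2", "NO2->N2O", "full", composites), and
  community-level exchange candidates: intermediates some genomes can
  only produce and others can only consume.
* **Auxotrophy & complementarity** — 20 amino-acid and 8 B-vitamin
  prototrophy matrices, per-compound provider/dependent partitions,
  community-wide auxotrophies.
* **Read screen** — semi-global (query-global/reference-local) read
  recruitment at inclusive identity 0.85 and query-coverage 0.90
  thresholds, both strands, summarised as reads per million (RPM).
* **Fixture & simulators** — a packaged 55-MAG PNA community whose gene
  content is pinned by a machine-readable constraint file (and
  re-validated on every build), plus seeded simulators for communities
  with known guild structure under completeness-driven gene dropout and
  for reads at a chosen divergence.

## Worked example

```r
library(nitroguild)

community <- build_fixture()        # packaged 55-MAG PNA community
kept      <- qc_filter(community)
cen       <- census(kept)
community_counts(cen)
#> # A tibble: 29 × 2
#>    metric                   count
#>  1 n_genomes                   55
#>  2 nitrate_reducers            23
#>  3 nxr_nar_homolog_carriers    28
#>  4 nitrite_reducers            27
#>  5 nir_and_nar                  7
#>  6 no_reducers                  8
#>  ...
```

23 of 55 genomes can respire nitrate, 27 can respire nitrite, but only 7
can do both — the hallmark of a community of truncated denitrifiers.
Guild calls and the exchange network make the division of labour
explicit:

```r
trophy <- classify_trophy(kept)
guilds <- assign_guilds(cen, trophy)
guilds$genome_id[guilds$denitrifier_complete]
#> [1] "PRO3"
guilds$genome_id[guilds$dnra_complete]
#> [1] "CFX8"  "CFX11" "CLB2"  "CLB3"  "ACD2"

net <- build_exchange_network(derive_edges(cen))
net
#> <ng_exchange_network> 115 edges over 9 intermediates
#> exchange candidates: N2O, NH4+, NO, NO2-
```

A single genome (PRO3) carries a complete denitrification pathway; NO,
N2O, nitrite and ammonium all come out as exchange candidates — produced
by genomes that cannot consume them and vice versa. The two anammox
genomes lacking nirK (AMX2, AMX3) appear among the NO acceptors,
consistent with growth on externally supplied NO. On the auxotrophy
side:

```r
profiles <- trophy_profiles(kept)
profiles$genome_id[profiles$aa_fraction == 1]
#> [1] "PRO4"
providers(profiles, "B12")
#> [1] "AMX1" "AMX2"
```

Only one genome is fully amino-acid prototrophic, and cobalamin can only
be made by two AnAOB — the rest of the community depends on them.

`run_pipeline()` chains all stages and writes a machine-readable
`summary.json` plus a human-readable `summary.txt`, deterministically.
Plot helpers (`plot_census()`, `plot_trophy()`, `autoplot()` on the
network) render the standard figures.

## Vignette

`vignettes/nitroguild-methods.Rmd` describes the model and heuristics,
every tunable threshold with its default, what the fixture and the
simulators do and do not emulate, and the package's design decisions.
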