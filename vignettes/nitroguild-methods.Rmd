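---
title: "Inferring nitrogen-cycle guilds, NOx exchange and auxotrophy from MAG annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nitrogen-cycle guilds, NOx exchange and auxotrophy from MAG annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroguild)
```

## The problem

Partial nitritation/anammox (PNA) communities remove ammonia
autotrophically: aerobic ammonia oxidizers (AOB, `amo` + `hao`) convert
part of the ammonia to nitrite, and anaerobic ammonia oxidizers (AnAOB,
`hzs` + `hdh`) combine the rest with that nitrite into dinitrogen gas.
Around this autotrophic core lives a heterotrophic majority whose
respiratory repertoire over the nitrogen oxides (NOx) is typically
fragmentary. Given draft genomes (MAGs) and their gene annotations,
`nitroguild` reconstructs who can do what: marker-gene census, guild
membership, pathway truncation, the implied cross-feeding of NOx
intermediates, and biosynthetic (amino-acid, B-vitamin) dependencies.

Everything operates on genomic *potential*. A gene's presence licenses a
capability; no claim is made about expression or in-situ activity, and
the exchange network is a hypothesis generator, not a flux model.

## Input filtering

Annotation rows are homology hits. The filter keeps a hit when
`evalue < 1e-5` **and** `bitscore > 60` **and** `identity > 30` (percent),
all strict, matching the usual practice for screening predicted proteins
against curated reference databases. Tables without hit statistics
(presence/absence exports) receive sentinel values that always pass, so
the filter is a no-op for them. Genome quality control keeps a MAG when
`completeness >= 70` percent **or** `contamination == 0`; the second
clause deliberately admits small but clean bins. "Without contamination"
is read as exactly zero, since the clause exists as the counterweight to
the completeness floor. Dereplication of repeated recoveries of one MAG
ranks by completeness, then contamination, then assembly size; the three
criteria have no published precedence, so this package fixes the order
most protective of gene content and documents it here.

## Pathway presence

Pathway definitions are declarative YAML: ordered steps, each listing the
alternative enzymes that catalyse it (`metE`/`metH` for methionine
synthase, for instance); a step is present when any one alternative is
encoded. The presence rule for a pathway is the standard draft-genome
completeness heuristic:

* more than two steps: at most one step may be missing;
* one or two steps: every step is required.

The two-step case sits between the stated "fewer than two" and "more than
two" rules; requiring both steps is the conservative choice and is the
default (`allow_missing_2step = FALSE` can be relaxed). The allowance
exists because a 70–100 % complete MAG loses genes at random: with
per-gene retention p = completeness/100, a five-step pathway survives the
call at p = 0.95 with probability about 0.98 (binomial, at most one
missing), where requiring all steps would drop it to 0.77. The shipped
step lists are a reconstruction at KEGG-module granularity (the exact
lists behind the original analysis are not published) and are deliberately
*pathway-committed*: shared trunk reactions (e.g. shikimate steps) are
represented inside one pathway only, so a pathway can never be called
present on the strength of another pathway's genes. The one retained
exception, `ilvE` shared by the branched-chain amino acids, was checked
against every constrained fixture pattern.

Autotrophy is different: a MAG is called autotrophic when **all** key
genes of at least one carbon-fixation pathway are present (e.g.
`rbcL` + `prkB` for CBB, `acsA` + `acsB` for Wood–Ljungdahl). Key-gene
screening is stricter than the one-missing-step rule on purpose: carbon
fixation is the classification criterion for the autotroph/heterotroph
split, and diagnostic key genes are the accepted way to call it.

## Nitrogen census and guilds

Marker groups are operon-aware. A flag is set when the catalytic core is
present: `amoA+amoB+amoC` (amoDE recorded as accessory), `narG+narH`
(narIJ accessory), all three `hzsABC` subunits, `norB+norC`,
`nrfA+nrfH`, `nirB+nirD`. The catalytic-core default is the weakest
assumption consistent with flag-level reporting; the subunit requirements
live in an editable YAML map. Two things cannot be decided from gene
symbols alone and therefore enter as per-gene metadata labels, expected
in a `label` column of the annotation table: the nosZ clade (I vs II) and
the phylogenetic class of nxr/nar homologs (anammox-type, periplasmic
nxr-like, canonical-NOB). Upstream these labels come from gene trees,
which are outside this package's scope. Multi-copy hao-like genes are
counted (not flagged); their hypothesized activities are modelled only as
optional network edges, disabled by default, because they are hypotheses.

Guild rules are conjunctions of flags: AOB = amo ∧ hao; AnAOB = hzs ∧
hdh; canonical NOB = canonical nxr ∧ autotrophy ∧ ¬amo ∧ ¬hzs; comammox =
amo ∧ any nxr; complete DNRA = (nar ∨ nap) ∧ (nrfHA ∨ nirBD); complete
denitrifier = nitrate reductase ∧ nitrite reductase ∧ NO reductase ∧
nosZ. `community_counts()` reports the per-marker and joint counts; the
`nxr_as_nar` switch adds genomes whose *only* nitrate-reduction candidate
is a periplasmic nxr-like homolog to the nitrate-reducer count, since the
direction of that enzyme family cannot be inferred from sequence.

## The NOx exchange network

A rule table licenses one transformation edge per marker group (amo:
NH3→NH2OH; hao: NH2OH→NO2-; nar/nap: NO3-→NO2-; nirS/nirK: NO2-→NO;
nirBD/nrfHA: NO2-→NH4+; norBC/norZ: NO→N2O; nosZ: N2O→N2; hzs:
NO+NH4+→N2H4; hdh: N2H4→N2). Edge derivation is a pure function of the
census, so community order is irrelevant. The anammox nxrAB is emitted in
both directions: these organisms are the community's plausible nitrate
source, but they also sit on the nitrite side of the equilibrium, and
the package does not adjudicate; the oxidative edge carries a note
identifying it as the AnAOB-attributed nitrate source. Hydrazine is kept
as an explicit intermediate so that anammox appears as NO and NH4+
consumption.

Endpoint labels follow the linear respiratory chain
NO3-→NO2-→NO→N2O→N2 only: each genome's maximal contiguous spans become
labels such as `NO3->NO2` or `NO2->N2O`, `full` for the whole chain,
composites (`NO3->NO2+N2O->N2`) for disjoint spans. DNRA edges are
reported but never folded into the endpoint label.

An intermediate is an **exchange candidate** when at least one genome
produces it without being able to consume it (a donor) and at least one
consumes it without producing it (an acceptor). This is a deliberately
strict, purely set-theoretic criterion: a genome that both produces and
consumes an intermediate is evidence for neither side. One consequence
worth knowing: because anammox nxr is reversible, AnAOB are producers
*and* consumers of nitrate, so nitrate does not appear as an exchange
candidate even though AnAOB are its only net source; NO, N2O, NO2- and
NH4+ do appear on the packaged community.

## Auxotrophy and complementarity

`trophy_profiles()` evaluates all 20 amino-acid and 8 B-vitamin pathways
per genome (glutamate, glutamine, aspartate and asparagine are separate
pathways; the vitamin panel is B1, B2, B3, B5, B6, B7, B9, B12).
`complementarity_report()` partitions the community per compound into
providers and dependents and flags compounds with zero providers as
community-wide auxotrophies. The correlation between a genome's
prototrophy fraction and its completeness or abundance is reported
unthresholded — it is a diagnostic for dropout-driven artefacts, not a
test statistic.

## Read screen

`align_reads()` mirrors the common usearch_global protocol: each read is
aligned end-to-end against each reference (reference-local), both strands,
and recruited when identity ≥ 0.85 and query coverage ≥ 0.90, both
inclusive. Identity is matches over alignment columns, internal gaps
counted — one of several defensible dialects of "percent identity"; it is
the package's documented choice and the thresholds are arguments. The
alignment itself is Biostrings' affine-gap `pairwiseAlignment(type =
"global-local")` (match 2, mismatch −3, gap open 5, extend 2); exact
scores are immaterial because recruitment depends only on the
identity/coverage thresholds. Reads shorter than 45 nt (the conventional
trimming floor) are not aligned. `rpm_summary()` scales per-group hit
counts to reads per million, reporting zero-hit groups explicitly —
an absence (0 RPM) is a result.

## The packaged community and the simulators

The 55-MAG fixture is assembled from three shipped tables (nitrogen
marker annotations with labels, a genome × pathway presence table, a
quality table) and is **constraint-checked on every build**: a YAML file
of 60 machine-readable assertions (marker counts, per-genome gene
presence/absence, guild sets, autotroph set, auxotrophy patterns,
exchange properties) is re-evaluated by `validate_fixture()` through the
package's own census/guild/pathway/network code — an independent path
from the assembly itself — and any violation aborts with the failing
constraint ids. Cells not pinned by any constraint are deterministic
fill (amino acids present except methionine; vitamins present except
biotin and cobalamin) and are tagged `constrained = 0` so that tests
never assert on them. Quality and abundance values are synthetic
placeholders in realistic ranges (four printed abundances are used
verbatim; the most abundant MAG is an AnAOB); abundance-weighted results
are therefore illustrative only.

`simulate_community()` draws genomes from guild templates (AOB, AnAOB,
complete denitrifier, DNRA, a partial-denitrifier filler) plus neutral
accessory genes, then thins every gene independently with retention
probability completeness/100. This emulates incompleteness-driven
dropout only — no operon linkage, no contamination, no misannotation —
so recovery results are an upper bound on real data. Under this model the
expected exact-recovery rate of a guild needing k marker genes is p^k:
at 90 % completeness, 0.9^4 ≈ 0.66 for AOB/AnAOB/DNRA and 0.9^6 ≈ 0.53
for the seven-gene complete denitrifier, giving an expected overall
recovery near 0.73 under the default mix. The acceptance property
therefore uses 0.6 as the documented floor at 90 % completeness, with
exact (1.0) recovery required when dropout is off, and monotonicity
across 70/80/90/100 %. `simulate_reads()` plants substring reads with
uniform substitutions (no indels, no quality profile) on both strands.

## Numerical and design choices

* Determinism everywhere: simulators require a seed; the pipeline's
  output directory is a pure function of inputs and configuration, and a
  rerun is byte-identical (no timestamps in any output).
* Problem sizes in the test-suite properties: 200 simulated genomes per
  completeness level, 100 random read/reference pairs of 50–200 nt for
  the alignment oracle, exhaustive 2^n enumeration of pathway patterns up
  to n = 10. These sizes make the binomial expectations above sharp
  enough to test against while keeping the default suite fast.
* Ties in dereplication fall back to input order, making the selection
  deterministic for identical metrics.
* Gene symbols are case-normalized (K-numbers preserved); unknown symbols
  in annotation tables are ignored with a note, not an error, because
  annotation vocabularies always exceed the definition files.
* Degenerate inputs: empty annotation tables yield empty (typed) results
  at every stage; an empty reference set or a zero read total are errors.

## Known limitations

* Pathway step lists are a curated reconstruction; swapping in alternative
  definitions is supported (all definitions are data files) and changes
  the auxotrophy matrix accordingly.
* nosZ clades and nxr classes must be supplied as labels; the package
  does not build gene trees.
* The exchange network ignores stoichiometry, kinetics, and spatial
  structure; "exchange candidate" is a necessary-condition screen.
* The read screen's identity definition approximates, but is not
  guaranteed to equal, the cited tool's internal formula in gapped
  corner cases.
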