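---
title: "Methods: semantic-graph drug repositioning"
author: "repograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic-graph drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repograph)
```

`repograph` infers candidate indications for approved small molecules by
integrating gene–disease evidence into a typed semantic graph, mining a
four-node drug–protein–gene–disease pattern, and pruning the matches
through pharmacological plausibility filters. This vignette describes
the model, the parameters that matter, the numerical choices, what the
synthetic fixtures do and do not emulate, and the known limitations.

## Evidence integration model

Evidence arrives as per-source tables of (gene, MeSH disease) pairs.
Sources differ enormously in curation quality, so each source $E$ is
scored by a Bayesian log-likelihood score against a gold-standard
source $G$:

$$\mathrm{LLS}(E) = \log\frac{P(L\mid E)/\neg P(L\mid E)}{P(L)/\neg P(L)},$$

estimated from four counts: the source's pairs inside and outside $G$,
the size of $G$, and the non-gold pairs of the *universe*. The universe
defaults to the union of all captured pairs across sources
(`ranking_config(universe = "captured")`); a Cartesian gene × disease
alternative is exposed but not default, because the captured union is
the only population all sources demonstrably sampled from. The log base
(natural by default) rescales but never reorders sources.

Two degenerate-count policies are provided: `error` (default for
interactive use — a zero cell usually means a malformed fixture) and
`pseudocount`, which adds 0.5 to each of the four counts; the pipeline
default is `pseudocount` because a legitimately disjoint source should
be down-weighted, not fatal.

The gold standard itself is chosen by round-robin: every source takes a
turn as gold, every other source is ranked by LLS (1 = best), and the
source with the lowest average rank wins, ties broken by id order. This
mirrors how a consistently well-ranked curated source earns the
reference role without an external arbiter.

Per-association confidences combine by the weighted sum
$\mathrm{WS} = \sum_{i} C_i / D^{\,i-1}$ over the LLS values of the
sources containing the pair, sorted descending. $D$ (> 1, default 5)
models between-source dependence: curated databases seed one another, so
a second confirmation is worth much less than the first. `tune_D()`
selects $D$ by ROC AUC with the gold source held out of the scoring
inputs and used as the positive label set; the default grid is 1.5–8 in
steps of 0.5 (the weighted sum requires $D > 1$, so 1.0 is not a valid
candidate). WS is bounded by $C_1 \le \mathrm{WS} < C_1 D/(D-1)$.

Two edge cases deserve note. Only sources with positive LLS enter the
weighted sums — a source at or below the prior carries no evidence of
linkage — and a pair supported by no informative source falls back to
its best (non-positive) LLS so that every captured pair receives a
score. With a single source the universe coincides with that source's
pairs and its LLS is identically zero: every WS is then equal, and the
min–max normalisation to the [0, 1] association score degenerates (all
scores 1, with a warning). The normalisation itself is rank-preserving
by construction; Spearman correlation between WS and the association
score is exactly 1 whenever the range is non-degenerate. The method for
mapping raw WS onto the unit interval is a design choice; min–max was
chosen over a sigmoid because it is parameter-free and bounded.

Directionality (loss- vs gain-of-function) is taken as the consensus of
the contributing sources: one annotated direction propagates,
conflicting annotations collapse to `unknown`. The conservative collapse
avoids triggering the mechanism-contradiction filter on disputed
annotations.

## The semantic graph

Nodes are typed (`Small_Molecule`, `Protein`, `Gene`, `Common_Disease`,
`Rare_Disease`) and edges are drawn from a closed relation set with
endpoint-type compatibility enforced by a validator. Attributes are
stored as text and parsed lazily, so unknown attributes survive TSV
round-trips; numeric accessors parse on demand. Unconnected nodes are
dropped at load — the graph is defined over connected entities, and the
hierarchy (`is_a`) edges keep un-annotated diseases connected so that
area statistics still see them.

Rare diseases carrying a synonymous MeSH UI are merged with the MeSH
node of that UI: the merged node stays a `Rare_Disease`, inherits the
tree numbers and heading it lacked, and takes over all edges. Two rare
diseases claiming one UI merge into the first by id order, with a
warning. Graph operations return new values rather than mutating shared
inputs.

Conflicting measurements (several activity values for one drug–protein
pair) are kept as parallel `binds_to` edges; each yields its own mapping
during mining, and deduplication later resolves to the best-scoring
path. No merge rule is imposed because none is defensible without
knowing the assay context.

## MeSH similarity

The similarity is the path-based measure
$\mathrm{Sim} = 1 - \log(\mathrm{Dist})/\log(2 \cdot depth)$ in the
Leacock–Chodorow family. Two conventions had to be fixed: the distance
unit and the depth. Node-count distances (identical = 1, parent–child
= 2) with depth 10 reproduce all three operating thresholds used
downstream — 0.768 (parent–child, the side-effect equivalence
threshold), 0.633 (two-node, the validation threshold) and 0.231
(nine-node, the relaxed bound) — simultaneously; this calibration is
over-determined (two parameters, three values) and no neighbouring
depth satisfies it, which the acceptance tests assert. The log base
cancels algebraically. Both parameters remain configurable via
`sim_params()`.

Concepts with several tree numbers take the minimum distance over all
position pairs (synonymous diseases sit in multiple branches of the
taxonomy). Pairs sharing no prefix are unreachable and score 0; no
virtual root joins the top-level branches, because a virtual root would
make all diseases weakly similar and pollute the side-effect filter.
Scores are clamped below at 0 for distances beyond $2 \cdot depth$.
Printed thresholds are matched by truncation to three decimals
(0.76862 → 0.768); tests compare at $|\Delta| \le 0.001$.

## Therapeutic-area scores

A disease belongs to every top-level code prefixing one of its tree
numbers, duplicated across areas. Coverage is the fraction of an area's
diseases with at least one `involved_in` (gene knowledge) or
`has_indication` (marketed treatment) edge. The unmet score is

$$\mathrm{TAU} = (1 - P(\mathrm{Dr\text{-}D}))\cdot P(\mathrm{G\text{-}D})
  \cdot f(|ta|),$$

where the size term $f$ defaults to $|ta|/\mathrm{MAX}$ — increasing in
area size and equal to 1 for the largest area. The defining contract
(small areas near 0; large, knowledge-rich, under-drugged areas near 1)
forces a factor of this shape; two alternative readings
(`"complement"` = $1 - |ta|/\mathrm{MAX}$ and `"reciprocal"` =
$1 - 1/(\mathrm{MAX}\cdot|ta|)$) are kept for sensitivity analysis
because the size term admits more than one algebraic transcription. The
richness score is $\mathrm{RTA} = P(\mathrm{Dr\text{-}D}) \cdot
P(\mathrm{G\text{-}D})$. Areas qualify for prioritisation only when
their share of total memberships strictly exceeds $1/n_\text{areas}$
(3.448 % with the full MeSH's 29 disease areas); the denominator counts
memberships with duplication.

## Mining and scoring

`find_mappings()` enumerates every
drug → protein → gene → disease path whose drug is an approved small
molecule (`group` contains `approved`; multi-group drugs such as
approved+withdrawn qualify). The enumeration is a three-way typed-edge
join, exact and exhaustive — the test suite proves multiset equality
against a naive four-tuple oracle on hundreds of random graphs,
including parallel-edge multiplicity.

Activities in nM (IC50, Ki, Kd, Potency) are normalised as
$1 - 0.1\log_{10} v$, clamped to [0, 1]: 1 nM → 1.0, 100 nM → 0.8,
≥ 10 µM-range values decay toward 0. The clamp handles the extreme
upper tail of recorded activities (up to $10^{19}$ nM) without letting
a scale factor tuned to the tail flatten the pharmacologically relevant
low-nM range. A `binds_to` edge without any activity (interaction
databases record binding without potency) scores 0.8 — on the
normalised scale, equivalent to 100 nM — so such mappings are neither
lost nor over-weighted. The mapping score is the arithmetic mean of
normalised activity and association score; deduplication keeps the
best-scoring mapping per (drug, disease), ties broken lexicographically
and deterministically. Known indications are *not* excluded from the
output: rediscovering them is how the approach is validated.

## Filter cascade

Three removal predicates, each depending only on the mapping itself:

* **Side effects** — removed iff the drug has a recorded side effect on
  the same disease node or on any disease with Sim ≥ ET (default
  0.768, i.e. one node away). Rare diseases without a MeSH UI
  participate by exact node matching only. Removal is monotone
  non-increasing in ET, and ET > 1 restricts to exact matches.
* **Mechanism contradiction** — removed iff an inhibitory action meets
  a LoF association or an activating action meets a GoF association.
  The action-term classification is not canonical; the shipped sets
  (antagonist/inhibitor/blocker/negative allosteric modulator/inverse
  agonist vs agonist/activator/positive allosteric modulator/partial
  agonist/opener/inducer) are configuration, matched
  case-insensitively, and unrecognised terms are kept and reported for
  triage. Missing annotations never remove a mapping.
* **ADME genes** — removed iff the mapping's gene symbol is in the
  configured list (case-insensitive); an empty list is a warning no-op.

Because the predicates are mapping-local, the final kept set is
invariant to stage order; per-stage counts are not, so `run_cascade()`
reports both sequential counts (removals from the shrinking survivor
set) and independent counts (each predicate on the full input), making
overlap between criteria visible and the cascade auditable.

## Validation

A known (drug, disease) indication counts as identified when the same
drug has an inferred indication within Sim ≥ 0.633 of it; an exact
disease match counts regardless of threshold (which also covers rare
diseases outside the MeSH forest), so matching at a threshold above 1
degenerates to exact set intersection. Knowns whose drug produced no
inference at all are excluded from the recall denominator (both
denominators are reported). The ROC labels every inferred indication
positive iff it matches some known at the threshold and computes AUC by
the Mann–Whitney rank statistic with midranks; this labelling is the
only one available from the method's own outputs, and the AUC is
invariant under monotone transforms of the scores (cross-checked
against an independent ROC implementation in the tests).

## Synthetic fixtures: what they emulate

`fixture_spec()` defaults define the generator's standard study
conditions: three top-level disease areas as depth-3 ternary trees (120
diseases), 60 genes, 60 true gene–disease pairs, four sources with
graduated reliabilities (0.9, 0.8, 0.6, 0.4) and noise rates (0.05,
0.1, 0.2, 0.3), 15 background drugs with two targets each (80 %
approved), activities log-uniform over 1–10⁶ nM, five planted
indication chains (1 nM binding through a dedicated gene), side-effect
traps at node distances 2, 2 and 3, one planted mechanism contradiction
and one ADME hit. These sizes exercise every code path — multi-area
membership, rare-disease merging, all three filters — while keeping a
full pipeline run under a second; tests that need different shapes
(e.g. three sources at reliabilities 0.9/0.6/0.3 for order-recovery, or
trap-free fixtures for clean-chain recovery) set them explicitly.

A single integer seed drives one RNG stream (R's default generator,
reproducible across platforms for a given R version); the same spec is
byte-identical across runs, and generation restores the caller's RNG
state. A truth manifest lists every planted structure and per-source
gold membership, enabling parameter-recovery tests.

What the fixtures do **not** emulate: real marginals (hundreds of
thousands of associations), the extreme skew of real source sizes,
literature-mined noise correlated between sources, multi-target
polypharmacology at scale, or a realistically deep (11-level) MeSH
forest. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted signal under controlled noise —
not predictive performance on real pharmacological data.

## Numerical and determinism choices

Problem sizes in the test suite are deliberately modest: oracle
equivalence runs on 100 random graphs of up to ~200 nodes, order
recovery on 100 seeds of a 3-source/60-gold-pair design, and end-to-end
checks on the default 120-disease bundle. Weighted sums agree with a
loop oracle to 1e-12; similarity thresholds are asserted after
truncation to three decimals. All outputs carry deterministic sort
orders (mappings by drug, disease, score, edge ids; ties by
lexicographic protein/gene/edge), so reruns are byte-identical — the
run manifest deliberately excludes timestamps.

## Known limitations

* The pipeline consumes pre-extracted tables; no retrieval from live
  databases, no text mining, no identifier-mapping construction.
* Storage is in-memory with TSV/GraphML export; there is no persistent
  graph-database backend.
* The action-term classification and the ADME list are user-editable
  inputs, and the contradiction-filter counts are sensitive to them.
* The matcher is specialised to the four-node pattern; it is not a
  generic subgraph-pattern language.
* Rare diseases without a synonymous MeSH UI are invisible to
  similarity-based filtering and matching (exact-node logic only).
* No burden-of-disease weighting, cellular-location or permeability
  filtering; these are natural extensions outside the current scope.
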