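---
title: "Methods: niche breadth, nonnative taxa and microdiversity in multi-habitat metacommunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche breadth, nonnative taxa and microdiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasink)
```

## The problem

Microbial communities in connected landscapes — lakes, soils, sediments,
plant surfaces, animal guts within one ecosystem — constantly exchange
organisms. Under source–sink dynamics, a taxon well adapted to one habitat
(its source) disperses into others where it persists at low abundance
without establishing. `metasink` asks three questions of a taxon-by-sample
count table spanning several habitats:

1. Which (taxon, habitat) pairs look like dispersal-derived, *putative
   nonnative* occurrences?
2. How much taxonomic and functional diversity do those occurrences
   contribute, relative to removing an equivalent number of random taxa?
3. Do taxa that span more habitats harbour more fine-scale genetic
   variation (microdiversity)?

Because real multi-habitat surveys require heavy upstream processing, the
package ships a seeded synthetic metacommunity generator with planted
ground truth, and every stage of the pipeline is validated against it.

## Niche breadth and the classification rule

For taxon $j$ in habitat $H$ with samples $i = 1,\dots,N_H$, the
within-habitat proportions are $P_{ij} = n_{ij} / \sum_i n_{ij}$ and
Levins' niche breadth is

$$B_j = \frac{1}{\sum_{i=1}^{N_H} P_{ij}^2},$$

the inverse Simpson concentration of the taxon's distribution over the
habitat's communities: $B_j = N_H$ for a perfectly even taxon, $B_j = 1$
for single-sample occupancy. Because habitats differ in sample number,
breadths are normalized within each habitat by the maximal breadth there,
so the broadest taxon of every habitat scores exactly 1.

A present pair $(j, H)$ is flagged putative nonnative only when all three
hold, with strict inequalities (ties fail):

* **abundance**: mean relative abundance of $j$ in $H$ is below its
  maximum over the other habitats where it is present;
* **breadth, cross-habitat**: normalized breadth of $j$ in $H$ is below
  its maximum elsewhere;
* **breadth, within-habitat**: normalized breadth of $j$ in $H$ is below
  a quantile (default: the median) of normalized breadths over the
  habitat's present taxa.

Design choices worth making explicit, since the underlying verbal rule
admits several readings:

* "Lower than in other habitats" is operationalized as "strictly below
  the taxon's maximum over other habitats". Under source–sink logic a
  taxon should be flaggable in *every* sink; a strict-minimum reading
  would allow at most one nonnative habitat per taxon.
* The cross-habitat breadth comparison uses *normalized* breadth, because
  raw breadths are bounded by habitat sample numbers and are not
  comparable across habitats of unequal size.
* The within-habitat reference ("other species in the habitat") is a
  configurable quantile of the habitat's normalized breadths, default
  0.5. Raising the quantile weakly enlarges the flagged set; this
  monotonicity is property-tested.
* Taxa detected in a single habitat are exempt: the cross-habitat
  criteria are undefined for them, and the conjunction is therefore
  false.
* $P_{ij}$ is normalized per taxon across samples *within* one habitat,
  giving one breadth per (taxon, habitat). The alternative — one global
  breadth across all samples — would make the within-habitat
  normalization step meaningless.

Breadth is computed on rarefied counts. Rarefaction subsamples each
sample without replacement to a common depth, by default the minimum
column sum within each habitat (`"per-habitat-min"`); samples below the
target are dropped with a warning, a conventional handling the data model
does not otherwise prescribe. A single seeded draw is used rather than an
average over repeated draws. "Detected" defaults to count ≥ 1 after
rarefaction; the threshold is configurable because no detection floor is
inherent in the model. Absence is distinct from minimal breadth: a taxon
absent from a habitat has *no* breadth there, not $B = 1$.

## Removal simulations

The contribution of flagged taxa is quantified by contrast, per habitat:

* **targeted removal** zeroes every taxon flagged nonnative in $H$ from
  all of $H$'s samples;
* **random removal** removes, in each of $R$ replicates (default 100), a
  uniform random subset of equal size from the habitat's detected-taxon
  pool.

Richness (taxonomic: count of taxa with reads; functional: count of
distinct KO/COG-style identifiers carried by present members) is computed
per sample under each scenario, normalized by the habitat's maximum
observed richness, and the three scenario pairs are contrasted with
paired t-tests, Benjamini–Hochberg adjusted across the whole habitat ×
comparison (× metric) family. Degenerate contrasts (no flagged taxa, so
targeted ≡ observed) are reported as `no_difference` rather than tested;
habitats with fewer than three samples are skipped with a warning.

Two deliberate choices: the random pool is the habitat's own detected
metacommunity, not the global taxon list — "an equivalent number of taxa"
is matched where the removal happens, and the global alternative would
change the expected richness drop; and removal does not trigger
re-rarefaction, since richness is count-based and renormalizing after
deletion would mix removal effects with resampling noise.

## Functional redundancy

For a function $f$ carried by a set $C_f$ of present members, the
redundancy index is a Rao-type quadratic entropy restricted to carriers:

$$\mathrm{FR}(f) = \sum_{i \ne j \in C_f} p_i\, p_j\, d_{ij},$$

with $p$ the relative abundances over the *whole* community and $d_{ij}$
patristic distance normalized by the tree's maximum pairwise distance.
FR is zero with at most one carrier, bounded by 1, invariant to taxon
relabeling, and grows when a function's carriers are abundant and
phylogenetically dispersed — the monotone behaviour expected of a
"phylogenetic distribution of function carriers" index. Keeping $p$ on the
whole community (rather than renormalizing over carriers) means that
losing carriers genuinely lowers FR. Published redundancy indices of this
family differ in detail; equivalence with any specific one is not claimed,
and the brute-force double sum serves as the in-package oracle.
Cycle-level summaries average FR over a named function set (C, N, P, S),
counting carrier-free functions as zeros.

## Microdiversity

ASVs are clustered into OTUs by greedy, abundance-sorted centroid
clustering at 97% identity: sequences in decreasing abundance order (ties
by id, so the result is independent of file order) join the
earliest-created centroid within the threshold or found a new one.
Pairwise identity is matches / alignment columns under global alignment
with match 1, mismatch 0 and a linear gap penalty of 1 per gap column.
Because co-optimal alignments can disagree on column counts, the package
fixes a deterministic rule — among maximum-score alignments, take the one
with the most matches — which is computable by a single scalarized dynamic
program without traceback. A shared 8-mer prefilter (as in production
clustering tools) limits which centroids are aligned; it is applied only
when the q-gram bound makes it safe for non-repetitive sequences, and
short or low-threshold instances automatically fall back to aligning
every centroid.

Per OTU, microdiversity is the intra-OTU ASV count; per ASV, the
nearest-taxon distance (patristic, or 1 − identity when no tree is
available) is minus-log-transformed into "closeness", with zero distances
floored to half the smallest positive distance before the log (natural
log by default; base 10 available). An OTU's habitat-occurrence level is
the maximum over its members — the aggregation rule is a package choice.
Occurrence levels are compared with all pairwise Welch t-tests
(BH-adjusted, compact letter display) plus a Spearman rank correlation
between occurrence and each metric.

## The synthetic generator

`simulate_metacommunity()` emulates the statistical structure the
pipeline targets, not any particular survey: habitat-exclusive natives
(log-normal weights, $\sigma = 2$, per-sample occupancy 0.6), regional
generalists present everywhere (occupancy 0.9, never labelled nonnative
— broadly adapted lineages are "native everywhere"), and habitat-level
colonization: each native colonizes each foreign habitat with probability
$m = 0.15$, appearing in sink samples with occupancy 0.15 at $\delta =
0.05$ times its home weight. Counts are one multinomial draw of `depth`
reads per sample, so column sums are exact. Colonization is planted at
the habitat level (then thinned per sample) because the classification
unit is the (taxon, habitat) pair. Dispersal parameters are chosen for
testability — they produce colonists that are detectable yet clearly
rarer and patchier than natives — not calibrated to any measured system,
and the log-normal weight distribution is a standard rank-abundance
shape adopted in the absence of a prescribed one.

`simulate_sequences()` gives each lineage a random ancestor and
$1 + \mathrm{Poisson}(0.8 \times \text{occurrence})$ variants at ≤ 2%
divergence, so all variants of a lineage fall inside one 97% OTU by
construction and variant counts rise with habitat occurrence — the planted
microdiversity signal. Inter-ASV *closeness* is not separately inflated
with occurrence, so only the intra-OTU count carries the planted trend.
`simulate_function_table()` draws Poisson repertoires over a function
universe and reserves a fraction (default 0.3) of each cycle set
exclusively for colonist taxa, so targeted removal demonstrably erodes
cycle-related functional diversity.

What passing tests on this generator do *not* show: robustness to
compositional artefacts, chimeras, relic DNA, primer bias, taxonomic
mis-binning, or ecological drift — none of which the generator emulates.
The generator defines sufficiency of the *algorithms*, not field validity.

## Validation conditions and numerical choices

* Parameter recovery runs the full default configuration (4 habitats ×
  30 samples, 250 natives/habitat, 50 generalists, depth 10 000) over 10
  simulation seeds, requiring mean precision and recall ≥ 0.7 over the
  evaluable universe: pairs whose taxon is detected in that habitat and
  in ≥ 2 habitats overall. Planted colonists never detected in their sink
  cannot be called and are excluded from the recall denominator. A
  companion check verifies recovery degrades when colonists approach
  native abundance ($\delta = 0.5$).
* The removal-direction check uses a planted condition in which flagged
  colonists have *above*-pool-average per-sample presence (occupancy 0.9,
  $\delta = 0.5$, 4 × 20 samples, 150 natives/habitat) and
  colonist-exclusive cycle functions; under it, targeted removal
  depresses taxonomic and functional richness significantly more than
  random removal. With the default rare-colonist parameters the direction
  reverses — rare, patchy taxa cost a sample little richness — which is
  itself informative about what the contrast measures.
* The microdiversity check uses 6 habitats × 10 samples × 40 natives
  (260 lineages, ~600–700 ASVs), sized so greedy clustering completes in
  seconds; a label permutation control confirms the occurrence
  association vanishes under the null.
* Oracles: Levins breadth, the FR double sum, per-replicate random
  removal richness, global-alignment identity, and greedy cluster
  membership are each checked against independent naive implementations
  on dozens of randomized small instances; small instances keep the
  clustering prefilter inactive, so the exact code path is exercised.
* All randomness flows from explicit integer seeds through R's default
  generator; per-habitat random-removal streams are offset by the
  habitat's rank in sorted order, so results are invariant to sample and
  habitat ordering. Identical seed and configuration give byte-identical
  TSV outputs across all CLI subcommands.

## Limitations

* The classifier is a screening rule: it cannot distinguish dispersal
  from other causes of "rare here, common there" patterns (seasonality,
  succession, relic DNA). Corroboration by variant-level source tracking
  or activity measurements lies outside the package's scope.
* The FR index is one member of a family; absolute values are not
  comparable across studies using different redundancy definitions.
* Greedy single-linkage-to-centroid clustering is order-dependent by
  construction (abundance order is the published convention); it is not a
  globally optimal clustering.
* With very uneven habitat sample numbers, normalized breadth only
  partially removes the $N_H$ dependence; interpreting cross-habitat
  breadth comparisons still assumes roughly comparable sampling effort.
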