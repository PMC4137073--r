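---
title: "Methods: weighted taxonomic distance and community pathway analysis"
author: "epgdbkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted taxonomic distance and community pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgdbkit)
```

# The problem

Metabolic pathways predicted from environmental (community) sequence data
inherit a hazard that single-genome predictions do not: the coding
sequences supporting a pathway may come from taxa far outside the range
in which that pathway has ever been observed. A plant-hormone pathway
"predicted" in a bacterioplankton sample is more plausibly an artifact of
promiscuous enzyme annotations than a discovery. This package quantifies
that hazard with a weighted taxonomic distance (WTD), and surrounds it
with the routine operations a community-pathway analysis needs: table QC
and normalization, presence/absence set analyses across samples and
nucleic-acid fractions, distributed-pathway detection, and performance
scoring against gold standards.

# The weighted taxonomic distance

## Model

Work on a rooted taxonomy $T$ (NCBI-style). For a pathway $p$:

* $x_{obs}$ — the lowest common ancestor (LCA) of the taxonomic
  annotations of $p$'s coding sequences in one sample
  (`observed_taxon_for_pathway()`);
* $TR(p)$ — the expected taxonomic range, the curated set of taxa in
  which $p$ has been observed (`expected_range_map()`).

For each $x_{exp} \in TR(p)$, the unique tree path
$P(x_{exp}, x_{obs})$ through their LCA is weighted edge-wise:

$$D(x_{exp}, x_{obs}) \;=\; s \cdot \sum_{(a,b)\, \in\, P} w^{-d(a)},
\qquad d(\mathrm{root}) = 0,$$

where $d(a)$ is the depth of the edge's shallower endpoint, $w$ is the
geometric base (`weight_base`, default 2), and the sign $s$ is $+1$ when
$x_{exp}$ is an ancestor-or-self of $x_{obs}$ (the observed lineage
descends from the expected range) and $-1$ otherwise. The pathway-level
distance (`pathway_wtd()`) is the minimum nonnegative $D$ if any
expected taxon contains $x_{obs}$, else the maximum (closest to zero)
negative $D$; among exactly tied winners the lexicographically smallest
expected label is reported, for determinism.

## Properties and numerical behaviour

* **Root steps dominate.** Along any descending segment of a path (at
  most one edge per depth), an edge at depth $d$ strictly outweighs all
  edges below it: $\sum_{k>d} w^{-k} < w^{-d}$ for $w \ge 2$. Note this
  holds per segment, not across the two sides of a divergent path: a
  V-shaped path may carry one edge per depth on *each* side, and
  $2\sum_{k>d}2^{-k} \to 2^{1-d}$ can exceed $2^{-d}$. The qualitative
  claim — near-root steps represent larger evolutionary jumps than
  near-tip steps — is a statement about lineages, and it is the
  per-segment form that the package tests.
* **Bounds.** A nonnegative (descending) distance is a single geometric
  series and is bounded by $w/(w-1)$ ($= 2$ at the default base). A
  divergent path stacks one series per side of the LCA, so the magnitude
  bound is $2w/(w-1)$ ($= 4$). Distances are exact floating-point sums of
  powers of two at the default base; no tolerance is needed.
* **Scale invariance.** Disagreement classes are rank statistics and the
  sign is containment, so rescaling all edge weights by a positive
  constant changes neither.
* The default base 2 is the simplest scheme with the dominance property;
  it is exposed as `weight_base` for sensitivity analysis, as is
  `ranked_only` (depth counted over canonically ranked ancestors only,
  for taxonomies rich in unranked internal nodes — the default counts
  every node, since real NCBI chains interleave unranked nodes
  irregularly and dropping them discards resolution).

## Disagreement classes

Per sample, records with positive WTD get class **None**; under the
default `zero_is_none = TRUE`, so do exact zeros (a zero means the
observed LCA *is* an expected taxon — perfect agreement; the alternative
policy, zeros entering the quartile pool, is available for the stricter
reading of "less than or equal to zero"). Records without an expected
range cannot disagree and also report **None** with a missing distance.

The strictly negative distances of a sample, sorted ascending (most
negative first, $n$ values), are partitioned by rank:

* positions $1 \dots \lfloor n/4 \rfloor$ — **High** (lowest quartile);
* up to $\lfloor n/2 \rfloor$ — **Medium** (second quartile);
* the rest — **Low** (above the median).

Floor-based bins are used because they reproduce the defining phrase
"greater than the median" exactly and handle the degenerate cases
coherently: with a single negative value no *strictly lower* quartile
exists, so it is classed Low rather than High (a ceiling-based bin
boundary would do the opposite). Ties take the class of the first
occupied position of their value, so a run spanning a boundary uniformly
receives the more severe class. The rank rule avoids every interpolation
ambiguity of numeric quantile definitions.

For reporting, matched expected taxa are collapsed onto high-level groups
(root, cellular organisms, archaea, bacteria, eukaryotes, animals, fungi,
plants, other — with "prokaryotes" available as a user-supplied anchor,
since no such node exists in the NCBI hierarchy) by walking the ancestor
chain tip-first and taking the deepest anchor (`collapse_to_group()`).

## Name resolution

Annotation strings are names, not taxon identifiers, so resolution
(`resolve_taxa()`) prefers scientific names, accepts synonyms, and
resolves homonyms only through a user-supplied anchor whose clade must
contain the candidate — otherwise an explicit ambiguity error. Labels
matching nothing are skipped with a warning and counted; an all-
unresolvable CDS list is a domain error rather than a silent NA.

# Table QC and normalization

The QC rule keeps records with **at least 10** mapped CDS per sample
(`qc_filter()`), treating each sample independently. The boundary is
deliberately inclusive at 10: of the three natural phrasings ("more than
ten", "nine or fewer removed", "less than 10 removed") two place ten on
the surviving side. The threshold is a parameter (`min_cds`).

Normalization (`normalize_counts()`) divides each record's CDS count by
the sample's **total predicted ORFs** and reports percentages. The
denominator is total predicted (not unannotated) ORFs — the quantity that
measures sequencing effort; an alternative denominator vector can be
supplied.

# Set analyses

`fraction_partition()` splits one depth's DNA and RNA pathway sets into
DNA-only / shared / RNA-only; `union_fractions_over_depths()` unions the
per-depth partitions component-wise, so a pathway classified differently
at different depths appears in several components by design (component
sizes may exceed the overall union — they answer "was it ever DNA-only
anywhere", which is the question the per-depth analysis asks).
`kway_regions()` assigns every pathway in the union of 2–6 labelled sets
to its exact membership pattern; all $2^k - 1$ patterns are reported
(empty ones included) in deterministic pattern order.

# Distributed metabolic pathways

A pathway predicted from a combined multi-genome database but from none
of the individual genomes is a candidate for distributed metabolism
(`distributed_candidates()`: combined minus the union of individuals).
Candidates pass the plausibility filter (`plausibility_filter()`) when at
least 75 % of the pathway's reactions carry CDS **from both** members of
the genome pair — a closed boundary, so exactly 75 % qualifies. The
per-reaction reading (a reaction counts only when both genomes contribute
to *it*) is the default because it is the literal sense of "reactions
with CDS from both taxa"; a looser per-pathway mode (75 % of reactions
covered by anyone, both genomes contributing somewhere) is available via
`coverage_mode`. Pairwise combinations are the default unit of analysis;
candidates lacking coverage data are reported implausible with a warning
rather than dropped.

# Performance metrics

`confusion_table()` labels every pathway of an explicit universe as
TP/FP/FN/TN; the universe is a required input because true negatives are
undefined without one (typically: all pathway identifiers of the
reference catalogue in use). `metric_suite()` computes sensitivity,
specificity, precision, accuracy, F-measure and the Matthews correlation
coefficient. Zero-denominator metrics are `NA` (not 0 — an undefined
precision is not a bad precision); MCC with a zero marginal returns 0
under the common convention, flagged via an attribute.

# Synthetic communities

The generators (`make_taxonomy()`, `make_community()`,
`sample_pathway_table()`, `collector_curve()`, `make_expected_ranges()`)
emulate the statistical structure of simulated-metagenome experiments at
the level of CDS observations, not reads: read simulation, ORF calling
and homology annotation are upstream of this package, so the test surface
is the behaviour of the downstream methods — recovery monotonicity,
sign ground truth, detection of engineered split pathways — not absolute
recovery values of any sequencing pipeline. Consequences: a pathway is
"recovered" when at least one of its CDS is drawn (no pathway-calling
evidence rules), and coverage effects enter through multinomial
subsampling with replacement, weighted by genome abundance.

Defaults encode the study conditions the generators emulate: 10 genomes;
abundance weight vector $(s, 1, \dots, 1)$ with $s = 1$ (even) or
$s = 20$ (one genome in 20-fold excess); 40 pathways per genome of which
30 % are drawn from a shared core (core-then-accessory accumulation gives
the collector's-curve shape); 4–8 reactions per pathway with 1–4 CDS
copies per reaction; subsampling fractions
$\{1/20, 1/10, 3/20, 1/5, 2/5, 3/5, 4/5, 1\}$. Engineered split pathways
carry 8 reactions with one-reaction offsets — genome 1 misses the last
reaction, genome 2 the first — so neither genome is complete, their union
is, and both contribute CDS to exactly $6/8 = 0.75$ of the reactions,
probing the closed plausibility boundary exactly.

`make_expected_ranges()` guarantees sign ground truth by construction:
correct ranges are drawn from the ancestor chain of the carrier genomes'
LCA (an ancestor of the full-carrier LCA is an ancestor of every
carrier-subset LCA, so the WTD is nonnegative under any subsampling),
while misassigned ranges are drawn from decoy clades containing no genome
(never an ancestor of any observed LCA, so the WTD is strictly negative).
The community taxonomy carries three decoy leaves by default for this
purpose.

Every generator saves and restores the global RNG state
(`withr::with_seed`), so outputs are pure functions of seed and
parameters.

# Problem sizes

The validation suite runs at deliberately modest scale, chosen to make
brute-force oracles exhaustive rather than to stress throughput: random
taxonomies of ≤ 200 nodes (100 trees for the WTD oracle comparison),
class-oracle sweeps over sample sizes 1–50, 1000 random confusion tables
over a 100-pathway universe, and collector's curves with 50 replicates
per fraction over ~300-pathway communities. At these sizes the entire
suite completes in under a minute on one core.

# Limitations

* The WTD weighting base is a modelling choice; only its dominance
  property, not its value, is principled. Comparisons of absolute
  distances across studies using different bases are meaningless —
  classes, being rank-based, are comparable.
* Expected taxonomic ranges are consumed as curated data; pathways
  missing from the range map cannot disagree and are reported as such
  rather than guessed.
* The synthetic generators validate method behaviour, not pipeline
  accuracy: they contain no annotation noise model, no read-length
  effects, and no pathway-calling evidence rules, so passing tests say
  nothing about the upstream prediction quality on real data.
* Set-difference distributed-pathway detection is quadratic in practice
  (pairwise combinations) and is not intended for large genome
  collections.
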