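# epgdbkit

Pathway-centric analysis of microbial communities builds *environmental
pathway/genome databases* (ePGDBs): metabolic pathways predicted from
metagenomic or metatranscriptomic coding sequences rather than from a
single genome. Because community sequence pools annotations from many
taxa, predicted pathways need downstream scrutiny: a pathway can be called
from coding sequences whose taxonomy is nowhere near the taxa in which
that pathway has actually been observed, and pathways can emerge from
reactions *distributed* across several genomes. `epgdbkit` provides that
downstream layer for anyone working with community pathway predictions —
it does not re-implement pathway inference itself.

## What it computes

**Weighted taxonomic distance (WTD).** For a predicted pathway *p*, let
*x*<sub>obs</sub> be the lowest common ancestor (LCA) of the taxonomic
annotations of the pathway's coding sequences, and let TR(*p*) be the
pathway's expected taxonomic range (the set of taxa in which curators have
observed it). For each *x*<sub>exp</sub> ∈ TR(*p*) the distance is summed
over the edges of the unique tree path *P*(*x*<sub>exp</sub>,
*x*<sub>obs</sub>) on the taxonomy:

> D(x_exp, x_obs) = ± Σ<sub>(a,b) ∈ P</sub> 2<sup>−d(a)</sup>

where *d(a)* is the depth of the shallower endpoint of the edge
(*d*(root) = 0), so steps near the root dominate steps near the tips. The
sign is positive (or zero) when *x*<sub>exp</sub> is an ancestor-or-self
of *x*<sub>obs</sub> — the observed lineage descends from the expected
range — and negative otherwise. The reported distance is the minimum
nonnegative one if any expected taxon contains the observed LCA, else the
maximum (closest to zero) negative one. Per sample, negative distances
are partitioned by rank into disagreement classes: **Low** (above the
median), **Medium** (second quartile), **High** (lowest quartile — the
strongest candidates for spurious predictions); positive distances get
**None**.

Around the WTD sit:

- pathway-table QC (drop records with fewer than 10 mapped CDS) and
  normalization to per-sample ORF percentages;
- k-way presence/absence set regions and DNA/RNA fraction partitions
  across samples and depths;
- distributed-pathway detection (pathways predicted from combined genomes
  but from no individual genome) with a 75 % both-taxa reaction-coverage
  plausibility filter;
- confusion-table performance metrics (sensitivity, specificity,
  precision, accuracy, F-measure, MCC) over an explicit pathway universe;
- seedable synthetic communities (even or 20-fold-skewed abundances,
  core/accessory pathway structure, engineered split pathways, coverage
  subsampling with replacement) for validation without any downloads.

## Worked example

```r
library(epgdbkit)

tree <- read_lineage_table(c("lineage",
  "root;cellular organisms;Bacteria;Cyanobacteria;Prochlorococcus",
  "root;cellular organisms;Bacteria;Proteobacteria;Pelagibacter",
  "root;cellular organisms;Eukaryota;Viridiplantae;Ostreococcus"))

tab <- read_pathway_table("pathways.tsv")   # sample, pathway, counts, CDS taxa
tab <- qc_filter(tab, min_cds = 10)         # drops sparsely supported records

ranges <- expected_range_map(list("PWY-101" = "Bacteria",
                                  "PWY-202" = "Viridiplantae"), tree)
res <- assign_disagreement_classes(compute_wtd(tab, tree, ranges))
print(res, row.names = FALSE)
```

```
 sample pathway_id observed_lca matched_expected    wtd disagreement_class
 HOT25m    PWY-101     Bacteria         Bacteria  0.000               None
 HOT25m    PWY-202 Pelagibacter    Viridiplantae -1.625                Low
```

`PWY-101`'s coding sequences (half *Prochlorococcus*, half
*Pelagibacter*) have LCA `Bacteria`, which sits inside the expected range
— distance 0, no disagreement. `PWY-202` is expected in green plants but
its coding sequences are all *Pelagibacter*: the path from
`Viridiplantae` crosses `cellular organisms` near the root, giving a
large negative distance (−1.625) and flagging the prediction as outside
its expected taxonomic range. A third record with only 3 mapped CDS was
removed by QC before scoring.

The same operations are available from the shell:

```sh
epgdbkit simulate --out sim --seed 11
epgdbkit qc --out qc --min-cds 10 sim/pathway_table.tsv sim/totals.tsv
epgdbkit wtd --out wtd qc/qc_table.tsv sim/lineage.tsv sim/expected_ranges.tsv
epgdbkit classify --out cls wtd/wtd.tsv
```

## Scope

Pathway inference (PathoLogic/Pathway Tools), ORF calling, and homology
annotation are upstream black boxes: this package consumes their tabular
outputs. Expected taxonomic ranges are consumed as curated data, never
re-derived. See `vignettes/epgdbkit-methods.Rmd` for the model details,
parameter choices and limitations.
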