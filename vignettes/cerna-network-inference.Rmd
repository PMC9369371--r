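---
title: "Inferring lncRNA-mediated ceRNA networks with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-mediated ceRNA networks with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
library(dplyr)
```

## The scientific problem

Under the competing endogenous RNA (ceRNA) hypothesis, a long non-coding RNA
(lncRNA) that shares miRNA response elements (MREs) with an mRNA can act as a
sponge: it sequesters the miRNA and thereby de-represses the mRNA. The
observable signature of a sponge triad in expression data is a *sign
pattern*: the lncRNA and the mRNA move together, and the miRNA moves against
them. `cernet` implements the complete inference chain that turns case/control
RNA-seq count matrices of three RNA classes plus target-prediction tables
into a ranked, sign-consistent lncRNA-miRNA-mRNA (L-M-T) network, with qPCR
concordance as the final filter. The intended design is the one used in
transgenic Alzheimer's-model (5×FAD) mouse studies: three cases versus three
controls per brain region (cortex and hippocampus), with a 4-vs-4 qPCR
validation panel.

## The screening model

Counts are normalized to TPM (lncRNA/mRNA, length-corrected) or CPM (miRNA).
Differential expression of a feature is summarized by a *floored* log2 fold
change of group means,

$$\mathrm{log_2FC} = \log_2\frac{\max(\bar x_{case},\ \epsilon)}
{\max(\bar x_{ctrl},\ \epsilon)},\qquad \epsilon = 10^{-4},$$

so that transcripts undetected in one group produce large finite fold
changes rather than infinities. The floor constant is fixed at `1e-4`
because reference SDEL tables print undetected group means as `0.0001`, and
with that floor every printed fold change in those tables reproduces to two
decimals (one row is off by 0.005 only because its printed *mean* is itself
rounded; the tests propagate that input-rounding bound).

Two screens are applied:

* **SDEL screen** (lncRNAs, and mRNAs entering networks): linear fold change
  strictly above 2 (equivalently |log2FC| > 1, evaluated strictly - a
  printed log2FC of exactly 1.00 can arise from a ratio of 2.0007, which
  passes) *and* Benjamini-Hochberg q-value below 0.01. The p-value is a
  two-sided equal-variance Student's t-test on the normalized values, with
  p = 1 assigned to features constant in both groups. BH is applied per RNA
  class and region list.
* **Changed screen** (miRNAs, and the mRNA anti-correlation pools): any
  strict change, i.e. signed fold change beyond ±1, where the signed
  convention reports r for up and -1/r for down so |value| ≥ 1 always.

The choice of a plain t-test on normalized values (rather than a count
model) follows the analysis style the pipeline reproduces; it deliberately
limits power at n = 3, which is why p-values from count-model reanalyses are
not comparable and are not treated as reference quantities anywhere in the
package. The z-score transform (`zscore_rows()`) uses the sample (n-1)
standard deviation.

## Target integration and the seed-match stand-in

Predictions from multiple databases are unioned on (source, target) with
provenance concatenated (`merge_predictions()`), so database-derived and
sequence-derived edges stay distinguishable. Where no database export is
available, `find_seed_sites()` provides a transparent stand-in: it scans a
transcript for reverse complements of the miRNA seed (positions 2-7/2-8,
counting the 5' nucleotide as position 1) and classifies sites into the
canonical hierarchy 8mer > 7mer-m8 > 7mer-A1 > 6mer, reporting each core
occurrence once at its strongest class. Coordinates are 0-based, half-open,
on the transcript's sense strand; T and U are equivalent on input. It does
not score thermodynamics or conservation - it is an explicit, reproducible
replacement for a trained predictor, not a reimplementation of one.

The ceRNA sign logic enters through two set filters: predicted miRNAs of
upregulated lncRNAs are intersected with *down*-changed miRNAs (and vice
versa, `anticorrelated_mirnas()`), and targets of down-regulated miRNAs are
intersected with *up*-changed mRNAs (`concordant_mrnas()`).

## Network construction and centralities

`cerna_graph` objects are typed undirected tripartite graphs (only
lncRNA-miRNA and miRNA-mRNA edges; no self-loops or parallel edges).
Centralities follow the Cytoscape NetworkAnalyzer conventions, because the
reference values the package reproduces were produced there:

* closeness(v) = (number of other nodes reachable from v) / (sum of
  shortest-path distances to them), computed within v's component; isolated
  nodes get 0;
* betweenness is the pair-dependency sum normalized by (N-1)(N-2)/2 with N
  the whole graph's node count.

Hub miRNAs are those whose degree strictly exceeds twice the median degree
over miRNA nodes (midpoint-rule median). Node ranking in the final network
is by (degree, betweenness, closeness) descending with a lexicographic ID
tie-break, so outputs are deterministic.

A caution on the packaged L-M-T worked example: the interaction table groups
mRNAs per row rather than per miRNA, so the exact miRNA-mRNA wiring is
under-determined. The package adopts the row-complete convention (every
miRNA of a row paired with every mRNA of that row). Degree and closeness of
the top lncRNA are provably insensitive to this choice - every mRNA remains
at distance 2 as long as it keeps at least one miRNA of its row - and the
tests verify this invariance by sampling random row-consistent assignments.
Betweenness is *not* invariant to the wiring, which is why the package
treats the top node's betweenness as wiring-dependent and does not present
it as a reference value.

## Triads, enrichment, and qPCR validation

`assemble_triads()` enumerates every (lncRNA, miRNA, mRNA) triple connected
by both required edges and splits it by the sign rule
(lnc = mRNA direction ≠ miRNA direction), returning rejected triples with
the violated rule named. Enrichment of network mRNAs is a generic
hypergeometric overrepresentation test over a user-supplied annotation
(GMT-style input; background defaults to all annotated genes; BH over
tested terms; significance at raw p < 0.01; top-10-per-category reporting
with ID tie-breaks). Real GO/KEGG content is an input, never fetched, so
term counts depend on the annotation supplied and are not reference values.

qPCR quantification uses the Livak 2^-ddCt convention: per-sample
dCt = Ct(gene) - Ct(reference), group ddCt = mean case dCt - mean control
dCt. Group differences are tested with a Mann-Whitney U test made exact by
enumerating all C(n+m, n) group assignments (mid-ranks for ties; the
enumeration conditions on the observed values, so tied data remain exact).
Exactness matters: at 4 vs 4 the smallest attainable two-sided p is
2/70 ≈ 0.029, so an asymptotic test is unreliable exactly where this design
operates. `concordance_filter()` classifies each gene as validated,
discordant, or not significant against its RNA-seq direction; only
validated RNAs survive into the final network.

## The synthetic-data generators

All pipeline inputs can be generated with ground truth
(`simulate_dataset()`), making every stage testable without external data.
What the generator emulates, and the defaults:

* **Design**: 3 vs 3 negative-binomial counts per region, two regions with
  consistent planted effects (optionally flipped per region); 4 vs 4 qPCR
  panel with 0.25-cycle Ct noise and class-appropriate reference genes
  (GAPDH/U6).
* **Scale**: 300 lncRNAs, 200 miRNAs, 500 mRNAs by default - a deliberately
  scaled-down transcriptome chosen so the full 20-replicate recovery study
  runs in seconds while keeping the multiple-testing burden realistic
  relative to the planted signal count.
* **Dispersion**: 0.005 (biological CV ≈ 7%). Reference q-values reach
  1e-20 and below in 3-vs-3 designs, which is only attainable when
  within-group variability is very low; the default emulates that regime. A
  plain t-test at df = 4 has a hard ceiling t ≈ √3/CV however large the
  fold change, so this parameter - not the effect size - controls power.
* **Effects**: twelve planted triads in two sign-pattern modules,
  |log2FC| = 8 (lncRNA), 2 (miRNA), 4 (mRNA), matching the magnitudes of
  the reference SDEL tables. Triads sharing a pattern form a sponge module:
  the lncRNA-miRNA layer is completed within the module (sponges bind many
  miRNAs), and the ground-truth triad set is defined as *all*
  sign-consistent triples induced by the planted edges, so recovery scoring
  has no hidden ambiguity.
* **Decoys** (rate 0.2): sponge decoys attach unplanted miRNAs to planted
  lncRNAs - real sponges predict dozens of partners, and this degree-1 tail
  is what makes the twice-the-median hub rule selective - plus background
  edges among unplanted features. No decoy can complete a sign-consistent
  planted triad by construction.
* **Dropout** (2%): unplanted features silenced in one random group,
  emulating the floored `0.0001` rows of the reference tables; they are
  recorded as true differential expression in the ground truth.

What the generator does **not** emulate: titration kinetics (the inference
uses signs and sets, not binding stoichiometry), library-preparation
artefacts, batch effects, correlated features, or length bias beyond TPM.
Passing recovery tests therefore demonstrate the pipeline's correctness
under its own model, not robustness to those real-data phenomena.

## Numerical and design choices

* Strict inequalities everywhere a threshold is named ("greater than"),
  including the hub rule and both fold-change screens; ties at the boundary
  are excluded.
* Features present in only one region are kept but flagged by
  `cross_region_consistency()`, so the core analysis can restrict to
  both-region features without losing information.
* Transcript-level IDs are the primary key; a gene-level alias (one core
  lncRNA is listed under its gene ID in the reference core table) is left
  to the user rather than resolved silently.
* Missing values in expression input are errors, not imputed: the
  statistics assume complete 3-vs-3 designs.
* Degenerate inputs: all-zero samples are errors in normalization; constant
  features are errors in z-scoring (named in the message) and get p = 1 in
  the t-test when constant in both groups.
* Problem sizes in the shipped tests: oracle suites run on exhaustive small
  configurations (hypergeometric N ≤ 12, graphs to ~12 nodes, Mann-Whitney
  to 6 per group, 200 random seed-match pairs) and the recovery study uses
  20 replicates at the generator defaults; these sizes were chosen as the
  smallest that exercise every code path with exhaustive or
  high-replication coverage.

## Known limitations

The t-test screening stage is faithful to the reproduced analysis style but
underpowered for n = 3 count data compared to count models (edgeR/DESeq2);
the package intentionally does not substitute one. The seed-match stand-in
over-predicts relative to trained target predictors. Enrichment results are
only as good as the supplied annotation. The qPCR stage assumes perfect
amplification efficiency (no standard-curve correction).
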